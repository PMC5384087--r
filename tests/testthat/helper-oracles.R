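# Small fixed trees used across tests
tree_cherry <- function() parse_newick("(A:1,B:1);")
tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree4_balanced <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
tree4_pectinate <- function() parse_newick("(((A:1,B:1):1,C:2):1,D:3);")

# ---------------------------------------------------------------------------
# Independent DEC oracle: exhaustive enumeration over internal-node state
# assignments. Everything (state enumeration, rate matrix, transition
# matrices, cladogenesis weights) is rebuilt here from first principles;
# the matrix exponential comes from Matrix::expm, a different implementation
# than anything on the package's pruning path.
# ---------------------------------------------------------------------------

oracle_states <- function(n_areas, max_size) {
  masks <- integer(0)
  for (size in seq_len(max_size)) {
    for (cmb in utils::combn(n_areas, size, simplify = FALSE)) {
      masks <- c(masks, sum(2L^(cmb - 1L)))
    }
  }
  # order by size then mask to mirror the documented state order
  sz <- vapply(masks, function(m) sum(bitwAnd(m, 2L^(0:30)) > 0), numeric(1))
  masks[order(sz, masks)]
}

oracle_Q <- function(masks, n_areas, d, e, mult, max_size) {
  all_masks <- c(masks, 0L)
  ns <- length(all_masks)
  Q <- matrix(0, ns, ns)
  for (si in seq_len(ns)) {
    S <- all_masks[si]
    if (S == 0L) next
    occ <- which(bitwAnd(S, 2L^(0:(n_areas - 1L))) > 0)
    if (length(occ) < max_size) {
      for (j in seq_len(n_areas)[-occ]) {
        tgt <- match(S + 2L^(j - 1L), all_masks)
        if (!is.na(tgt)) Q[si, tgt] <- Q[si, tgt] + d * sum(mult[occ, j])
      }
    }
    for (i in occ) {
      tgt <- match(S - 2L^(i - 1L), all_masks)
      Q[si, tgt] <- Q[si, tgt] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# ordered-daughter cladogenesis weight per the documented law
oracle_clado_w <- function(S, X, Y, n_areas) {
  occ <- which(bitwAnd(S, 2L^(0:(n_areas - 1L))) > 0)
  if (length(occ) == 1L) return(as.numeric(X == S && Y == S))
  w <- 1 / (2 * length(occ))
  tot <- 0
  for (i in occ) {
    ib <- 2L^(i - 1L)
    rem <- S - ib
    if ((X == ib && Y == S) || (X == S && Y == ib)) tot <- tot + w
    if ((X == ib && Y == rem) || (X == rem && Y == ib)) tot <- tot + w
  }
  tot
}

# transition matrix over a branch, segmenting at slice boundaries
oracle_P <- function(Qs, boundaries, pa, ca, ns) {
  P <- diag(ns)
  if (pa <= ca) return(P)
  cuts <- boundaries[-c(1, length(boundaries))]
  pts <- sort(unique(c(ca, pa, cuts[cuts > ca & cuts < pa])), decreasing = TRUE)
  for (i in seq_len(length(pts) - 1L)) {
    hi <- pts[i]; lo <- pts[i + 1L]
    mid <- (hi + lo) / 2
    sl <- which(boundaries[-length(boundaries)] >= mid &
                  mid > boundaries[-1L])
    if (length(sl) == 0L) sl <- 1L
    P <- P %*% as.matrix(Matrix::expm(Matrix::Matrix(Qs[[sl[1]]] * (hi - lo))))
  }
  P
}

oracle_dec_loglik <- function(tree, tip_range_strings, d, e, areas_n,
                              max_size, boundaries = c(100, 0),
                              mults = NULL) {
  if (is.null(mults)) {
    m <- matrix(1, areas_n, areas_n); diag(m) <- 0
    mults <- rep(list(m), length(boundaries) - 1L)
  }
  masks <- oracle_states(areas_n, max_size)
  all_masks <- c(masks, 0L)
  ns <- length(all_masks)
  Qs <- lapply(mults, function(m) oracle_Q(masks, areas_n, d, e, m, max_size))
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[1:n]) - depth
  tip_mask <- vapply(tip_range_strings[tree$tip.label], function(s) {
    sum(2L^(match(strsplit(s, "")[[1]], LETTERS) - 1L))
  }, numeric(1))
  internal <- (n + 1L):nn
  # precompute branch transition matrices over observable states
  Pmat <- vector("list", nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    Pmat[[k]] <- oracle_P(Qs, boundaries, age[tree$edge[k, 1]],
                          age[tree$edge[k, 2]], ns)
  }
  kids <- lapply(seq_len(nn), function(v) which(tree$edge[, 1] == v))
  state_of <- function(node, assign) {
    if (node <= n) tip_mask[node] else assign[[as.character(node)]]
  }
  total <- 0
  grid <- do.call(expand.grid, rep(list(seq_along(masks)), length(internal)))
  for (g in seq_len(nrow(grid))) {
    assign <- as.list(masks[as.integer(grid[g, ])])
    names(assign) <- as.character(internal)
    contrib <- 1 / length(masks) # flat root prior over observable states
    for (v in internal) {
      Sv <- assign[[as.character(v)]]
      es <- kids[[v]]
      cl <- tree$edge[es[1], 2]; cr <- tree$edge[es[2], 2]
      Sl <- state_of(cl, assign); Sr <- state_of(cr, assign)
      il <- match(Sl, all_masks); ir <- match(Sr, all_masks)
      node_sum <- 0
      for (X in masks) for (Y in masks) {
        w <- oracle_clado_w(Sv, X, Y, areas_n)
        if (w > 0) {
          node_sum <- node_sum +
            w * Pmat[[es[1]]][match(X, all_masks), il] *
            Pmat[[es[2]]][match(Y, all_masks), ir]
        }
      }
      contrib <- contrib * node_sum
      if (contrib == 0) break
    }
    total <- total + contrib
  }
  log(total)
}

# ---------------------------------------------------------------------------
# Independent Yule (pure birth, constant rate, f = 1) closed form for the
# crown-conditioned, root-excluded likelihood convention
# ---------------------------------------------------------------------------
oracle_yule_loglik <- function(bt, lambda) {
  n <- length(bt) + 1L
  (n - 2) * log(lambda) - lambda * (2 * bt[1] + sum(bt[-1]))
}

# dense multivariate-normal BM log-likelihood built directly from vcv
oracle_bm_dense <- function(tree, x, sigma2, root) {
  V <- ape::vcv.phylo(tree) * sigma2
  n <- length(x)
  r <- x[rownames(V)] - root
  -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
            drop(r %*% solve(V, r)))
}
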