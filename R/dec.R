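#' Biogeographic area system
#'
#' Ordered set of single-letter area labels with human-readable names. The
#' default is the nine Neotropical areas used throughout the package:
#' Central America (A), Western lowlands (B), slopes of the Western/Central
#' Cordillera of Ecuador and Colombia (C), Central Andes (D), slopes of the
#' Eastern Cordillera of Colombia and Venezuela (E), Upper Amazon (F),
#' Lower Amazon (G), Atlantic Forest (H) and Guiana Shield (I).
#'
#' @param labels Character vector of unique single-letter labels (>= 2).
#' @param names Optional human-readable names (same length).
#' @return Character vector of labels with a `names` attribute, class
#'   `area_system`.
#' @export
area_system <- function(labels = LETTERS[1:9], names = NULL) {
  if (length(labels) < 2L) stop("need >= 2 areas", call. = FALSE)
  if (anyDuplicated(labels)) stop("area labels must be unique", call. = FALSE)
  if (any(nchar(labels) != 1L)) stop("area labels must be single characters", call. = FALSE)
  if (is.null(names)) {
    names <- if (identical(labels, LETTERS[1:9])) {
      c("Central America", "Western lowlands", "Northern Andes (W/C cordilleras)",
        "Central Andes", "Eastern Cordillera (Colombia/Venezuela)",
        "Upper Amazon", "Lower Amazon", "Atlantic Forest", "Guiana Shield")
    } else labels
  }
  stopifnot(length(names) == length(labels))
  structure(as.character(labels), names = names, class = "area_system")
}

n_areas <- function(areas) length(unclass(areas))

# ---- range states as bitmasks -----------------------------------------------

popcount <- function(mask) {
  n <- integer(length(mask))
  while (any(mask > 0L)) {
    n <- n + (mask %% 2L)
    mask <- mask %/% 2L
  }
  n
}

mask_to_label <- function(mask, areas) {
  labs <- unclass(areas)
  vapply(mask, function(m) {
    if (m == 0L) return("0")
    paste(labs[bitwAnd(m, bitwShiftL(1L, seq_along(labs) - 1L)) > 0L], collapse = "")
  }, character(1))
}

#' Parse an area string like `"ACD"` into a range-state bitmask
#' @param x Character vector of concatenated area letters.
#' @param areas An [area_system()].
#' @return Integer bitmask vector (bit i set when area i occupied).
#' @export
parse_range <- function(x, areas = area_system()) {
  labs <- unclass(areas)
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) == 0L) stop("empty range string", call. = FALSE)
    if (anyDuplicated(ch)) stop("duplicated area letter in range '", s, "'", call. = FALSE)
    idx <- match(ch, labs)
    if (anyNA(idx)) {
      stop("unknown area '", paste(ch[is.na(idx)], collapse = ""),
           "' in range '", s, "'", call. = FALSE)
    }
    sum(bitwShiftL(1L, idx - 1L))
  }, integer(1), USE.NAMES = !is.null(names(x)))
}

#' Enumerate observable range states
#'
#' All non-empty subsets of the areas up to `max_range_size`, ordered by size
#' then by bitmask (lexicographic in the area ordering); the empty (null)
#' range, used internally as the absorbing extirpated state, is appended last.
#'
#' @inheritParams parse_range
#' @param max_range_size Largest observable range size (default 4, the cap
#'   used for the nine-area system).
#' @return Tibble with columns `state` (index), `mask`, `label`, `size`;
#'   the final row is the null range (`size` 0).
#' @export
enumerate_states <- function(areas = area_system(), max_range_size = 4L) {
  k <- n_areas(areas)
  if (max_range_size < 1L || max_range_size > k) {
    stop("max_range_size must be in [1, ", k, "]", call. = FALSE)
  }
  masks <- seq_len(2L^k - 1L)
  sz <- popcount(masks)
  masks <- masks[sz <= max_range_size]
  sz <- sz[sz <= max_range_size]
  ord <- order(sz, masks)
  masks <- c(masks[ord], 0L)
  tibble::tibble(
    state = seq_along(masks),
    mask = masks,
    label = mask_to_label(masks, areas),
    size = popcount(masks)
  )
}

# ---- dispersal schedule -----------------------------------------------------

#' Time-stratified dispersal multiplier schedule
#'
#' Epochs are delimited by `boundaries` in my before present (strictly
#' decreasing, ending at 0); `multipliers` holds one `n_areas x n_areas`
#' matrix in `[0, 1]` per epoch, oldest first. Branches older than the first
#' boundary fall into the oldest epoch (extended, never an error).
#'
#' @inheritParams parse_range
#' @param boundaries Numeric vector, default `c(11, 8, 5, 0)` (three epochs).
#' @param multipliers List of matrices, one per epoch.
#' @return Object of class `dispersal_schedule`.
#' @seealso [default_dispersal_schedule()]
#' @export
dispersal_schedule <- function(areas = area_system(),
                               boundaries = c(11, 8, 5, 0),
                               multipliers) {
  k <- n_areas(areas)
  if (any(diff(boundaries) >= 0)) {
    stop("slice boundaries must be strictly decreasing toward the present",
         call. = FALSE)
  }
  if (utils::tail(boundaries, 1) != 0) stop("last boundary must be 0", call. = FALSE)
  n_slice <- length(boundaries) - 1L
  if (!is.list(multipliers)) multipliers <- list(multipliers)
  if (length(multipliers) == 1L && n_slice > 1L) {
    multipliers <- rep(multipliers, n_slice)
  }
  if (length(multipliers) != n_slice) {
    stop("need one multiplier matrix per slice (", n_slice, ")", call. = FALSE)
  }
  for (m in multipliers) {
    stopifnot(is.matrix(m), nrow(m) == k, ncol(m) == k)
    if (any(m < 0 | m > 1)) stop("multipliers must lie in [0, 1]", call. = FALSE)
  }
  structure(list(areas = areas, boundaries = boundaries, multipliers = multipliers),
            class = "dispersal_schedule")
}

#' Default nine-area, three-epoch dispersal schedule
#'
#' A reproducible three-class scheme over the default Neotropical areas:
#' adjacent areas 1.0, areas two steps apart on the adjacency graph 0.5, and
#' long-distance or blocked pairs 0.01. Epochs are 11-8, 8-5 and 5-0 my; in
#' the two epochs older than 5 my, dispersal into and out of Central America
#' is reduced to 0.01 (pre-Isthmus), and in the oldest epoch dispersal
#' involving the Upper Amazon is also reduced to 0.01 (Pebas wetland system).
#' These values are a synthetic, clearly documented stand-in for
#' expert-drawn matrices, not an empirical reconstruction; supply your own
#' matrices through [dispersal_schedule()] for real analyses.
#'
#' @return A `dispersal_schedule` object.
#' @export
default_dispersal_schedule <- function() {
  areas <- area_system()
  k <- n_areas(areas)
  adj_pairs <- c("AB", "AC", "BC", "CD", "CE", "DE", "DF", "EF", "EI",
                 "FG", "FI", "GH", "GI")
  adj <- matrix(FALSE, k, k, dimnames = list(unclass(areas), unclass(areas)))
  for (p in adj_pairs) {
    i <- substr(p, 1, 1); j <- substr(p, 2, 2)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  # graph distances by repeated neighbourhood expansion
  dist <- matrix(Inf, k, k); diag(dist) <- 0
  dist[adj] <- 1
  for (s in seq_len(k)) {
    for (via in seq_len(k)) {
      cand <- outer(dist[, via], dist[via, ], `+`)
      dist <- pmin(dist, cand)
    }
  }
  base <- matrix(0.01, k, k, dimnames = dimnames(adj))
  base[dist == 1] <- 1.0
  base[dist == 2] <- 0.5
  diag(base) <- 0
  m_old <- base
  m_old["A", ] <- pmin(m_old["A", ], 0.01); m_old[, "A"] <- pmin(m_old[, "A"], 0.01)
  m_oldest <- m_old
  m_oldest["F", ] <- pmin(m_oldest["F", ], 0.01); m_oldest[, "F"] <- pmin(m_oldest[, "F"], 0.01)
  dispersal_schedule(areas, c(11, 8, 5, 0), list(m_oldest, m_old, base))
}

#' Anagenetic DEC rate matrix for one epoch
#'
#' Transition rates (events/my) between range states: dispersal
#' `S -> S + {j}` at rate `d * sum_{i in S} m[i, j]` (only while
#' `|S| < max_range_size`), extirpation `S -> S - {i}` at rate `e` per
#' occupied area (a single-area range is extirpated into the absorbing null
#' range). No direct range switching. The diagonal closes each row to zero.
#'
#' @param states Tibble from [enumerate_states()].
#' @param d,e Non-negative dispersal and extirpation rates (events/my).
#' @param multiplier Area-by-area dispersal multiplier matrix for the epoch.
#' @return Square rate matrix over all states (null last, absorbing).
#' @export
build_rate_matrix <- function(states, d, e, multiplier) {
  if (d < 0 || e < 0) stop("d and e must be non-negative", call. = FALSE)
  masks <- states$mask
  ns <- length(masks)
  max_size <- max(states$size)
  k <- nrow(multiplier)
  bit <- bitwShiftL(1L, seq_len(k) - 1L)
  idx_of <- integer(max(masks) + 1L)
  idx_of[masks + 1L] <- seq_len(ns)
  Q <- matrix(0, ns, ns, dimnames = list(states$label, states$label))
  for (s in seq_len(ns)) {
    S <- masks[s]
    if (S == 0L) next # null range is absorbing
    occ <- which(bitwAnd(S, bit) > 0L)
    if (length(occ) < max_size) {
      for (j in setdiff(seq_len(k), occ)) {
        rate <- d * sum(multiplier[occ, j])
        if (rate > 0) {
          tgt <- idx_of[bitwOr(S, bit[j]) + 1L]
          if (tgt > 0L) Q[s, tgt] <- Q[s, tgt] + rate
        }
      }
    }
    if (e > 0) {
      for (i in occ) {
        tgt <- idx_of[(S - bit[i]) + 1L]
        Q[s, tgt] <- Q[s, tgt] + e
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# slice index for an age interval: slice i spans (boundaries[i], boundaries[i+1]]
# returns a matrix with rows (slice, dt), oldest segment first
slice_segments <- function(boundaries, parent_age, child_age) {
  cuts <- boundaries[-c(1L, length(boundaries))]
  pts <- sort(unique(c(child_age, parent_age, cuts[cuts > child_age & cuts < parent_age])))
  if (length(pts) < 2L) return(NULL)
  lo <- pts[-length(pts)]; hi <- pts[-1L]
  mid <- (lo + hi) / 2
  slice <- findInterval(-mid, -boundaries, rightmost.closed = TRUE)
  slice[slice < 1L] <- 1L # older than the oldest boundary: extend oldest slice
  slice[slice > length(boundaries) - 1L] <- length(boundaries) - 1L
  ord <- order(hi, decreasing = TRUE)
  cbind(slice = slice[ord], dt = (hi - lo)[ord])
}

#' Transition probabilities along a branch crossing epoch boundaries
#'
#' The branch from `parent_age` down to `child_age` is split at the epoch
#' boundaries of the schedule; per-segment matrix exponentials are multiplied
#' in time order (older first). A zero-length branch yields the identity.
#'
#' @param Q_slices List of rate matrices, one per epoch (oldest first).
#' @param boundaries Epoch boundaries (my, decreasing, ending 0).
#' @param parent_age,child_age Ages in my before present, `parent >= child`.
#' @return Stochastic matrix (rows sum to 1; tiny negative entries clamped).
#' @export
branch_transition <- function(Q_slices, boundaries, parent_age, child_age) {
  stopifnot(parent_age >= child_age, child_age >= -1e-12)
  ns <- nrow(Q_slices[[1]])
  P <- diag(ns)
  segs <- slice_segments(boundaries, parent_age, child_age)
  if (is.null(segs)) return(P)
  expms <- lapply(Q_slices, expm_factory)
  # multiply oldest segment first: rows index the parent (older) state
  for (r in seq_len(nrow(segs))) {
    if (segs[r, "dt"] <= 0) next
    P <- P %*% expms[[segs[r, "slice"]]](segs[r, "dt"])
  }
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q_slices[[1]])
  P
}

# ---- cladogenesis law -------------------------------------------------------

# Precompute, for every observable state index, the scenario structure used by
# the node inheritance law. For |S| = 1 the only scenario is sympatry (S, S).
# For |S| >= 2 there are 2|S| scenarios with weight 1/(2|S|) each: subset
# sympatry ({i}, S) and vicariance ({i}, S \ {i}) for every occupied area i,
# each scenario summed over both daughter orderings.
clado_structure <- function(states) {
  masks <- states$mask
  ns_obs <- length(masks) - 1L # null excluded
  idx_of <- integer(max(masks) + 1L)
  idx_of[masks + 1L] <- seq_along(masks)
  lapply(seq_len(ns_obs), function(s) {
    S <- masks[s]
    occ_bits <- bitwShiftL(1L, which(bitwAnd(S, bitwShiftL(1L, 0:30)) > 0L) - 1L)
    size <- length(occ_bits)
    if (size == 1L) {
      return(list(size = 1L, self = s))
    }
    i_idx <- idx_of[occ_bits + 1L]                 # singleton daughter {i}
    rem_idx <- idx_of[(S - occ_bits) + 1L]         # complement daughter S \ {i}
    list(size = size, self = s, i_idx = i_idx, rem_idx = rem_idx,
         w = 1 / (2 * size))
  })
}

# combine two daughter vectors (already propagated to the node) into the
# node's conditional likelihood over observable states
clado_combine <- function(cl, wl, wr) {
  ns_obs <- length(cl)
  out <- numeric(ns_obs)
  for (s in seq_len(ns_obs)) {
    st <- cl[[s]]
    if (st$size == 1L) {
      out[s] <- wl[s] * wr[s]
    } else {
      acc <- sum(wl[st$i_idx] * wr[s] + wl[s] * wr[st$i_idx] +
                   wl[st$i_idx] * wr[st$rem_idx] + wl[st$rem_idx] * wr[st$i_idx])
      out[s] <- st$w * acc
    }
  }
  out
}

# ---- pruning likelihood -----------------------------------------------------

# internal: shared setup for dec_loglik / ancestral_ranges
dec_setup <- function(tree, tip_ranges, schedule, max_range_size) {
  validate_chronogram(tree)
  areas <- schedule$areas
  states <- enumerate_states(areas, max_range_size)
  ns_obs <- nrow(states) - 1L
  if (is.character(tip_ranges)) tip_ranges <- parse_range(tip_ranges, areas)
  tip_ranges <- tip_ranges[tree$tip.label]
  if (anyNA(tip_ranges)) {
    stop("tip ranges missing for: ",
         paste(tree$tip.label[is.na(tip_ranges)], collapse = ", "), call. = FALSE)
  }
  sizes <- popcount(as.integer(tip_ranges))
  bad <- sizes > max_range_size | sizes < 1L
  if (any(bad)) {
    stop("tip range of ", paste(tree$tip.label[bad], collapse = ", "),
         " outside [1, max_range_size=", max_range_size, "]", call. = FALSE)
  }
  tip_state <- match(as.integer(tip_ranges), states$mask)
  if (anyNA(tip_state)) stop("tip range not among observable states", call. = FALSE)
  ages <- node_ages(tree)
  # parameter-independent traversal structures, computed once per dataset
  n_edge <- nrow(tree$edge)
  segs <- vector("list", n_edge)
  for (k in seq_len(n_edge)) {
    segs[[k]] <- slice_segments(schedule$boundaries,
                                ages[tree$edge[k, 1L]], ages[tree$edge[k, 2L]])
  }
  po_edges <- ape::postorder(tree)
  po_nodes <- unique(tree$edge[po_edges, 1L])
  n <- ape::Ntip(tree)
  child_edges <- matrix(0L, n + tree$Nnode, 2L)
  for (k in seq_len(n_edge)) {
    p <- tree$edge[k, 1L]
    child_edges[p, if (child_edges[p, 1L] == 0L) 1L else 2L] <- k
  }
  if (any(rowSums(child_edges[po_nodes, , drop = FALSE] == 0L) > 0L)) {
    stop("DEC machinery requires a binary tree (polytomy found)", call. = FALSE)
  }
  list(states = states, ns_obs = ns_obs, tip_state = tip_state,
       clado = clado_structure(states), ages = ages,
       segs = segs, po_nodes = po_nodes, child_edges = child_edges)
}

# eigendecomposition-backed matrix exponential: exp(Q * t) for many t from a
# single eigen(Q); falls back to Pade scaling-and-squaring when the
# eigenvector matrix is ill-conditioned (defective or nearly so)
expm_factory <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- NULL
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      # validate the decomposition actually reproduces Q (defective check)
      err <- max(abs(Re(eg$vectors %*% (eg$values * Vi)) - Q))
      scale <- max(abs(Q), 1)
      if (!is.finite(err) || err > 1e-9 * scale) Vi <- NULL
    }
  }
  if (!is.null(Vi)) {
    function(t) {
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      P <- pracma::expm(Q * t)
      P[P < 0] <- 0
      P
    }
  }
}

# per-branch observable-block transition matrices for given params
dec_branch_mats <- function(tree, setup, d, e, schedule) {
  Qs <- lapply(schedule$multipliers, function(m)
    build_rate_matrix(setup$states, d, e, m))
  expms <- lapply(Qs, expm_factory)
  obs <- seq_len(setup$ns_obs)
  ns <- nrow(Qs[[1]])
  n_edge <- nrow(tree$edge)
  I_ns <- diag(ns)
  mats <- vector("list", n_edge)
  for (k in seq_len(n_edge)) {
    segs <- setup$segs[[k]]
    if (is.null(segs)) { mats[[k]] <- I_ns[obs, obs, drop = FALSE]; next }
    if (nrow(segs) == 1L) {
      P <- expms[[segs[1L, 1L]]](segs[1L, 2L])
    } else {
      P <- I_ns
      for (r in seq_len(nrow(segs))) {
        if (segs[r, 2L] <= 0) next
        P <- P %*% expms[[segs[r, 1L]]](segs[r, 2L])
      }
    }
    mats[[k]] <- P[obs, obs, drop = FALSE]
  }
  mats
}

# post-order pruning; returns per-node conditional likelihood vectors (L),
# per-edge propagated daughter vectors (w), and log scaling factors
dec_prune <- function(tree, setup, mats, clamp_node = NULL, clamp_state = NULL) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  L <- matrix(0, nn, setup$ns_obs)
  logscale <- numeric(nn)
  for (i in seq_len(n)) L[i, setup$tip_state[i]] <- 1
  for (v in setup$po_nodes) {
    es <- setup$child_edges[v, ]
    w1 <- mats[[es[1L]]] %*% L[tree$edge[es[1L], 2L], ]
    w2 <- mats[[es[2L]]] %*% L[tree$edge[es[2L], 2L], ]
    Lv <- clado_combine(setup$clado, w1, w2)
    if (!is.null(clamp_node) && v == clamp_node) {
      keep <- Lv[clamp_state]
      Lv[] <- 0
      Lv[clamp_state] <- keep
    }
    sc <- sum(Lv)
    if (sc > 0) {
      L[v, ] <- Lv / sc
      logscale[v] <- log(sc) + logscale[tree$edge[es[1L], 2L]] +
        logscale[tree$edge[es[2L], 2L]]
    } else {
      L[v, ] <- 0
      logscale[v] <- -Inf
    }
  }
  list(L = L, logscale = logscale)
}

dec_root_prior <- function(setup, root_prior) {
  if (is.character(root_prior) && root_prior == "flat") {
    rep(1 / setup$ns_obs, setup$ns_obs)
  } else {
    stopifnot(is.numeric(root_prior), length(root_prior) == setup$ns_obs)
    root_prior / sum(root_prior)
  }
}

#' Log-likelihood of tip ranges under the time-stratified DEC model
#'
#' Felsenstein pruning over observable range states. At each internal node
#' daughter likelihoods are combined through the DEC cladogenesis law:
#' single-area ranges speciate sympatrically (both daughters inherit the
#' range); widespread ranges divide by subset sympatry or vicariance with
#' equal scenario weights (see vignette). The root is summed under a flat
#' weight over observable states by default.
#'
#' @inheritParams mrca_clade
#' @param tip_ranges Named character vector of area strings (e.g. `"ACD"`),
#'   names matching tip labels, or a named integer bitmask vector.
#' @param d,e Dispersal and extirpation rates (events/my).
#' @param schedule A [dispersal_schedule()].
#' @param max_range_size Cap on range size (default 4).
#' @param root_prior `"flat"` (default) or a numeric weight vector over
#'   observable states.
#' @return Log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, tip_ranges, d, e, schedule = default_dispersal_schedule(),
                       max_range_size = 4L, root_prior = "flat") {
  setup <- dec_setup(tree, tip_ranges, schedule, max_range_size)
  mats <- dec_branch_mats(tree, setup, d, e, schedule)
  pr <- dec_prune(tree, setup, mats)
  root <- ape::Ntip(tree) + 1L
  w <- dec_root_prior(setup, root_prior)
  lik <- sum(w * pr$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[root]
}

#' Maximum-likelihood fit of the DEC dispersal and extirpation rates
#'
#' Bounded ML over `(d, e)` in `[1e-8, 10]^2` on the log scale with seeded
#' multi-start L-BFGS-B. The fit carries the marginal ancestral range
#' reconstruction at the optimum.
#'
#' @inheritParams dec_loglik
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Integer seed controlling the start points.
#' @param compute_ancestral Attach marginal ancestral ranges (default `TRUE`).
#' @return Object of class `dec_fit` with elements `d`, `e`, `logL`,
#'   `convergence`, `starts`, and `ancestral` (tibble from
#'   [ancestral_ranges()]).
#' @export
fit_dec <- function(tree, tip_ranges, schedule = default_dispersal_schedule(),
                    max_range_size = 4L, root_prior = "flat",
                    n_starts = 5L, seed = 1L, compute_ancestral = TRUE) {
  setup <- dec_setup(tree, tip_ranges, schedule, max_range_size)
  root <- ape::Ntip(tree) + 1L
  w <- dec_root_prior(setup, root_prior)
  nll <- function(par) {
    d <- exp(par[1]); e <- exp(par[2])
    mats <- dec_branch_mats(tree, setup, d, e, schedule)
    pr <- dec_prune(tree, setup, mats)
    lik <- sum(w * pr$L[root, ])
    if (lik <= 0 || !is.finite(pr$logscale[root])) return(1e10)
    -(log(lik) + pr$logscale[root])
  }
  lb <- log(1e-8); ub <- log(10)
  starts <- with_seed(seed, {
    s0 <- matrix(stats::runif(2L * (n_starts - 1L), log(1e-3), log(1)),
                 ncol = 2L)
    rbind(c(log(0.05), log(0.02)), s0)
  })
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = c(lb, lb), upper = c(ub, ub),
                   control = list(factr = 1e9)),
      error = function(e) list(value = Inf, par = starts[i, ], convergence = 99L)
    )
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (!any(is.finite(vals))) stop("DEC optimizer failed from every start", call. = FALSE)
  best <- runs[[which.min(vals)]]
  fit <- structure(list(
    d = exp(best$par[1]), e = exp(best$par[2]),
    logL = -best$value, convergence = best$convergence,
    starts = tibble::tibble(
      start = seq_len(nrow(starts)),
      d0 = exp(starts[, 1]), e0 = exp(starts[, 2]),
      logL = -vals
    ),
    tree = tree, tip_ranges = tip_ranges, schedule = schedule,
    max_range_size = max_range_size, root_prior = root_prior,
    n_tips = ape::Ntip(tree), seed = seed
  ), class = "dec_fit")
  if (compute_ancestral) {
    fit$ancestral <- ancestral_ranges(tree, tip_ranges, fit$d, fit$e, schedule,
                                      max_range_size, root_prior)
  }
  fit
}

#' @export
print.dec_fit <- function(x, ...) {
  cat("Time-stratified DEC fit\n")
  cat(sprintf("  d (dispersal)   : %.5f events/my\n", x$d))
  cat(sprintf("  e (extirpation) : %.5f events/my\n", x$e))
  cat(sprintf("  logL            : %.4f  (%d tips)\n", x$logL, x$n_tips))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.dec_fit <- function(x, ...) {
  tibble::tibble(term = c("d", "e"), estimate = c(x$d, x$e))
}

#' @importFrom generics glance
#' @export
glance.dec_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logL, n_tips = x$n_tips,
                 convergence = x$convergence,
                 max_range_size = x$max_range_size)
}

#' Marginal ancestral range probabilities
#'
#' For every node, the marginal posterior probability of each observable
#' range state given the tip data and parameters, computed by a full up-down
#' pass (conditional likelihoods from pruning combined with outside partial
#' likelihoods). The most-probable state per node breaks ties towards the
#' lowest state index (size, then lexicographic).
#'
#' @inheritParams dec_loglik
#' @return Tibble with one row per node: `node`, `is_tip`, `age`, `mp_state`
#'   (most-probable label), `mp_prob`, `top3` (label string), and a
#'   probability matrix column `prob` (list of named vectors).
#' @export
ancestral_ranges <- function(tree, tip_ranges, d, e,
                             schedule = default_dispersal_schedule(),
                             max_range_size = 4L, root_prior = "flat") {
  setup <- dec_setup(tree, tip_ranges, schedule, max_range_size)
  mats <- dec_branch_mats(tree, setup, d, e, schedule)
  pr <- dec_prune(tree, setup, mats)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  w <- dec_root_prior(setup, root_prior)
  ns <- setup$ns_obs
  # outside pass (pre-order): U[v, ] = partial likelihood of everything
  # outside v's subtree, as a function of v's state at its node
  U <- matrix(0, nn, ns)
  U[root, ] <- w
  pree <- rev(ape::postorder(tree))
  wcache <- vector("list", nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    wcache[[k]] <- as.numeric(mats[[k]] %*% pr$L[ch, ])
  }
  clado <- setup$clado
  for (e_idx in pree) {
    v <- tree$edge[e_idx, 1L]; ch <- tree$edge[e_idx, 2L]
    both <- setup$child_edges[v, ]
    wsib <- wcache[[if (both[1L] == e_idx) both[2L] else both[1L]]]
    # Utop[x]: outside likelihood at the top of ch's branch, state x
    Utop <- numeric(ns)
    for (s in seq_len(ns)) {
      uv <- U[v, s]
      if (uv == 0) next
      st <- clado[[s]]
      if (st$size == 1L) {
        Utop[s] <- Utop[s] + uv * wsib[s]
      } else {
        wgt <- uv * st$w
        # scenario ({i}, S): child can be {i} (sib gets S) or S (sib gets {i})
        Utop[st$i_idx] <- Utop[st$i_idx] + wgt * wsib[s]
        Utop[s] <- Utop[s] + wgt * sum(wsib[st$i_idx])
        # scenario ({i}, S \ {i})
        Utop[st$i_idx] <- Utop[st$i_idx] + wgt * wsib[st$rem_idx]
        Utop[st$rem_idx] <- Utop[st$rem_idx] + wgt * wsib[st$i_idx]
      }
    }
    Uraw <- as.numeric(Utop %*% mats[[e_idx]])
    sc <- sum(Uraw)
    U[ch, ] <- if (sc > 0) Uraw / sc else 0
  }
  labels <- setup$states$label[seq_len(ns)]
  prob_list <- vector("list", nn)
  mp_state <- character(nn); mp_prob <- numeric(nn); top3 <- character(nn)
  for (v in seq_len(nn)) {
    p <- U[v, ] * pr$L[v, ]
    tot <- sum(p)
    p <- if (tot > 0) p / tot else rep(NA_real_, ns)
    names(p) <- labels
    prob_list[[v]] <- p
    mp <- which.max(p) # ties: first index = lowest state order
    mp_state[v] <- labels[mp]
    mp_prob[v] <- p[mp]
    ord <- order(-p, seq_len(ns))[1:min(3L, ns)]
    top3[v] <- paste(sprintf("%s:%.3f", labels[ord], p[ord]), collapse = " ")
  }
  ages <- setup$ages
  tibble::tibble(
    node = seq_len(nn),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    is_tip = seq_len(nn) <= n,
    age = unname(ages),
    mp_state = mp_state,
    mp_prob = mp_prob,
    top3 = top3,
    prob = prob_list
  )
}

# ---- event counting ---------------------------------------------------------

#' Count in-situ speciation events within a focal region
#'
#' An internal node is an in-situ speciation event for the focal area set iff
#' its most-probable range and both daughters' most-probable ranges are
#' subsets of the focal set.
#'
#' @param reconstruction Tibble from [ancestral_ranges()] (or a `dec_fit`).
#' @param tree The chronogram the reconstruction was computed on.
#' @param focal_areas Character vector of area letters (or a single string).
#' @param areas The [area_system()] (defaults to the nine-area system).
#' @return One-row tibble: `count`, `n_internal`, `fraction`.
#' @export
count_in_situ_speciation <- function(reconstruction, tree, focal_areas,
                                     areas = area_system()) {
  if (inherits(reconstruction, "dec_fit")) {
    tree <- reconstruction$tree
    reconstruction <- reconstruction$ancestral
  }
  focal_areas <- paste(focal_areas, collapse = "")
  if (!nzchar(focal_areas)) stop("empty focal area set", call. = FALSE)
  focal <- parse_range(focal_areas, areas)
  masks <- parse_range(reconstruction$mp_state, areas)
  n <- ape::Ntip(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  in_focal <- function(m) bitwAnd(m, bitwNot(focal)) == 0L
  hits <- vapply(internal, function(v) {
    ch <- kids[[as.character(v)]]
    in_focal(masks[v]) && all(vapply(masks[ch], in_focal, logical(1)))
  }, logical(1))
  tibble::tibble(count = sum(hits), n_internal = length(internal),
                 fraction = sum(hits) / length(internal))
}

#' List colonization events of a target area
#'
#' A colonization of area X is a branch whose parent's most-probable range
#' excludes X and whose child's most-probable range includes X; the event is
#' dated to the branch's age interval.
#'
#' @inheritParams count_in_situ_speciation
#' @param target_area Single area letter.
#' @return Tibble with one row per event: `parent`, `child`, `from`, `to`,
#'   `age_older`, `age_younger`.
#' @export
count_colonizations <- function(reconstruction, tree, target_area,
                                areas = area_system()) {
  if (inherits(reconstruction, "dec_fit")) {
    tree <- reconstruction$tree
    reconstruction <- reconstruction$ancestral
  }
  if (!(target_area %in% unclass(areas))) {
    stop("unknown area '", target_area, "'", call. = FALSE)
  }
  bit <- parse_range(target_area, areas)
  masks <- parse_range(reconstruction$mp_state, areas)
  ages <- reconstruction$age
  has <- bitwAnd(masks, bit) > 0L
  idx <- which(!has[tree$edge[, 1L]] & has[tree$edge[, 2L]])
  tibble::tibble(
    parent = tree$edge[idx, 1L],
    child = tree$edge[idx, 2L],
    from = reconstruction$mp_state[tree$edge[idx, 1L]],
    to = reconstruction$mp_state[tree$edge[idx, 2L]],
    age_older = ages[tree$edge[idx, 1L]],
    age_younger = ages[tree$edge[idx, 2L]]
  )
}
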