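#' Parse a Newick string into a validated chronogram
#'
#' Reads a Newick tree (branch lengths in millions of years, my) and validates
#' it as a chronogram: a single root, non-negative branch lengths, unique
#' non-empty tip labels and, unless `check_ultrametric = FALSE`, root-to-tip
#' depths equal within a relative tolerance. Quoted labels and internal-node
#' labels (support values from dating software) are preserved but unused.
#'
#' @param text A Newick string (terminated by `;`).
#' @param check_ultrametric Validate equal root-to-tip depths (default `TRUE`).
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_newick <- function(text, check_ultrametric = TRUE, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  # balance check first so the error names the offending structure
  op <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  cl <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (op != cl) {
    stop(sprintf("unbalanced parentheses in Newick string: %d '(' vs %d ')'",
                 op, cl), call. = FALSE)
  }
  if (!grepl(";", text)) stop("Newick string must end with ';'", call. = FALSE)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable string", call. = FALSE)
  validate_chronogram(tree, check_ultrametric = check_ultrametric, tol = tol)
}

#' @rdname parse_newick
#' @param path Path to a file with one Newick tree per line.
#' @return `read_newick()` returns a list of `phylo` objects, one per line,
#'   named `tree_1`, `tree_2`, ... by line number.
#' @export
read_newick <- function(path, check_ultrametric = TRUE, tol = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trees in ", path, call. = FALSE)
  out <- lapply(lines, parse_newick, check_ultrametric = check_ultrametric, tol = tol)
  names(out) <- paste0("tree_", seq_along(out))
  out
}

#' @rdname parse_newick
#' @param tree A `phylo` object.
#' @return `write_newick()` returns the Newick string, invisibly when writing
#'   to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_chronogram <- function(tree, check_ultrametric = TRUE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (ape::Ntip(tree) < 2L) stop("chronogram needs >= 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label", call. = FALSE)
  if (is.null(tree$edge.length)) stop("missing branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length)) stop("missing branch lengths on some edges", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (check_ultrametric) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
    dev <- diff(range(depth)) / max(depth)
    if (!is.finite(dev) || dev > tol) {
      stop(sprintf("tree is not ultrametric: max relative tip-depth deviation %.3g exceeds tol %.3g",
                   dev, tol), call. = FALSE)
    }
  }
  tree
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured in my before present: tips have age 0 (snapped after
#' validation), the root has the crown age. Nodes are indexed as in
#' `ape::phylo`: tips `1..n`, root `n+1`, further internal nodes above.
#'
#' @inheritParams write_newick
#' @param tol Relative ultrametricity tolerance.
#' @return Named numeric vector of ages for all `2n - 1` (binary case) nodes.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  validate_chronogram(tree, check_ultrametric = TRUE, tol = tol)
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(n)]) - depth
  age[seq_len(n)] <- 0 # snap tips
  names(age) <- c(tree$tip.label, paste0("node_", (n + 1L):(n + tree$Nnode)))
  age
}

#' Branching times of a binary ultrametric tree
#'
#' @inheritParams node_ages
#' @return Internal-node ages sorted in descending order (crown age first);
#'   length `n_tips - 1`.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  validate_chronogram(tree, check_ultrametric = TRUE, tol = tol)
  if (tree$Nnode != ape::Ntip(tree) - 1L) {
    stop("tree contains polytomies; resolve before computing branching times",
         call. = FALSE)
  }
  n <- ape::Ntip(tree)
  age <- node_ages(tree, tol = tol)
  sort(unname(age[(n + 1L):(n + tree$Nnode)]), decreasing = TRUE)
}

#' Pagel's delta transformation of a chronogram
#'
#' Each node's depth from the root, x, is mapped to `x^delta * T^(1 - delta)`
#' where `T` is the crown depth, so that total depth is preserved and ages
#' stay comparable (in my) before and after rescaling. `delta > 1` compresses
#' early history (accelerating trait evolution towards the present);
#' `delta < 1` stretches it (early burst).
#'
#' @inheritParams write_newick
#' @param delta Positive scalar exponent.
#' @return A `phylo` object with rescaled branch lengths, identical topology.
#' @export
delta_transform <- function(tree, delta) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop("delta must be a positive finite scalar", call. = FALSE)
  }
  depth <- ape::node.depth.edgelength(tree)
  T_ <- max(depth)
  if (T_ <= 0) stop("tree has zero depth", call. = FALSE)
  new_depth <- depth^delta * T_^(1 - delta)
  out <- tree
  out$edge.length <- new_depth[tree$edge[, 2L]] - new_depth[tree$edge[, 1L]]
  out
}

#' Phylogenetic covariance of an ultrametric tree
#'
#' Matrix of shared root-to-MRCA path lengths between tip pairs (my); the
#' Brownian-motion trait covariance implied by the tree, up to the rate
#' constant.
#'
#' @inheritParams write_newick
#' @return Square matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_chronogram(tree, check_ultrametric = TRUE)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving tip variances intact.
#' `lambda = 1` keeps the Brownian covariance; `lambda = 0` yields the star
#' phylogeny (phylogenetic independence).
#'
#' @param cov Covariance matrix from [phylo_covariance()].
#' @param lambda Scalar in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(cov, lambda) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a scalar in [0, 1]", call. = FALSE)
  }
  d <- diag(cov)
  out <- cov * lambda
  diag(out) <- d
  out
}

#' Most recent common ancestor of a set of tips
#'
#' @inheritParams node_ages
#' @param tips Character vector of tip labels (>= 2).
#' @return A one-row tibble with the MRCA node index, crown age (MRCA age),
#'   stem age (its parent's age; `NA` with `stem_defined = FALSE` when the
#'   MRCA is the root) and the number of descendant tips.
#' @export
mrca_clade <- function(tree, tips) {
  validate_chronogram(tree, check_ultrametric = TRUE)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0L) {
    stop("tip labels not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(tips) < 2L) stop("need >= 2 tips for an MRCA", call. = FALSE)
  mrca <- ape::getMRCA(tree, tips)
  age <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  stem_defined <- mrca != root
  stem_age <- if (stem_defined) {
    parent <- tree$edge[tree$edge[, 2L] == mrca, 1L]
    unname(age[parent])
  } else NA_real_
  tibble::tibble(
    node = mrca,
    crown_age = unname(age[mrca]),
    stem_age = stem_age,
    stem_defined = stem_defined,
    n_tips = length(ape::extract.clade(tree, mrca)$tip.label)
  )
}

# tips descending from each node, as label list (internal helper)
clade_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  # postorder edge order guarantees children are merged before their parent
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# run code with a temporary RNG state seeded by `seed`, restoring on exit
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}
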