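#' Elevational summary of occurrence records
#'
#' Lower and upper boundaries of the interval containing 95% of the records
#' (2.5th and 97.5th percentiles with linear interpolation) and the
#' arithmetic mean, all in metres.
#'
#' @param records Numeric vector of recorded elevations (m), length >= 1.
#' @return One-row tibble with `lower`, `mean`, `upper`.
#' @examples
#' elevational_summary(c(900))          # single record: 900 [900-900]
#' elevational_summary(0:100)           # [2.5, 97.5], mean 50
#' @export
elevational_summary <- function(records) {
  if (length(records) == 0L) stop("no elevation records", call. = FALSE)
  if (anyNA(records)) stop("NA elevation records", call. = FALSE)
  q <- stats::quantile(records, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(lower = q[1], mean = mean(records), upper = q[2])
}

# lambda/delta-transformed Brownian covariance among tips
transformed_vcv <- function(tree, lambda = 1, delta = 1, base_vcv = NULL) {
  C <- if (is.null(base_vcv)) ape::vcv.phylo(tree) else base_vcv
  T_ <- max(diag(C))
  if (delta != 1) C <- C^delta * T_^(1 - delta)
  if (lambda != 1) C <- lambda_transform(C, lambda)
  C
}

# GLS profile of (root, sigma2) at fixed covariance; returns logL too
profile_bm <- function(V, x) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Vix <- backsolve(ch, forwardsolve(t(ch), x))
  root <- sum(Vi1 * x) / sum(Vi1)
  r <- x - root
  Vir <- Vix - root * Vi1
  s2 <- sum(r * Vir) / n
  if (s2 < 0) s2 <- 0
  logL <- if (s2 == 0) -Inf else {
    -0.5 * n * (log(2 * pi) + 1 + log(s2)) - 0.5 * logdet
  }
  list(root = root, sigma2 = s2, logL = logL, chol = ch, logdet = logdet)
}

#' Brownian-motion log-likelihood with Pagel lambda/delta scaling
#'
#' Multivariate-normal likelihood of tip values with mean `root_state` and
#' covariance `sigma2` times the lambda/delta-transformed phylogenetic
#' covariance. `method = "dense"` evaluates the MVN density directly from the
#' covariance matrix; `method = "pruning"` uses Felsenstein's contrasts
#' algorithm on the transformed tree — the two agree to numerical precision
#' and serve as mutual checks.
#'
#' @inheritParams mrca_clade
#' @param trait Named numeric vector of tip values (m), names = tip labels.
#' @param sigma2 Brownian rate (m^2/my), > 0.
#' @param root_state Root value (m).
#' @param lambda,delta Pagel scaling parameters.
#' @param method `"dense"` or `"pruning"`.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, trait, sigma2, root_state, lambda = 1, delta = 1,
                      method = c("dense", "pruning")) {
  method <- match.arg(method)
  x <- check_trait(tree, trait)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  n <- length(x)
  if (method == "dense") {
    V <- transformed_vcv(tree, lambda, delta) * sigma2
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      stop("singular trait covariance (duplicate zero-length tips?); ",
           "consider jittering tip branch lengths", call. = FALSE)
    }
    r <- x - root_state
    z <- forwardsolve(t(ch), r)
    -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
  } else {
    tr <- lambda_tree(delta_transform_safe(tree, delta), lambda)
    bm_prune_loglik(tr, x, sigma2, root_state)
  }
}

check_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait vector must be named by tip label", call. = FALSE)
  if (anyNA(trait) || any(!is.finite(trait))) stop("non-finite trait values", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0L) {
    stop("trait values missing for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trait[tree$tip.label]
}

delta_transform_safe <- function(tree, delta) {
  if (delta == 1) tree else delta_transform(tree, delta)
}

# branch-level lambda transform: internal branches scaled by lambda, tip
# branches extended to preserve tip depth (exact for ultrametric trees)
lambda_tree <- function(tree, lambda) {
  if (lambda == 1) return(tree)
  depth <- ape::node.depth.edgelength(tree)
  n <- ape::Ntip(tree)
  T_ <- max(depth[seq_len(n)])
  new_depth <- depth * lambda
  new_depth[seq_len(n)] <- T_
  out <- tree
  out$edge.length <- new_depth[tree$edge[, 2L]] - new_depth[tree$edge[, 1L]]
  out
}

# Felsenstein pruning: exact BM log-likelihood for fixed (sigma2, root)
bm_prune_loglik <- function(tree, x, sigma2, root_state) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  val <- numeric(nn); extra <- numeric(nn)
  val[seq_len(n)] <- x
  blen <- numeric(nn)
  blen[tree$edge[, 2L]] <- tree$edge.length
  logL <- 0
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (v in unique(tree$edge[ape::postorder(tree), 1L])) {
    ch <- kids[[as.character(v)]]
    if (length(ch) != 2L) stop("pruning likelihood requires a binary tree", call. = FALSE)
    v1 <- extra[ch[1]] + blen[ch[1]]
    v2 <- extra[ch[2]] + blen[ch[2]]
    contrast <- val[ch[1]] - val[ch[2]]
    logL <- logL + stats::dnorm(contrast, 0, sqrt(sigma2 * (v1 + v2)), log = TRUE)
    val[v] <- (val[ch[1]] / v1 + val[ch[2]] / v2) / (1 / v1 + 1 / v2)
    extra[v] <- v1 * v2 / (v1 + v2)
  }
  root <- n + 1L
  logL + stats::dnorm(val[root], root_state, sqrt(sigma2 * extra[root]), log = TRUE)
}

#' Joint maximum-likelihood fit of Pagel's lambda and delta
#'
#' Profiles the Brownian rate and root state analytically at each
#' `(lambda, delta)` and maximizes over the free scaling parameters with a
#' bounded grid-plus-quasi-Newton search (`lambda` in `[0, 1]`, `delta` in
#' `[1e-5, delta_max]`). Likelihood-ratio tests against `delta = 1` and
#' `lambda = 1` (one fixed parameter each, chi-square with 1 df) are attached
#' for the parameters being estimated.
#'
#' @inheritParams bm_loglik
#' @param free Character subset of `c("lambda", "delta")` to estimate;
#'   the others are fixed at 1.
#' @param delta_max Upper bound for delta (default 3).
#' @param seed Integer seed (start-point jitter; the search is deterministic
#'   given the seed).
#' @param tests Compute the LRTs against `delta = 1` / `lambda = 1`
#'   (default `TRUE`; skipping saves two constrained refits).
#' @param trait_name Optional label carried into reports.
#' @return Object of class `trait_fit`: ML `lambda`, `delta`, `sigma2`,
#'   `root_state`, `logL`, LRT statistics/p-values, and bound flags.
#' @export
fit_trait_model <- function(tree, trait, free = c("lambda", "delta"),
                            delta_max = 3, seed = 1L, tests = TRUE,
                            trait_name = NULL) {
  x <- check_trait(tree, trait)
  if (stats::sd(x) == 0) stop("trait is constant: zero variance", call. = FALSE)
  if (length(free) > 0L) {
    free <- match.arg(free, c("lambda", "delta"), several.ok = TRUE)
  }
  C0 <- ape::vcv.phylo(tree)
  obj <- function(lambda, delta) {
    V <- transformed_vcv(tree, lambda, delta, base_vcv = C0)
    p <- profile_bm(V, x)
    if (is.null(p)) return(NULL)
    p
  }
  opt_free <- function(free_now) {
    lam_fixed <- !("lambda" %in% free_now)
    del_fixed <- !("delta" %in% free_now)
    par_of <- function(p) {
      lam <- if (lam_fixed) 1 else p[["lambda"]]
      del <- if (del_fixed) 1 else p[["delta"]]
      c(lambda = lam, delta = del)
    }
    nll <- function(p) {
      q <- par_of(as.list(p))
      pr <- obj(q[["lambda"]], q[["delta"]])
      if (is.null(pr) || !is.finite(pr$logL)) return(1e10)
      -pr$logL
    }
    if (length(free_now) == 0L) {
      pr <- obj(1, 1)
      return(list(lambda = 1, delta = 1, logL = pr$logL,
                  sigma2 = pr$sigma2, root = pr$root))
    }
    lo <- c(lambda = 0, delta = 1e-5)[free_now]
    hi <- c(lambda = 1, delta = delta_max)[free_now]
    grid <- with_seed(seed, {
      g <- expand.grid(lambda = seq(0.05, 1, length.out = 5),
                       delta = exp(seq(log(0.1), log(delta_max), length.out = 5)))
      g
    })
    if (!("lambda" %in% free_now)) grid$lambda <- 1
    if (!("delta" %in% free_now)) grid$delta <- 1
    grid <- unique(grid[free_now])
    gval <- apply(grid, 1L, function(r) {
      p <- as.list(r); names(p) <- free_now
      nll(unlist(p))
    })
    starts <- grid[order(gval)[seq_len(min(3L, nrow(grid)))], , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      p0 <- unlist(starts[i, free_now])
      names(p0) <- free_now
      r <- tryCatch(
        stats::optim(p0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e7)),
        error = function(e) NULL
      )
      if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
    }
    if (is.null(best)) stop("trait model optimization failed", call. = FALSE)
    q <- par_of(as.list(best$par))
    pr <- obj(q[["lambda"]], q[["delta"]])
    list(lambda = unname(q[["lambda"]]), delta = unname(q[["delta"]]),
         logL = pr$logL, sigma2 = pr$sigma2, root = pr$root)
  }
  full <- opt_free(free)
  lrt_delta <- lrt_lambda <- NULL
  if (tests && "delta" %in% free) {
    null_d <- opt_free(setdiff(free, "delta"))
    lrt_delta <- lrt_chi2(full$logL, null_d$logL, df = 1L)
  }
  if (tests && "lambda" %in% free) {
    null_l <- opt_free(setdiff(free, "lambda"))
    lrt_lambda <- lrt_chi2(full$logL, null_l$logL, df = 1L)
  }
  structure(list(
    trait_name = trait_name %||% "trait",
    lambda = full$lambda, delta = full$delta,
    sigma2 = full$sigma2, root_state = full$root, logL = full$logL,
    free = free, delta_max = delta_max,
    delta_at_bound = isTRUE(abs(full$delta - delta_max) < 1e-6),
    lrt_delta = lrt_delta, lrt_lambda = lrt_lambda,
    n_tips = ape::Ntip(tree), seed = seed
  ), class = "trait_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Pagel lambda/delta fit (%s, %d tips)\n", x$trait_name, x$n_tips))
  cat(sprintf("  lambda = %.3f   delta = %.3f%s\n", x$lambda, x$delta,
              if (x$delta_at_bound) " (at bound)" else ""))
  cat(sprintf("  sigma2 = %.4g   root = %.1f   logL = %.3f\n",
              x$sigma2, x$root_state, x$logL))
  if (!is.null(x$lrt_delta)) {
    cat(sprintf("  LRT delta=1 : %.3f (p = %.3f)\n",
                x$lrt_delta$statistic, x$lrt_delta$p_value))
  }
  if (!is.null(x$lrt_lambda)) {
    cat(sprintf("  LRT lambda=1: %.3f (p = %.3f)\n",
                x$lrt_lambda$statistic, x$lrt_lambda$p_value))
  }
  invisible(x)
}

#' @export
tidy.trait_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "delta", "sigma2", "root_state"),
    estimate = c(x$lambda, x$delta, x$sigma2, x$root_state)
  )
}

#' @export
glance.trait_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logL, n_tips = x$n_tips,
    lrt_delta = x$lrt_delta$statistic %||% NA_real_,
    p_delta = x$lrt_delta$p_value %||% NA_real_,
    lrt_lambda = x$lrt_lambda$statistic %||% NA_real_,
    p_lambda = x$lrt_lambda$p_value %||% NA_real_,
    delta_at_bound = x$delta_at_bound
  )
}

#' Likelihood-ratio test against a chi-square reference
#'
#' `LRT = 2 (logL_free - logL_constrained)`, clamped at zero; the p-value is
#' the upper chi-square tail with `df` degrees of freedom (no boundary
#' mixture correction).
#'
#' @param logL_free,logL_constrained Log-likelihoods of the nested pair.
#' @param df Degrees of freedom (>= 1).
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' lrt_chi2(-10, -12.58, 1) # LRT 5.16, p 0.023
#' @export
lrt_chi2 <- function(logL_free, logL_constrained, df = 1L) {
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  if (logL_free < logL_constrained - 1e-6) {
    stop("logL_free below logL_constrained: not a nested comparison", call. = FALSE)
  }
  stat <- max(0, 2 * (logL_free - logL_constrained))
  list(statistic = stat, df = as.integer(df),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Rescale the tree by fitted lambda/delta and reconstruct ancestral values
#'
#' The tree is rescaled with the fitted delta (node-depth exponent) and
#' lambda (internal-branch shrinkage) and ancestral node values are
#' reconstructed by generalized-least-squares (BLUP) prediction under
#' Brownian motion with the GLS root estimate; prediction variances account
#' for root-estimation uncertainty, so they are zero at tips and grow toward
#' the root. By default a scaling parameter is applied only when its LRT is
#' significant at `alpha` (otherwise it is left at 1), mirroring a rescale-
#' only-when-supported workflow; set `apply = "always"` or `"never"` to
#' override.
#'
#' @inheritParams bm_loglik
#' @param fit A `trait_fit` from [fit_trait_model()].
#' @param apply `"significant"` (default), `"always"`, or `"never"`.
#' @param alpha Significance level for the rescaling decision.
#' @return Tibble (class `ancestral_trait`): `node`, `label`, `is_tip`,
#'   `age`, `mean` (m), `variance` (m^2); attributes carry the applied
#'   `lambda`/`delta`.
#' @export
rescale_and_reconstruct <- function(tree, trait, fit = NULL,
                                    apply = c("significant", "always", "never"),
                                    alpha = 0.05) {
  apply <- match.arg(apply)
  x <- check_trait(tree, trait)
  lam <- del <- 1
  if (!is.null(fit) && apply != "never") {
    use_l <- apply == "always" ||
      (!is.null(fit$lrt_lambda) && fit$lrt_lambda$p_value < alpha)
    use_d <- apply == "always" ||
      (!is.null(fit$lrt_delta) && fit$lrt_delta$p_value < alpha)
    if (use_l) lam <- fit$lambda
    if (use_d) del <- fit$delta
  }
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  T_ <- max(depth[seq_len(n)])
  ddepth <- depth^del * T_^(1 - del)
  # shared transformed depth between any two nodes = transformed depth of
  # their MRCA, shrunk by lambda for all internal ancestry; tip variances stay T
  mrca_all <- ape::mrca(tree, full = TRUE)
  M <- matrix(lam * ddepth[mrca_all], nn, nn)
  diag(M) <- lam * ddepth
  diag(M)[seq_len(n)] <- T_
  tipV <- M[seq_len(n), seq_len(n), drop = FALSE]
  # tip-tip off-diagonals already carry lambda; ensure exact tip variances
  pr <- profile_bm(tipV, x)
  if (is.null(pr)) stop("singular covariance in reconstruction", call. = FALSE)
  ch <- pr$chol
  solveV <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  Vi1 <- solveV(rep(1, n))
  s11 <- sum(Vi1)
  r <- x - pr$root
  Vir <- solveV(r)
  nodes <- seq_len(nn)
  Cnt <- M[nodes, seq_len(n), drop = FALSE]
  mean_hat <- pr$root + as.numeric(Cnt %*% Vir)
  ViC <- solveV(t(Cnt))
  quad <- colSums(t(Cnt) * ViC)
  one_term <- (1 - as.numeric(Cnt %*% Vi1))^2 / s11
  var_hat <- pr$sigma2 * (diag(M) - quad + one_term)
  var_hat[var_hat < 0] <- 0
  out <- tibble::tibble(
    node = nodes,
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    is_tip = nodes <= n,
    age = unname(node_ages(tree)[nodes]),
    mean = mean_hat,
    variance = var_hat
  )
  attr(out, "lambda_applied") <- lam
  attr(out, "delta_applied") <- del
  attr(out, "root_estimate") <- pr$root
  attr(out, "sigma2") <- pr$sigma2
  class(out) <- c("ancestral_trait", class(out))
  out
}

#' Summarize lambda/delta fits across a posterior sample of trees
#'
#' @param fits List of `trait_fit` objects for the same trait.
#' @return One-row tibble: mean and sd of delta, lambda and the delta-LRT,
#'   mean p-value, and the percentage of trees with `p < 0.05`.
#' @export
summarize_over_trees <- function(fits) {
  if (length(fits) == 0L) stop("no fits to summarize", call. = FALSE)
  g <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      delta = f$delta, lambda = f$lambda,
      lrt = f$lrt_delta$statistic %||% NA_real_,
      p = f$lrt_delta$p_value %||% NA_real_
    )
  })
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  tibble::tibble(
    n_trees = nrow(g),
    delta_mean = mean(g$delta), delta_sd = sd0(g$delta),
    lambda_mean = mean(g$lambda), lambda_sd = sd0(g$lambda),
    lrt_mean = mean(g$lrt), lrt_sd = sd0(g$lrt),
    p_mean = mean(g$p), p_sd = sd0(g$p),
    pct_significant = 100 * mean(g$p < 0.05)
  )
}

#' Plot an ancestral elevational reconstruction against node age
#'
#' @param object An `ancestral_trait` tibble from [rescale_and_reconstruct()].
#' @param ... Unused.
#' @return A ggplot object: node means with +/- 1 SD ribbons over age.
#' @export
autoplot.ancestral_trait <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$sd <- sqrt(df$variance)
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$age, y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
                   colour = .data$is_tip),
      linewidth = 0.3, size = 0.3
    ) +
    ggplot2::scale_x_continuous(labels = function(v) -v) +
    ggplot2::labs(x = "age (my before present)", y = "elevation (m)",
                  colour = "tip") +
    ggplot2::theme_minimal()
}
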