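#' The six canonical time-dependent birth-death model specifications
#'
#' Speciation and extinction rates are exponential functions of time measured
#' backward from the present: `lambda(t) = lambda0 * exp(alpha t)`,
#' `mu(t) = mu0 * exp(beta t)`. The six models are BCST (constant pure
#' birth), BVAR (time-varying speciation, no extinction), BCST-DCST,
#' BVAR-DCST, BCST-DVAR and BVAR-DVAR; free-parameter counts are 1, 2, 2, 3,
#' 3 and 4.
#'
#' @return Tibble with columns `model`, `lambda_var`, `mu_present`, `mu_var`,
#'   `k`.
#' @export
bd_model_specs <- function() {
  tibble::tibble(
    model = c("BCST", "BVAR", "BCST-DCST", "BVAR-DCST", "BCST-DVAR", "BVAR-DVAR"),
    lambda_var = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    mu_present = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    mu_var = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    k = c(1L, 2L, 2L, 3L, 3L, 4L)
  )
}

#' Evaluate a birth-death rate function through time
#'
#' @param lambda0,alpha,mu0,beta Rate-at-present and exponential time
#'   coefficients (`t` in my before present).
#' @param t Non-negative time(s) before present.
#' @param which `"speciation"` or `"extinction"`.
#' @return Rate(s) in events/lineage/my.
#' @examples
#' rate_at(0.161, 0.110, t = 10) # 0.161 * exp(1.10)
#' @export
rate_at <- function(lambda0, alpha = 0, mu0 = 0, beta = 0, t,
                    which = c("speciation", "extinction")) {
  which <- match.arg(which)
  if (any(t < 0)) stop("t must be >= 0 (my before present)", call. = FALSE)
  if (which == "speciation") lambda0 * exp(alpha * t) else mu0 * exp(beta * t)
}

# integral of (lambda - mu) from 0 to t (vectorized, exact for exponentials)
bd_rho <- function(t, lambda0, alpha, mu0, beta) {
  lam_part <- if (alpha == 0) lambda0 * t else lambda0 * (exp(alpha * t) - 1) / alpha
  mu_part <- if (beta == 0) mu0 * t else mu0 * (exp(beta * t) - 1) / beta
  lam_part - mu_part
}

# J(t) = integral_0^t lambda(s) exp(rho(s)) ds, vectorized over t.
# Closed forms when mu0 = 0 (J = exp(rho) - 1) or both rates constant;
# otherwise fixed-order Gauss-Legendre (48 nodes per time, smooth integrand),
# with stats::integrate available through quadrature = "adaptive".
bd_J <- function(t, lambda0, alpha, mu0, beta, quadrature = "gauss") {
  if (mu0 == 0) {
    return(expm1(bd_rho(t, lambda0, alpha, 0, 0)))
  }
  if (alpha == 0 && beta == 0) {
    r <- lambda0 - mu0
    if (abs(r) < 1e-12) return(lambda0 * t)
    return(lambda0 * (exp(r * t) - 1) / r)
  }
  g <- function(s) lambda0 * exp(alpha * s + bd_rho(s, lambda0, alpha, mu0, beta))
  if (quadrature == "adaptive") {
    return(vapply(t, function(ti) {
      if (ti == 0) return(0)
      stats::integrate(g, 0, ti, abs.tol = 1e-8, rel.tol = 1e-10)$value
    }, numeric(1)))
  }
  gl <- gauss_nodes_48()
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    s <- ti / 2 * (gl$x + 1)
    ti / 2 * sum(gl$w * g(s))
  }, numeric(1))
}

gauss_cache <- new.env(parent = emptyenv())
gauss_nodes_48 <- function() {
  if (is.null(gauss_cache$gl)) {
    gl <- pracma::gaussLegendre(48, -1, 1)
    gauss_cache$gl <- list(x = gl$x, w = gl$w)
  }
  gauss_cache$gl
}

# log p1(t): probability density that a lineage at time t is represented by
# exactly one sampled lineage at present (sampling fraction f)
bd_log_p1 <- function(t, lambda0, alpha, mu0, beta, f, quadrature = "gauss") {
  rho <- bd_rho(t, lambda0, alpha, mu0, beta)
  J <- bd_J(t, lambda0, alpha, mu0, beta, quadrature)
  out <- rho - 2 * log1p(f * J) + log(f)
  big <- !is.finite(J) | f * J > 1e300
  if (any(big)) {
    # asymptotic regime: log(1 + fJ) ~ log f + log J; recompute in log space
    out[big] <- -Inf
  }
  out
}

# log P(t): probability that a lineage at time t has sampled descendants
bd_log_surv <- function(t, lambda0, alpha, mu0, beta, f, quadrature = "gauss") {
  rho <- bd_rho(t, lambda0, alpha, mu0, beta)
  J <- bd_J(t, lambda0, alpha, mu0, beta, quadrature)
  rho - log(1 / f + J)
}

#' Time-dependent birth-death log-likelihood of branching times
#'
#' Crown-conditioned likelihood of a completely-sampled-to-fraction-`f`
#' reconstructed tree under exponential time-dependence of speciation and
#' extinction, with the root (crown) speciation term excluded. The two crown
#' lineages and every later branching each contribute a single-lineage
#' propagation term; inner time integrals use closed forms where they exist
#' (pure birth, constant rates) and fixed-order Gauss-Legendre quadrature
#' otherwise (`quadrature = "adaptive"` switches to [stats::integrate()]).
#'
#' @param branching_times Descending internal-node ages (crown age first),
#'   e.g. from [branching_times()].
#' @inheritParams rate_at
#' @param f Sampling fraction in `(0, 1]`.
#' @param condition_survival Also condition on both crown lineages having
#'   sampled descendants (default `FALSE`).
#' @param quadrature `"gauss"` (default) or `"adaptive"`.
#' @return Log-likelihood (scalar; `-Inf` for numerically impossible
#'   parameters).
#' @export
bd_loglik <- function(branching_times, lambda0, alpha = 0, mu0 = 0, beta = 0,
                      f = 1, condition_survival = FALSE, quadrature = "gauss") {
  bt <- branching_times
  if (length(bt) < 1L || is.unsorted(rev(bt), strictly = FALSE)) {
    stop("branching times must be in descending order, crown age first",
         call. = FALSE)
  }
  if (f <= 0 || f > 1) stop("sampling fraction f must be in (0, 1]", call. = FALSE)
  if (lambda0 <= 0 || mu0 < 0) return(-Inf)
  crown <- bt[1]
  lp1 <- bd_log_p1(bt, lambda0, alpha, mu0, beta, f, quadrature)
  if (any(!is.finite(lp1))) return(-Inf)
  ll <- 2 * lp1[1]
  if (length(bt) > 1L) {
    ll <- ll + sum(log(lambda0) + alpha * bt[-1] + lp1[-1])
  }
  if (condition_survival) {
    ll <- ll - 2 * bd_log_surv(crown, lambda0, alpha, mu0, beta, f, quadrature)
  }
  ll
}

bd_par_layout <- function(spec) {
  nm <- "log_lambda0"
  if (spec$lambda_var) nm <- c(nm, "alpha")
  if (spec$mu_present) nm <- c(nm, "mu0")
  if (spec$mu_var) nm <- c(nm, "beta")
  nm
}

bd_unpack <- function(par, layout) {
  p <- c(lambda0 = exp(unname(par[match("log_lambda0", layout)])),
         alpha = 0, mu0 = 0, beta = 0)
  if ("alpha" %in% layout) p["alpha"] <- par[match("alpha", layout)]
  if ("mu0" %in% layout) p["mu0"] <- par[match("mu0", layout)]
  if ("beta" %in% layout) p["beta"] <- par[match("beta", layout)]
  p
}

fit_one_bd <- function(bt, spec, f, n_starts, seed, condition_survival) {
  layout <- bd_par_layout(spec)
  lo <- c(log_lambda0 = log(1e-4), alpha = -2, mu0 = 0, beta = -2)[layout]
  hi <- c(log_lambda0 = log(10), alpha = 2, mu0 = 10, beta = 2)[layout]
  nll <- function(par) {
    p <- bd_unpack(par, layout)
    ll <- bd_loglik(bt, p["lambda0"], p["alpha"], p["mu0"], p["beta"],
                    f = f, condition_survival = condition_survival)
    if (!is.finite(ll)) 1e10 else -ll
  }
  n <- length(bt) + 1L
  lam_guess <- max(5e-4, min(5, (log(n) - log(2)) / bt[1]))
  det_start <- c(log_lambda0 = log(lam_guess), alpha = 0.01, mu0 = 0.01,
                 beta = 0.01)[layout]
  starts <- with_seed(seed, {
    rand <- replicate(max(0L, n_starts - 1L), {
      c(log_lambda0 = stats::runif(1, log(5e-3), log(1)),
        alpha = stats::runif(1, -0.5, 0.5),
        mu0 = stats::runif(1, 0, 0.5),
        beta = stats::runif(1, -0.5, 0.5))[layout]
    }, simplify = FALSE)
    c(list(det_start), rand)
  })
  best <- NULL
  for (s0 in starts) {
    r <- tryCatch(
      stats::optim(s0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e7, maxit = 300)),
      error = function(e) NULL
    )
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  if (is.null(best)) stop("birth-death optimizer failed for ", spec$model, call. = FALSE)
  p <- bd_unpack(best$par, layout)
  list(model = spec$model, k = spec$k,
       lambda0 = unname(p["lambda0"]), alpha = unname(p["alpha"]),
       mu0 = unname(p["mu0"]), beta = unname(p["beta"]),
       logL = -best$value, par = best$par, layout = layout)
}

# embed a nested model's solution as a warm start for its superset
bd_nestings <- function() {
  list(
    "BVAR" = "BCST",
    "BCST-DCST" = "BCST",
    "BVAR-DCST" = c("BVAR", "BCST-DCST"),
    "BCST-DVAR" = "BCST-DCST",
    "BVAR-DVAR" = c("BVAR-DCST", "BCST-DVAR")
  )
}

#' Fit the six time-dependent diversification models and rank them by AIC
#'
#' Bounded multi-start ML per model (`lambda0` in `[1e-4, 10]` on the log
#' scale, `mu0` in `[0, 10]`, `alpha`/`beta` in `[-2, 2]`), warm-starting
#' each model from the solutions of its nested sub-models so that a superset
#' never scores below a model it contains. Models are ranked by ascending
#' `AIC = 2k - 2 logL`; the best model is flagged `supported` when every
#' rival has `dAIC > 2`.
#'
#' @param tree A chronogram (`phylo`), or `NULL` if `branching_times` given.
#' @inheritParams bd_loglik
#' @param specs Model table from [bd_model_specs()] (subset allowed).
#' @param n_starts Optimizer starts per model (default 8).
#' @param seed Integer seed for the random starts.
#' @return Object of class `bd_fit_set`: ranked tibble in `$table`
#'   (model, k, logL, AIC, dAIC, lambda0, alpha, mu0, beta), per-model fits
#'   in `$fits`, crown age and tip count.
#' @export
fit_bd_models <- function(tree = NULL, branching_times = NULL,
                          specs = bd_model_specs(), f = 1,
                          n_starts = 8L, seed = 1L,
                          condition_survival = FALSE) {
  bt <- if (is.null(branching_times)) {
    stopifnot(!is.null(tree))
    branching_times(tree)
  } else branching_times
  if (length(bt) < 2L) stop("need >= 3 tips to fit diversification models", call. = FALSE)
  fits <- list()
  for (i in seq_len(nrow(specs))) {
    fits[[specs$model[i]]] <-
      fit_one_bd(bt, specs[i, ], f, n_starts, seed + i, condition_survival)
  }
  # nesting repair: a superset restarted from any better nested solution
  for (pass in 1:2) {
    for (super in names(bd_nestings())) {
      if (is.null(fits[[super]])) next
      for (sub in bd_nestings()[[super]]) {
        if (is.null(fits[[sub]])) next
        if (fits[[sub]]$logL > fits[[super]]$logL + 1e-6) {
          layout <- fits[[super]]$layout
          warm <- c(log_lambda0 = log(fits[[sub]]$lambda0),
                    alpha = fits[[sub]]$alpha, mu0 = max(fits[[sub]]$mu0, 1e-8),
                    beta = fits[[sub]]$beta)[layout]
          lo <- c(log_lambda0 = log(1e-4), alpha = -2, mu0 = 0, beta = -2)[layout]
          hi <- c(log_lambda0 = log(10), alpha = 2, mu0 = 10, beta = 2)[layout]
          nll <- function(par) {
            p <- bd_unpack(par, layout)
            ll <- bd_loglik(bt, p["lambda0"], p["alpha"], p["mu0"], p["beta"],
                            f = f, condition_survival = condition_survival)
            if (!is.finite(ll)) 1e10 else -ll
          }
          r <- tryCatch(
            stats::optim(warm, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                         control = list(factr = 1e7, maxit = 300)),
            error = function(e) NULL
          )
          if (!is.null(r) && -r$value > fits[[super]]$logL) {
            p <- bd_unpack(r$par, layout)
            fits[[super]][c("lambda0", "alpha", "mu0", "beta", "logL")] <-
              list(unname(p["lambda0"]), unname(p["alpha"]), unname(p["mu0"]),
                   unname(p["beta"]), -r$value)
          }
        }
      }
    }
  }
  tab <- purrr::map_dfr(fits, function(ft) {
    tibble::tibble(model = ft$model, k = ft$k, logL = ft$logL,
                   AIC = 2 * ft$k - 2 * ft$logL,
                   lambda0 = ft$lambda0, alpha = ft$alpha,
                   mu0 = ft$mu0, beta = ft$beta)
  })
  tab <- tab[order(tab$AIC, tab$k, tab$lambda0), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab <- tab[, c("model", "k", "logL", "AIC", "dAIC",
                 "lambda0", "alpha", "mu0", "beta")]
  structure(list(
    table = tab, fits = fits, crown_age = bt[1],
    n_tips = length(bt) + 1L, f = f, seed = seed,
    supported = nrow(tab) > 1L && all(tab$dAIC[-1] > 2)
  ), class = "bd_fit_set")
}

#' @export
print.bd_fit_set <- function(x, ...) {
  cat(sprintf("Time-dependent birth-death model selection (%d tips, crown %.2f my)\n",
              x$n_tips, x$crown_age))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  cat(if (x$supported) "Best model supported (all rivals dAIC > 2)\n"
      else "Best model not decisively supported (some rival dAIC <= 2)\n")
  invisible(x)
}

#' @export
tidy.bd_fit_set <- function(x, ...) x$table

#' @export
glance.bd_fit_set <- function(x, ...) {
  tibble::tibble(best_model = x$table$model[1], AIC = x$table$AIC[1],
                 logLik = x$table$logL[1], supported = x$supported,
                 n_tips = x$n_tips, crown_age = x$crown_age)
}

#' Rate-through-time curve of a fitted model
#'
#' @param fit A `bd_fit_set` (its best model is used) or a single model row
#'   name present in the set.
#' @param times Grid of times (my before present); default 101 points from
#'   the present to the crown age.
#' @param model Optional model name to extract instead of the best.
#' @return Tibble (class `rate_curve`): `t`, `speciation`, `extinction`.
#' @export
rate_through_time <- function(fit, times = NULL, model = NULL) {
  stopifnot(inherits(fit, "bd_fit_set"))
  nm <- model %||% fit$table$model[1]
  ft <- fit$fits[[nm]]
  if (is.null(ft)) stop("model not in fit set: ", nm, call. = FALSE)
  if (is.null(times)) times <- seq(0, fit$crown_age, length.out = 101L)
  if (length(times) == 0L) stop("empty time grid", call. = FALSE)
  out <- tibble::tibble(
    t = times,
    speciation = rate_at(ft$lambda0, ft$alpha, t = times),
    extinction = rate_at(mu0 = ft$mu0, beta = ft$beta, t = times,
                         which = "extinction")
  )
  attr(out, "model") <- nm
  class(out) <- c("rate_curve", class(out))
  out
}

#' @rdname rate_through_time
#' @param object A `rate_curve`.
#' @param ... Unused.
#' @export
autoplot.rate_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$t, y = .data$value,
                                   colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(v) -v) +
    ggplot2::labs(x = "time (my before present)",
                  y = "rate (events/lineage/my)",
                  title = attr(object, "model")) +
    ggplot2::theme_minimal()
}

# ---- stepwise clade shift scan ----------------------------------------------

aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  2 * k - 2 * logL + 2 * k * (k + 1) / (n - k - 1)
}

# constant-rate BD fit of a branching-time vector (2 parameters)
fit_const_bd <- function(bt, n_starts = 3L, seed = 1L) {
  spec <- bd_model_specs()[3, ] # BCST-DCST
  fit_one_bd(bt, spec, f = 1, n_starts = n_starts, seed = seed,
             condition_survival = FALSE)
}

# branching times of the tree with a clade collapsed to a single tip
backbone_btimes <- function(tree, clade_tips) {
  keep_one <- clade_tips[1]
  bb <- ape::drop.tip(tree, setdiff(clade_tips, keep_one))
  if (is.null(bb) || ape::Ntip(bb) < 3L) return(NULL)
  branching_times(bb)
}

scan_one_tree <- function(tree, threshold, min_clade_size, n_starts, seed) {
  n <- ape::Ntip(tree)
  sets <- clade_tip_sets(tree)
  ages <- node_ages(tree)
  accepted <- list()
  active_tips <- tree$tip.label
  current_tree <- tree
  repeat {
    base_bt <- branching_times(current_tree)
    n_obs <- length(base_bt)
    base <- fit_const_bd(base_bt, n_starts, seed)
    base_aicc <- aicc(base$logL, 2L, n_obs)
    root <- ape::Ntip(current_tree) + 1L
    candidates <- setdiff(
      (ape::Ntip(current_tree) + 1L):(ape::Ntip(current_tree) + current_tree$Nnode),
      root
    )
    cur_sets <- clade_tip_sets(current_tree)
    best <- NULL
    for (v in candidates) {
      ct <- cur_sets[[v]]
      if (length(ct) < min_clade_size) next
      if (ape::Ntip(current_tree) - length(ct) < max(3L, min_clade_size - 1L)) next
      clade_bt <- branching_times(ape::extract.clade(current_tree, v))
      bb_bt <- backbone_btimes(current_tree, ct)
      if (is.null(bb_bt) || length(clade_bt) < 2L) next
      fc <- fit_const_bd(clade_bt, n_starts, seed + v)
      fb <- fit_const_bd(bb_bt, n_starts, seed + v + 1L)
      shift_aicc <- aicc(fc$logL + fb$logL, 5L, n_obs)
      gain <- base_aicc - shift_aicc
      if (gain >= threshold && (is.null(best) || gain > best$gain)) {
        best <- list(gain = gain, tips = ct,
                     clade_lambda = fc$lambda0, clade_mu = fc$mu0,
                     bg_lambda = fb$lambda0, bg_mu = fb$mu0,
                     age = unname(node_ages(current_tree)[v]))
      }
    }
    if (is.null(best)) break
    accepted[[length(accepted) + 1L]] <- best
    # collapse the accepted clade and keep scanning the remainder
    nt <- ape::Ntip(current_tree)
    if (nt - length(best$tips) + 1L < 2L * min_clade_size + 1L) break
    current_tree <- ape::drop.tip(current_tree, setdiff(best$tips, best$tips[1]))
    if (is.null(current_tree) || ape::Ntip(current_tree) < 2L * min_clade_size) break
  }
  accepted
}

#' Stepwise clade rate-shift scan with a posterior-frequency rule
#'
#' Per tree: fit a homogeneous constant-rate birth-death model; for every
#' internal node whose clade (and remaining backbone) is large enough, fit a
#' two-regime model (the clade gets its own speciation and extinction rate,
#' plus one parameter for the shift location) and accept the best shift if
#' AICc improves by at least `threshold`; repeat on the remainder until no
#' shift is accepted. Across trees, shift locations are matched by tip-set
#' Jaccard similarity >= 0.9 and a location is significant only when found
#' in at least `min_fraction` of the trees.
#'
#' @param trees A list of chronograms (or a single `phylo`).
#' @param threshold Required AICc improvement (> 0, default 4).
#' @param min_fraction Fraction of trees required for significance
#'   (default 0.05).
#' @param min_clade_size Smallest clade considered (default 5 tips).
#' @param n_starts Optimizer starts per regime fit (default 3).
#' @param seed Integer seed.
#' @return Object of class `shift_scan`: `$per_tree` (list of accepted
#'   shifts), `$locations` (tibble: representative tips, `n_trees`,
#'   `frequency`, `significant`), `$n_trees`.
#' @export
shift_scan <- function(trees, threshold = 4, min_fraction = 0.05,
                       min_clade_size = 5L, n_starts = 3L, seed = 1L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  per_tree <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    per_tree[[i]] <- scan_one_tree(trees[[i]], threshold, min_clade_size,
                                   n_starts, seed + 1000L * i)
  }
  locations <- shift_location_frequencies(
    lapply(per_tree, function(sh) lapply(sh, `[[`, "tips")),
    n_trees = length(trees), min_fraction = min_fraction
  )
  structure(list(per_tree = per_tree, locations = locations,
                 n_trees = length(trees), threshold = threshold,
                 min_fraction = min_fraction),
            class = "shift_scan")
}

#' Match shift locations across trees and apply the frequency rule
#'
#' @param tip_sets_per_tree List (one element per tree) of lists of tip-label
#'   vectors, each the clade of one accepted shift.
#' @param n_trees Total number of trees scanned.
#' @param min_fraction Significance threshold on the across-tree frequency.
#' @param jaccard Minimum Jaccard similarity for two tip sets to be the same
#'   location (default 0.9).
#' @return Tibble: `location` (representative tip set, comma-separated),
#'   `n_trees_with_shift`, `frequency`, `significant`.
#' @export
shift_location_frequencies <- function(tip_sets_per_tree, n_trees,
                                       min_fraction = 0.05, jaccard = 0.9) {
  reps <- list(); count <- integer(0)
  for (tree_sets in tip_sets_per_tree) {
    seen <- logical(length(reps))
    for (ts in tree_sets) {
      matched <- FALSE
      for (j in seq_along(reps)) {
        jac <- length(intersect(ts, reps[[j]])) / length(union(ts, reps[[j]]))
        if (jac >= jaccard) {
          if (!seen[j]) { count[j] <- count[j] + 1L; seen[j] <- TRUE }
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        reps[[length(reps) + 1L]] <- ts
        count <- c(count, 1L)
        seen <- c(seen, TRUE)
      }
    }
  }
  if (length(reps) == 0L) {
    return(tibble::tibble(location = character(0),
                          n_trees_with_shift = integer(0),
                          frequency = numeric(0), significant = logical(0)))
  }
  freq <- count / n_trees
  tibble::tibble(
    location = vapply(reps, function(ts) paste(sort(ts), collapse = ","),
                      character(1)),
    n_trees_with_shift = count,
    frequency = freq,
    significant = freq >= min_fraction
  )
}

#' @export
print.shift_scan <- function(x, ...) {
  cat(sprintf("Stepwise shift scan over %d tree(s), AICc threshold %.1f\n",
              x$n_trees, x$threshold))
  sig <- x$locations[x$locations$significant, ]
  if (nrow(sig) == 0L) {
    cat(sprintf("No significant shift (frequency rule: >= %.0f%% of trees)\n",
                100 * x$min_fraction))
  } else {
    cat(sprintf("%d significant shift location(s):\n", nrow(sig)))
    print(as.data.frame(sig), row.names = FALSE)
  }
  invisible(x)
}
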