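test_that("elevational summaries follow the percentile definition", {
  one <- elevational_summary(900)
  expect_equal(unlist(one), c(lower = 900, mean = 900, upper = 900))
  rng <- elevational_summary(0:100)
  expect_equal(unlist(rng), c(lower = 2.5, mean = 50, upper = 97.5))
  same <- elevational_summary(rep(1200, 7))
  expect_equal(unlist(same), c(lower = 1200, mean = 1200, upper = 1200))
  expect_error(elevational_summary(numeric(0)), "record")
})

test_that("BM likelihood matches closed forms and the dense oracle", {
  ch <- tree_cherry()
  # two independent standard normals
  expect_equal(bm_loglik(ch, c(A = 0, B = 0), 1, 0), -log(2 * pi))
  # doubling sigma2 with tips at the root value costs (n/2) log 2
  tr <- tree3()
  x <- c(A = 5, B = 5, C = 5)
  expect_equal(bm_loglik(tr, x, 2, 5) - bm_loglik(tr, x, 1, 5),
               -1.5 * log(2))
  # lambda = 0 is iid normals with variance sigma2 * depth
  xs <- c(A = 1, B = -2, C = 0.5)
  iid <- sum(dnorm(xs, 0, sqrt(2 * 3), log = TRUE))
  expect_equal(bm_loglik(tr, xs, 3, 0, lambda = 0), iid)
  # independent dense construction
  expect_equal(bm_loglik(tr, xs, 1.7, 0.3),
               oracle_bm_dense(tr, xs, 1.7, 0.3), tolerance = 1e-10)
})

test_that("dense and pruning evaluations agree on random trees and transforms", {
  for (seed in 1:100) {
    tr <- simulate_bd_tree(0.4, n_tips = sample(5:50, 1), seed = 2000 + seed)
    x <- simulate_bm_trait(tr, sigma2 = 2, root_state = 10,
                           seed = 3000 + seed)
    lam <- runif(1, 0.2, 1)
    del <- runif(1, 0.3, 2.5)
    dense <- bm_loglik(tr, x, 1.3, 9, lambda = lam, delta = del)
    prune <- bm_loglik(tr, x, 1.3, 9, lambda = lam, delta = del,
                       method = "pruning")
    expect_equal(dense, prune, tolerance = 1e-8)
  }
})

test_that("profiled root and rate match closed-form GLS", {
  tr <- tree3()
  x <- c(A = 0, B = 0, C = 3)
  V <- phylo_covariance(tr)
  Vi <- solve(V)
  root <- drop(rep(1, 3) %*% Vi %*% x[rownames(V)]) /
    drop(rep(1, 3) %*% Vi %*% rep(1, 3))
  expect_equal(root, 9 / 7)
  r <- x[rownames(V)] - root
  s2 <- drop(r %*% Vi %*% r) / 3
  fit <- fit_trait_model(tr, x, free = character(0))
  expect_equal(fit$root_state, root, tolerance = 1e-8)
  expect_equal(fit$sigma2, s2, tolerance = 1e-8)
})

test_that("lambda-only fit agrees with an independent phylogenetic-signal estimator", {
  skip_if_not_installed("phytools")
  tr <- simulate_bd_tree(0.3, n_tips = 80, seed = 77)
  x <- simulate_bm_trait(tr, 1, 0, lambda = 0.6, seed = 78)
  mine <- fit_trait_model(tr, x, free = "lambda", tests = FALSE)
  ref <- phytools::phylosig(tr, x[tr$tip.label], method = "lambda")
  expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(mine$logL, ref$logL, tolerance = 1e-4)
})

test_that("LRT arithmetic and guardrails", {
  expect_equal(round(lrt_chi2(-10, -12.58, 1)$p_value, 3), 0.023)
  expect_equal(round(lrt_chi2(-10, -11.55, 1)$p_value, 3), 0.078)
  expect_equal(lrt_chi2(-5, -5, 1)$p_value, 1)
  expect_error(lrt_chi2(-5, -4, 1), "nested")
  expect_error(lrt_chi2(-5, -6, 0), "df")
})

test_that("fixing a parameter never increases the likelihood; bounds are honoured", {
  tr <- simulate_bd_tree(0.3, n_tips = 60, seed = 42)
  x <- simulate_bm_trait(tr, 2, 0, delta = 2.5, seed = 43)
  full <- fit_trait_model(tr, x)
  only_l <- fit_trait_model(tr, x, free = "lambda", tests = FALSE)
  only_d <- fit_trait_model(tr, x, free = "delta", tests = FALSE)
  expect_gte(full$logL + 1e-6, only_l$logL)
  expect_gte(full$logL + 1e-6, only_d$logL)
  expect_lte(full$delta, 3)
  expect_gte(full$lrt_delta$statistic, 0)
  expect_error(fit_trait_model(tr, stats::setNames(rep(1, 60), tr$tip.label)),
               "constant")
})

test_that("reconstruction honours observations, GLS root, and variance growth", {
  tr <- tree3()
  x <- c(A = 0, B = 0, C = 3)
  rec <- rescale_and_reconstruct(tr, x)
  expect_equal(rec$mean[1:3], unname(x[tr$tip.label]))
  expect_equal(rec$variance[1:3], rep(0, 3), tolerance = 1e-10)
  expect_equal(rec$mean[4], 9 / 7, tolerance = 1e-8) # GLS root
  expect_gt(rec$variance[4], 0)

  # equal tips reconstruct flat; the profiled rate (hence all prediction
  # variances) degenerates to zero for a constant trait
  xeq <- c(A = 7, B = 7, C = 7)
  receq <- rescale_and_reconstruct(tr, xeq, fit = NULL)
  expect_equal(receq$mean, rep(7, 5))
  expect_equal(receq$variance, rep(0, 5))

  # variance increases from tips toward the root along each path
  trs <- simulate_bd_tree(0.3, n_tips = 30, seed = 9)
  xs <- simulate_bm_trait(trs, 1, 0, seed = 10)
  rec2 <- rescale_and_reconstruct(trs, xs)
  for (e in seq_len(nrow(trs$edge))) {
    p <- trs$edge[e, 1]; chld <- trs$edge[e, 2]
    expect_gte(rec2$variance[p] + 1e-10, rec2$variance[chld])
  }

  # reconstruction is invariant under tip reordering
  perm <- sample(names(xs))
  rec3 <- rescale_and_reconstruct(trs, xs[perm])
  expect_equal(rec2$mean, rec3$mean, tolerance = 1e-10)
})

test_that("rescaling applies fitted parameters only when supported", {
  tr <- simulate_bd_tree(0.3, n_tips = 60, seed = 42)
  x <- simulate_bm_trait(tr, 2, 0, delta = 2.5, seed = 43)
  fit <- fit_trait_model(tr, x)
  rec_always <- rescale_and_reconstruct(tr, x, fit, apply = "always")
  rec_never <- rescale_and_reconstruct(tr, x, fit, apply = "never")
  expect_equal(attr(rec_always, "delta_applied"), fit$delta)
  expect_equal(attr(rec_never, "delta_applied"), 1)
  rec_sig <- rescale_and_reconstruct(tr, x, fit)
  expect_equal(attr(rec_sig, "delta_applied"),
               if (fit$lrt_delta$p_value < 0.05) fit$delta else 1)
})

test_that("multi-tree summaries aggregate estimates and significance", {
  mk <- function(delta, p) {
    structure(list(delta = delta, lambda = 1, sigma2 = 1, root_state = 0,
                   lrt_delta = list(statistic = 1, p_value = p)),
              class = "trait_fit")
  }
  fits <- list(mk(2, 0.01), mk(2.2, 0.02), mk(1.1, 0.2), mk(0.9, 0.6))
  s <- summarize_over_trees(fits)
  expect_equal(s$pct_significant, 50)
  expect_equal(s$delta_mean, mean(c(2, 2.2, 1.1, 0.9)))
  single <- summarize_over_trees(list(mk(2, 0.3)))
  expect_equal(single$delta_sd, 0)
  expect_error(summarize_over_trees(list()), "no fits")
})
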