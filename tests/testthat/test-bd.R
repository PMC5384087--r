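test_that("rate functions evaluate the exponential time-dependence", {
  expect_equal(rate_at(0.161, 0.110, t = 0), 0.161)
  expect_equal(rate_at(0.161, 0.110, t = 10), 0.161 * exp(1.10))
  expect_equal(rate_at(0.2, 0, t = c(0, 3, 12)), rep(0.2, 3))
  expect_error(rate_at(0.2, 0.1, t = -1), "t must be")
})

test_that("pure-birth likelihood matches the independent Yule closed form", {
  expect_equal(bd_loglik(c(2, 1), 0.2), oracle_yule_loglik(c(2, 1), 0.2))
  for (seed in 1:20) {
    tr <- simulate_bd_tree(0.3, n_tips = sample(5:60, 1), seed = 4000 + seed)
    bt <- branching_times(tr)
    lam <- runif(1, 0.05, 0.6)
    expect_equal(bd_loglik(bt, lam), oracle_yule_loglik(bt, lam),
                 tolerance = 1e-9)
  }
  expect_error(bd_loglik(c(1, 2), 0.2), "descending")
  expect_error(bd_loglik(c(2, 1), 0.2, f = 0), "sampling fraction")
})

test_that("model nesting collapses exactly", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- simulate_bd_tree(0.3, n_tips = sample(10:80, 1), seed = 5000 + rep)
    bt <- branching_times(tr)
    lam <- runif(1, 0.05, 0.5)
    # BVAR with alpha = 0 equals BCST
    expect_equal(bd_loglik(bt, lam, alpha = 0), bd_loglik(bt, lam),
                 tolerance = 1e-10)
    # extinction models with mu0 = 0 collapse to pure birth
    al <- runif(1, -0.3, 0.3); be <- runif(1, -0.3, 0.3)
    expect_equal(bd_loglik(bt, lam, al, mu0 = 0, beta = be),
                 bd_loglik(bt, lam, al), tolerance = 1e-10)
  }
})

test_that("analytic inner integral agrees with adaptive quadrature", {
  # exponential speciation, no extinction: J(t) = exp(rho(t)) - 1 in closed
  # form; the quadrature route must reproduce it across a parameter grid
  grid <- expand.grid(lambda0 = c(0.05, 0.15, 0.4, 0.8),
                      alpha = c(-0.3, -0.1, 0.05, 0.2, 0.5),
                      t = c(0.5, 2, 5, 10, 15))
  # keep the cumulative intensity in floating-point range
  grid <- grid[grid$lambda0 * (exp(grid$alpha * grid$t) - 1) / grid$alpha < 500, ]
  expect_gte(nrow(grid), 90)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    closed <- exp(g$lambda0 * (exp(g$alpha * g$t) - 1) / g$alpha) - 1
    quad <- stats::integrate(
      function(s) g$lambda0 * exp(g$alpha * s) *
        exp(g$lambda0 * (exp(g$alpha * s) - 1) / g$alpha),
      0, g$t, abs.tol = 1e-10, rel.tol = 1e-12
    )$value
    expect_equal(closed, quad, tolerance = 1e-7)
  }
  # and the fixed-order Gauss path used for extinction models matches the
  # adaptive one
  for (i in seq(1, nrow(grid), by = 7)) {
    g <- grid[i, ]
    gauss <- bd_loglik(c(g$t, g$t / 2, g$t / 3), g$lambda0, g$alpha,
                       mu0 = 0.05, beta = 0.1)
    adapt <- bd_loglik(c(g$t, g$t / 2, g$t / 3), g$lambda0, g$alpha,
                       mu0 = 0.05, beta = 0.1, quadrature = "adaptive")
    expect_equal(gauss, adapt, tolerance = 1e-6)
  }
})

test_that("model table satisfies the AIC identity and ranking contract", {
  tr <- simulate_bd_tree(0.3, n_tips = 60, seed = 77)
  fits <- fit_bd_models(tr, seed = 5)
  tab <- fits$table
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logL, tolerance = 1e-12)
  expect_true(!is.unsorted(tab$AIC))
  expect_equal(tab$dAIC[1], 0)
  expect_true(all(tab$dAIC >= 0))
  # nested models never beat their superset
  logl <- stats::setNames(tab$logL, tab$model)
  expect_gte(logl["BVAR"] + 1e-4, logl["BCST"])
  expect_gte(logl["BVAR-DCST"] + 1e-4, logl["BVAR"])
  expect_gte(logl["BVAR-DVAR"] + 1e-4, logl["BVAR-DCST"])
  expect_error(fit_bd_models(branching_times = 1), ">= 3 tips")
})

test_that("rate-through-time curves reflect the fitted parameters", {
  tr <- simulate_bd_tree(0.3, n_tips = 40, seed = 13)
  fits <- fit_bd_models(tr, specs = bd_model_specs()[1:2, ], seed = 2)
  rc <- rate_through_time(fits, model = "BCST")
  expect_true(all(rc$speciation == rc$speciation[1])) # flat line
  ft <- fits$fits[["BVAR"]]
  rc2 <- rate_through_time(fits, model = "BVAR")
  expect_equal(rc2$speciation[1], ft$lambda0)
  expect_equal(rc2$speciation[nrow(rc2)],
               ft$lambda0 * exp(ft$alpha * fits$crown_age))
  if (ft$alpha > 0) expect_true(all(diff(rc2$speciation) > 0))
  single <- rate_through_time(fits, times = 0)
  expect_equal(single$speciation, ft_best <- fits$fits[[fits$table$model[1]]]$lambda0)
  expect_error(rate_through_time(fits, times = numeric(0)), "empty")
})

test_that("the posterior-frequency rule marks rare shifts non-significant", {
  # a shift found in 4 of 100 trees falls below the 5% rule
  sets <- c(rep(list(list(c("a", "b", "c", "d"))), 4),
            rep(list(list()), 96))
  loc <- shift_location_frequencies(sets, n_trees = 100, min_fraction = 0.05)
  expect_equal(loc$n_trees_with_shift, 4L)
  expect_false(loc$significant)
  # 5 of 100 reaches the threshold
  sets5 <- c(rep(list(list(c("a", "b", "c", "d"))), 5),
             rep(list(list()), 95))
  loc5 <- shift_location_frequencies(sets5, n_trees = 100, min_fraction = 0.05)
  expect_true(loc5$significant)
  # near-identical tip sets merge under the Jaccard rule
  sets_j <- list(list(letters[1:10]), list(letters[1:9]))
  locj <- shift_location_frequencies(sets_j, n_trees = 2, min_fraction = 0.05)
  expect_equal(nrow(locj), 1L)
  expect_equal(locj$n_trees_with_shift, 2L)
  expect_error(shift_scan(tree_cherry(), threshold = 0), "threshold")
})

test_that("a strongly shifted clade is detected and homogeneous trees are not", {
  # power: background Yule at 0.15 with a 10x clade
  bg <- simulate_bd_tree(0.15, crown_age = 14, seed = 301)
  pend <- bg$edge.length[bg$edge[, 2] <= ape::Ntip(bg)]
  tip <- bg$tip.label[which.max(pend)]
  cl <- simulate_bd_tree(1.5, crown_age = min(max(pend) * 0.9, 2.2), seed = 302)
  shifted <- graft_clade(bg, tip, cl)
  sc <- shift_scan(shifted, seed = 5)
  expect_gte(nrow(sc$locations), 1L)
  found <- any(vapply(strsplit(sc$locations$location, ","), function(ts) {
    jac <- length(intersect(ts, paste0(tip, "_", cl$tip.label))) /
      length(union(ts, paste0(tip, "_", cl$tip.label)))
    jac >= 0.6
  }, logical(1)))
  expect_true(found)

  # calibration: one homogeneous tree yields nothing
  hom <- simulate_bd_tree(0.25, n_tips = 40, seed = 303)
  sc0 <- shift_scan(hom, seed = 6)
  expect_equal(sum(sc0$locations$significant), 0L)
})
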