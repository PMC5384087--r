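areas2 <- area_system(c("A", "B"))
areas3 <- area_system(c("A", "B", "C"))
flat_schedule <- function(k, areas) {
  m <- matrix(1, k, k); diag(m) <- 0
  dispersal_schedule(areas, c(100, 0), list(m))
}

test_that("state enumeration is ordered, capped, and validated", {
  st9 <- enumerate_states(area_system(), 4L)
  expect_equal(nrow(st9) - 1L, 255L) # C(9,1)+C(9,2)+C(9,3)+C(9,4)
  expect_equal(st9$mask[nrow(st9)], 0L) # null appended last
  expect_true(!is.unsorted(st9$size[-nrow(st9)]))

  st2 <- enumerate_states(areas2, 2L)
  expect_equal(st2$label[1:3], c("A", "B", "AB"))
  expect_error(enumerate_states(areas3, 5L), "max_range_size")
})

test_that("anagenetic rate matrix has DEC structure", {
  st <- enumerate_states(areas2, 2L)
  m <- matrix(1, 2, 2); diag(m) <- 0
  Q <- build_rate_matrix(st, d = 0.1, e = 0.05, m)
  expect_equal(Q["A", "AB"], 0.1)
  expect_equal(Q["AB", "A"], 0.05)
  expect_equal(Q["A", "B"], 0)          # no direct switching
  expect_equal(Q["A", "0"], 0.05)       # single-area loss goes to null
  expect_equal(unname(rowSums(Q)), rep(0, nrow(Q)), tolerance = 1e-12)
  expect_equal(unname(Q["0", ]), rep(0, nrow(Q)))  # null absorbing
  expect_error(build_rate_matrix(st, -0.1, 0, m), "non-negative")
})

test_that("branch transitions are stochastic and match a direct expm", {
  st <- enumerate_states(areas2, 2L)
  m <- matrix(1, 2, 2); diag(m) <- 0
  Q <- build_rate_matrix(st, 0.13, 0.07, m)
  P <- branch_transition(list(Q), c(100, 0), 4.2, 1.1)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-8)
  expect_true(all(P >= 0))
  # independent 4-state matrix exponential
  P_direct <- as.matrix(Matrix::expm(Matrix::Matrix(Q * 3.1)))
  expect_lt(max(abs(P - P_direct)), 1e-8)
  # zero span and zero rates give the identity
  expect_equal(branch_transition(list(Q), c(100, 0), 2, 2), diag(4))
  Q0 <- build_rate_matrix(st, 0, 0, m)
  expect_equal(unname(branch_transition(list(Q0), c(100, 0), 9, 0)), diag(4))
})

test_that("pruning likelihood reproduces the hand-derived cherry cases", {
  ch <- tree_cherry()
  sch <- flat_schedule(2, areas2)
  expect_equal(dec_loglik(ch, c(A = "A", B = "A"), 0, 0, sch, 2), log(1 / 3))
  expect_equal(dec_loglik(ch, c(A = "A", B = "B"), 0, 0, sch, 2),
               log((1 / 3) * (1 / 2)))
  expect_error(
    dec_loglik(ch, c(A = "AB", B = "A"), 0, 0, sch, max_range_size = 1),
    "max_range_size"
  )
  expect_error(dec_loglik(ch, c(A = "AZ", B = "A"), 0, 0, sch, 2), "unknown area")
})

test_that("pruning equals exhaustive enumeration over small instances", {
  trees <- list(tree_cherry(), tree3(), tree4_balanced(), tree4_pectinate())
  grid <- c(0, 0.01, 0.1, 1)
  n_cases <- 0
  for (tr in trees) {
    tips <- tr$tip.label
    for (ar in list(list(n = 2, areas = areas2), list(n = 3, areas = areas3))) {
      sch <- flat_schedule(ar$n, ar$areas)
      set.seed(ar$n * 17 + ape::Ntip(tr))
      labs <- unclass(ar$areas)
      # random observable tip ranges of size <= 2
      rng <- vapply(tips, function(x) {
        sz <- sample(1:2, 1)
        paste(sort(sample(labs, sz)), collapse = "")
      }, character(1))
      for (d in grid) for (e in grid) {
        got <- dec_loglik(tr, rng, d, e, sch, max_range_size = 2)
        want <- oracle_dec_loglik(tr, rng, d, e, ar$n, 2)
        expect_equal(got, want, tolerance = 1e-6)
        n_cases <- n_cases + 1
      }
    }
  }
  expect_gte(n_cases, 128)
})

test_that("time-stratified likelihood matches the enumeration oracle", {
  m1 <- matrix(1, 2, 2); m2 <- matrix(0.3, 2, 2)
  diag(m1) <- 0; diag(m2) <- 0
  sch <- dispersal_schedule(areas2, c(1.5, 0.7, 0), list(m1, m2))
  tr <- tree3() # crown 2 extends past the oldest boundary
  rng <- c(A = "A", B = "AB", C = "B")
  for (d in c(0.05, 0.4)) for (e in c(0, 0.1)) {
    got <- dec_loglik(tr, rng, d, e, sch, 2)
    want <- oracle_dec_loglik(tr, rng, d, e, 2, 2,
                              boundaries = c(1.5, 0.7, 0),
                              mults = list(m1, m2))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("likelihood is invariant to area relabelling and slice duplication", {
  tr <- tree4_pectinate()
  rng <- c(A = "A", B = "AB", C = "C", D = "BC")
  m <- matrix(c(0, 1, 0.4, 1, 0, 0.9, 0.4, 0.9, 0), 3, 3)
  sch1 <- dispersal_schedule(areas3, c(100, 0), list(m))
  base <- dec_loglik(tr, rng, 0.08, 0.02, sch1, 2)

  # permute areas A->C->B->A and permute the multiplier matrix to match
  perm <- c(2L, 3L, 1L) # new index of old areas
  mp <- m[order(perm), order(perm)]
  relabel <- c(A = "B", B = "C", C = "A")
  rng_p <- vapply(rng, function(s) {
    paste(sort(relabel[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1))
  schp <- dispersal_schedule(areas3, c(100, 0), list(mp))
  expect_equal(dec_loglik(tr, rng_p, 0.08, 0.02, schp, 2), base,
               tolerance = 1e-10)

  # identical multipliers in three slices = single slice
  sch3 <- dispersal_schedule(areas3, c(3, 2, 1, 0), list(m, m, m))
  expect_equal(dec_loglik(tr, rng, 0.08, 0.02, sch3, 2), base,
               tolerance = 1e-10)
})

test_that("conflicting tip data lower the likelihood on the cherry", {
  sch <- flat_schedule(2, areas2)
  for (r in c(0.01, 0.05, 0.2)) {
    same <- dec_loglik(tree_cherry(), c(A = "A", B = "A"), r, r, sch, 2)
    diff <- dec_loglik(tree_cherry(), c(A = "A", B = "B"), r, r, sch, 2)
    expect_gte(same, diff)
  }
})

test_that("ancestral marginals are proper, symmetric, and certain when forced", {
  sch <- flat_schedule(2, areas2)
  anc <- ancestral_ranges(tree_cherry(), c(A = "A", B = "A"), 0, 0, sch, 2)
  root_p <- anc$prob[[3]]
  expect_equal(unname(root_p["A"]), 1)

  anc2 <- ancestral_ranges(tree_cherry(), c(A = "A", B = "B"), 0.05, 0.02, sch, 2)
  root_p2 <- anc2$prob[[3]]
  expect_equal(unname(root_p2["A"]), unname(root_p2["B"]), tolerance = 1e-10)
  for (p in anc2$prob) expect_equal(sum(p), 1, tolerance = 1e-8)

  # root marginal weighted by the prior reproduces the total likelihood
  tr <- tree4_pectinate()
  rng <- c(A = "A", B = "AB", C = "B", D = "A")
  ll <- dec_loglik(tr, rng, 0.07, 0.03, sch, 2)
  anc3 <- ancestral_ranges(tr, rng, 0.07, 0.03, sch, 2)
  expect_equal(sum(vapply(anc3$prob, sum, numeric(1))),
               ape::Ntip(tr) + tr$Nnode, tolerance = 1e-8)
  expect_true(is.finite(ll))
})

test_that("ML fit is deterministic, boundary-seeking on uniform data, and recovers rates", {
  sch <- flat_schedule(2, areas2)
  tr <- simulate_bd_tree(0.35, n_tips = 25, seed = 50)
  uni <- stats::setNames(rep("A", 25), tr$tip.label)
  fit <- fit_dec(tr, uni, sch, 2, seed = 3, compute_ancestral = FALSE)
  expect_lt(fit$d, 1e-6)
  expect_lt(fit$e, 1e-6)
  fit2 <- fit_dec(tr, uni, sch, 2, seed = 3, compute_ancestral = FALSE)
  expect_identical(fit$d, fit2$d)
  expect_identical(fit$logL, fit2$logL)
  expect_true(all(fit$logL >= fit$starts$logL - 1e-6))
})

test_that("simulated dispersal rate is recovered within a factor of two", {
  areas4 <- area_system(LETTERS[1:4])
  m <- matrix(1, 4, 4); diag(m) <- 0
  sch <- dispersal_schedule(areas4, c(100, 0), list(m))
  d_true <- 0.05
  ok <- 0; n_rep <- 10
  for (rep in seq_len(n_rep)) {
    tr <- simulate_bd_tree(0.35, n_tips = 100, seed = 600 + rep)
    h <- simulate_dec_history(tr, d_true, 0.01, sch, 2, root_range = "A",
                              seed = 700 + rep)
    keep <- names(h$tip_ranges)[h$tip_ranges != "0"]
    fit <- fit_dec(ape::keep.tip(tr, keep), h$tip_ranges[keep], sch, 2,
                   seed = rep, compute_ancestral = FALSE)
    if (fit$d > d_true / 2 && fit$d < d_true * 2) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.8)
})

test_that("event counting rules work on hand-built reconstructions", {
  # 4-tip pectinate tree, hand-assigned most-probable states:
  # root {A,B}; next node {A}; cherry node {A}; tips A,A,A,B
  tr <- tree4_pectinate()
  rec <- tibble::tibble(
    node = 1:7,
    mp_state = c("A", "A", "A", "B", "AB", "A", "A"),
    age = c(0, 0, 0, 0, 3, 2, 1)
  )
  insitu <- count_in_situ_speciation(rec, tr, "A")
  expect_equal(insitu$count, 2L) # the two all-A internal nodes
  expect_equal(insitu$n_internal, 3L)

  none <- count_in_situ_speciation(rec, tr, "C")
  expect_equal(none$count, 0L)
  expect_error(count_in_situ_speciation(rec, tr, ""), "empty")

  # colonization: two independent gains of B (root {A,B} -> both crown
  # daughters lack B except tip D which has it; plus a gain on a tip branch)
  rec2 <- tibble::tibble(
    node = 1:7,
    mp_state = c("A", "AB", "A", "B", "A", "A", "A"),
    age = c(0, 0, 0, 0, 3, 2, 1)
  )
  ev <- count_colonizations(rec2, tr, "B")
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$age_older > ev$age_younger))
  expect_error(count_colonizations(rec2, tr, "Z"), "unknown")
  # no state contains C anywhere
  expect_equal(nrow(count_colonizations(rec2, tr, "C")), 0L)
})
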