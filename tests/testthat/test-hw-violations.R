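test_that("gamete kernel is the hypergeometric chromosome-sampling law", {
  expect_equal(gamete_kernel(0:2, 2, 4), c(1, 4, 1) / 6)
  expect_equal(gamete_kernel(0:2, 0, 4), c(1, 0, 0))
  for (kp in 0:6) expect_equal(sum(gamete_kernel(0:3, kp, 6)), 1)
  expect_error(gamete_kernel(3, 2, 4), "gamete dosage")
})

test_that("Hardy-Weinberg distributions are exact random-mating fixed points", {
  for (p in c(2L, 4L, 6L, 8L)) {
    for (f in seq(0.1, 0.9, by = 0.2)) {
      res <- random_mating_residual(hw_dosage_distribution(p, f), p)
      expect_lt(max(abs(res)), 1e-12)
    }
    fixed <- c(rep(0, p), 1)  # allele fixed at dosage p
    expect_lt(max(abs(random_mating_residual(fixed, p))), 1e-12)
  }
  # an unmixed 50/50 stack of opposite homozygotes is not an equilibrium
  mix <- c(0.5, 0, 0, 0, 0.5)
  expect_gt(max(abs(random_mating_residual(mix, 4))), 0.01)
  expect_error(random_mating_residual(c(0.5, 0.2), 4), "normalized")
})

test_that("selfing perturbation conserves mass and frequency, inflates homozygotes", {
  d <- selfing_perturbation(0.3, 4, 0.05)$delta
  expect_lt(abs(sum(d)), 1e-12)
  expect_lt(abs(sum((0:4) * d)), 1e-12)
  d5 <- selfing_perturbation(0.5, 4, 0.05)$delta
  expect_gt(d5[1], 0)
  expect_gt(d5[5], 0)
  expect_equal(selfing_perturbation(0.4, 4, 0)$delta, rep(0, 5))
  expect_warning(selfing_perturbation(0.4, 4, 0.5), "0.2")
  expect_error(selfing_perturbation(0, 4, 0.05), "strictly inside")
})

test_that("selfing perturbation signs match one-generation mating simulation", {
  set.seed(77)
  mc <- oracle_selfing_mc(4, 0.3, n_draws = 2e5)
  analytic <- suppressWarnings(selfing_perturbation(0.3, 4, 1))$delta
  noise <- 4 / sqrt(2e5)  # ~3 binomial SDs on a difference of proportions
  idx <- abs(mc) > noise
  expect_true(any(idx))
  expect_equal(sign(analytic[idx]), sign(mc[idx]))
})

test_that("disomic selfing conserves, favors even dosages, reduces to polysomic at p=2", {
  d <- disomic_selfing_perturbation(0.3, 4, 0.05)$delta
  expect_lt(abs(sum(d)), 1e-12)
  expect_lt(abs(sum((0:4) * d)), 1e-12)
  # even-dosage excess relative to the polysomic case at f = 0.5
  d_dis <- disomic_selfing_perturbation(0.5, 4, 0.05)$delta
  d_pol <- selfing_perturbation(0.5, 4, 0.05)$delta
  expect_gt(d_dis[3], d_pol[3])
  for (f in c(0.2, 0.5, 0.8)) {
    expect_equal(disomic_selfing_perturbation(f, 2, 0.03)$delta,
                 selfing_perturbation(f, 2, 0.03)$delta, tolerance = 1e-12)
  }
})

test_that("disomic selfing signs match per-pair mating simulation", {
  set.seed(78)
  mc <- oracle_selfing_mc(4, 0.4, n_draws = 2e5, disomic = TRUE)
  analytic <- suppressWarnings(disomic_selfing_perturbation(0.4, 4, 1))$delta
  idx <- abs(mc) > 4 / sqrt(2e5)
  expect_true(any(idx))
  expect_equal(sign(analytic[idx]), sign(mc[idx]))
})

test_that("mixed inheritance interpolates linearly between the pure cases", {
  f <- 0.35; p <- 4L; ps <- 0.04
  pol <- selfing_perturbation(f, p, ps)$delta
  dis <- disomic_selfing_perturbation(f, p, ps)$delta
  expect_equal(mixed_inheritance_perturbation(f, p, ps, 0)$delta, pol)
  expect_equal(mixed_inheritance_perturbation(f, p, ps, 1)$delta, dis)
  expect_equal(mixed_inheritance_perturbation(f, p, ps, 0.5)$delta,
               (pol + dis) / 2)
})

test_that("selection perturbation solves the linearized system", {
  p <- 4L
  expect_equal(selection_perturbation(0.5, p, rep(0, p + 1))$delta,
               rep(0, p + 1))
  het <- selection_perturbation(0.5, p,
                                fitness_scheme(p, "heterozygote_advantage",
                                               0.01))$delta
  expect_lt(het[1], 0)
  expect_lt(het[p + 1], 0)
  rec <- selection_perturbation(0.5, p,
                                fitness_scheme(p, "recessive_deleterious",
                                               0.01))$delta
  expect_lt(rec[p + 1], 0)
  for (d in list(het, rec)) {
    expect_lt(abs(sum(d)), 1e-12)
    expect_lt(abs(sum((0:p) * d)), 1e-10)
  }
})

test_that("selection shapes match the iterated selection-mating map", {
  p <- 4L
  s <- fitness_scheme(p, "recessive_deleterious", 0.005)
  it <- oracle_selection_iteration(p, 0.5, s, gens = 3000)
  lin <- selection_perturbation(it$f, p, s)$delta
  expect_lt(max(abs(lin - it$delta)) / max(abs(it$delta)), 0.05)

  s2 <- fitness_scheme(p, "heterozygote_advantage", 0.005)
  it2 <- oracle_selection_iteration(p, 0.5, s2, gens = 3000)
  lin2 <- selection_perturbation(it2$f, p, s2)$delta
  expect_lt(max(abs(lin2 - it2$delta)) / max(abs(it2$delta)), 0.05)
})

test_that("frequency integration is linear and conserves what the pointwise law conserves", {
  p <- 4L
  zero <- integrate_over_neutral_frequencies(function(f) rep(0, p + 1), p)
  expect_equal(zero$delta, rep(0, p + 1))
  ig <- integrate_over_neutral_frequencies(
    function(f) selfing_perturbation(f, p, 0.05), p)
  expect_lt(abs(sum(ig$delta)), 1e-10)
  # integrated selfing shape keeps its homozygote excess
  expect_gt(ig$delta[1], 0)
  expect_gt(ig$delta[p + 1], 0)
  expect_error(integrate_over_neutral_frequencies(function(f) rep(0, p + 1),
                                                  p, grid = numeric()),
               "empty")
})

test_that("single-individual SFS is the heterozygous DD slice over theta/d", {
  p <- 6L
  s <- single_individual_sfs(rep(0, p + 1), p, theta = 2)
  expect_equal(s$xi_neutral, 2 / (1:(p - 1)))
  expect_equal(s$delta_xi, rep(0, p - 1))
  dev <- c(0.3, -0.1, 0.05, -0.15, 0.02, -0.12, 0)
  s2 <- single_individual_sfs(dev, p)
  expect_equal(s2$delta_xi, dev[2:p])
  # visible heterozygous part need not sum to zero even if the DD deviation does
  expect_false(isTRUE(all.equal(sum(s2$delta_xi), 0)))
})

test_that("test directions are unit vectors with the standard sign behavior", {
  p <- 4L
  z <- test_direction(rep(0, p - 1), p)
  expect_equal(as.numeric(z), c(0, 0))
  # pure singleton deficit: D responds positively
  sing <- test_direction(c(-1, 0, 0), p)
  expect_gt(sing[["D"]], 0)
  # pure high-frequency-derived excess: H responds negatively
  high <- test_direction(c(0, 0, 1), p)
  expect_lt(high[["H"]], 0)
  expect_equal(sum(high^2), 1)
})
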