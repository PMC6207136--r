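test_that("Watterson estimator divides by the harmonic number", {
  expect_equal(theta_watterson(0, 10)$value, 0)
  expect_equal(theta_watterson(5, 2)$value, 5)
  expect_equal(theta_watterson(10, 8)$value, 10 / sum(1 / (1:7)))
  # digamma continuation agrees with the sum at integers
  expect_equal(theta_watterson(1, 23)$components$a_n, sum(1 / (1:22)))
  expect_error(theta_watterson(3, 1), "exceed 1")
})

test_that("read-pair diversity units follow their closed forms", {
  expect_equal(pi_within(2, 1), 1)
  expect_equal(pi_within(4, 1), 0.5)
  expect_equal(pi_within(c(5, 3), c(0, 3)), c(0, 0))
  expect_equal(pi_within(1, 1), 0)  # single read: no pair
  expect_error(pi_within(2, 3), "exceeds depth")

  expect_equal(pi_between(3, 0, 5, 0), 0)
  expect_equal(pi_between(4, 4, 3, 0), 1)  # all cross pairs differ
  expect_equal(pi_between(2, 1, 4, 1), (1 * 3 + 1 * 1) / 8)
  expect_error(pi_between(2, 3, 2, 0), "exceeds depth")
})

test_that("pairwise theta is a per-site weighted average of unbiased units", {
  # n = 2 diploids, one site, reads (2,1) and (2,0): units are
  # (p/(p-1))*pi_1 = 2, pi_2 = 0, pi_12 = 0.5 with weights 1, 1, 2
  rc <- read_counts(depth = rbind(2, 2), derived = rbind(1, 0), ploidy = 2)
  expect_equal(theta_pi(rc)$value, (2 + 0 + 2 * 0.5) / 4)

  mono <- read_counts(matrix(5L, 3, 4), matrix(0L, 3, 4), 4)
  expect_equal(theta_pi(mono)$value, 0)
  expect_equal(theta_pi_mvue(mono)$value, 0)

  allzero <- read_counts(matrix(0L, 3, 2), matrix(0L, 3, 2), 4)
  expect_error(theta_pi(allzero), "all depths are zero")
})

test_that("simulated neutral replicates recover theta without bias", {
  set.seed(101)
  reps <- 400
  est <- vapply(seq_len(reps), function(i)
    theta_pi(sim_replicate(5, 8, 4, 6))$value, 0)
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 5), 4 * se)
})

test_that("theta_pi expectation is invariant to doubling the depth", {
  set.seed(7)
  reps <- 300
  pair <- vapply(seq_len(reps), function(i) {
    G <- simulate_neutral_genotypes(5, 8, 4)
    c(theta_pi(simulate_reads(G, 3))$value,
      theta_pi(simulate_reads(G, 6))$value)
  }, numeric(2))
  d <- pair[1, ] - pair[2, ]
  expect_lt(abs(mean(d)), 4 * sd(d) / sqrt(reps))
})

test_that("variance-weighted estimator equals the equal-weight one at equal depth", {
  set.seed(11)
  for (p in c(2L, 4L)) {
    G <- simulate_neutral_genotypes(6, 5, p)
    rc <- simulate_reads(G, 7, depth_model = "fixed")
    expect_equal(theta_pi_mvue(rc)$value, theta_pi(rc)$value,
                 tolerance = 1e-12)
  }
})

test_that("individuals with zero mean depth are excluded with a warning", {
  r <- rbind(c(4L, 6L), c(0L, 0L), c(5L, 3L))
  cc <- rbind(c(1L, 0L), c(0L, 0L), c(2L, 3L))
  rc <- read_counts(r, cc, 4)
  expect_warning(est <- theta_pi_mvue(rc), "zero mean depth")
  expect_equal(est$n, 2L)
})

test_that("effective sample size hits its unit-depth, finite and asymptotic values", {
  rc1 <- read_counts(matrix(1L, 10, 3), matrix(0L, 10, 3), 4)
  expect_equal(effective_sample_size(rc1), 10)
  rc_inf <- read_counts(matrix(1000L, 10, 2), matrix(0L, 10, 2), 4)
  expect_equal(effective_sample_size(rc_inf), 40, tolerance = 1e-6)
  rc_one <- read_counts(matrix(4L, 1, 1), matrix(2L, 1, 1), 4)
  expect_equal(effective_sample_size(rc_one), 4 * (1 - (3 / 4)^4))
  expect_error(effective_sample_size(read_counts(matrix(0L, 2, 0),
                                                 matrix(0L, 2, 0), 4)),
               "no sites")
})

test_that("the Zeng normalizer grows with depth and reaches (pn-1)/pn", {
  p <- 4L; n <- 5L
  base <- c(3L, 0L, 2L, 5L, 1L)
  n0 <- zeng_normalizer(base, p)
  for (i in seq_len(n)) {
    bumped <- base; bumped[i] <- bumped[i] + 2L
    expect_gte(zeng_normalizer(bumped, p), n0)
  }
  expect_equal(zeng_normalizer(rep(2000L, n), p), (p * n - 1) / (p * n),
               tolerance = 1e-8)
})

test_that("frequency-weighted theta reduces to the genotype form at full depth", {
  set.seed(3)
  n <- 5L; p <- 4L
  G <- simulate_neutral_genotypes(6, n, p)
  # deterministic 'reads': depth divisible by p, counts exactly r*d/p
  r <- matrix(2000L, n, ncol(G$dosages))
  cc <- r * G$dosages / p
  rc <- read_counts(r, cc, p)
  j <- colSums(G$dosages)
  expect_equal(theta_zeng(rc)$value, sum(j) / (p * n - 1), tolerance = 1e-6)

  none <- read_counts(matrix(3L, 2, 3), matrix(0L, 2, 3), 4)
  expect_equal(theta_zeng(none)$value, 0)
})

test_that("simulated neutral replicates recover theta with the Zeng estimator", {
  set.seed(57)
  reps <- 400
  est <- vapply(seq_len(reps), function(i)
    theta_zeng(sim_replicate(5, 6, 4, 5))$value, 0)
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 5), 4 * se)
})
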