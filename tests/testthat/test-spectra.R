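test_that("dd_at_site counts dosages and tracks the derived count", {
  dd <- dd_at_site(c(4, 1, 0, 3), ploidy = 4)
  expect_equal(unname(dd$counts), c(1, 1, 0, 1, 1))
  expect_equal(dd$derived_count, 8)
  expect_equal(sum(dd$counts), dd$n)

  dd0 <- dd_at_site(c(0, 0), ploidy = 4)
  expect_equal(unname(dd0$counts), c(2, 0, 0, 0, 0))
  expect_equal(dd0$derived_count, 0)

  dd2 <- dd_at_site(c(2, 2, 2, 2), ploidy = 4)
  expect_equal(unname(dd2$counts), c(0, 0, 4, 0, 0))
  expect_equal(dd2$derived_count, 8)

  expect_error(dd_at_site(c(5, 0), ploidy = 4), "invalid genotype")
  expect_error(dd_at_site(c(-1, 0), ploidy = 4), "invalid genotype")
})

test_that("empirical SFS matches the worked tetraploid example and edge cases", {
  sfs <- empirical_sfs(fig_example_matrix())
  expect_equal(sfs$j, 8)
  expect_equal(sfs$count, 3)
  expect_equal(attr(sfs, "n_segregating"), 3)

  empty <- empirical_sfs(genotype_matrix(matrix(0L, 4, 5), ploidy = 4))
  expect_equal(nrow(empty), 0)

  one_het <- genotype_matrix(matrix(c(1L, 0L, 0L, 0L), 4, 1), ploidy = 4)
  expect_equal(empirical_sfs(one_het)$j, 1)
  expect_equal(empirical_sfs(one_het)$count, 1)
})

test_that("normalized SFDS puts mass 1/3 on each class of the worked example", {
  sfds <- empirical_sfds(fig_example_matrix(), normalized = TRUE)
  expect_equal(nrow(sfds), 3)
  expect_true(all(sfds$j == 8))
  got <- sfds[order(sfds$I1, sfds$I2), c("I1", "I2", "I3")]
  expect_equal(unname(as.matrix(got)),
               rbind(c(0L, 4L, 0L), c(1L, 0L, 1L), c(1L, 2L, 1L)))
  expect_equal(sfds$mass, rep(1 / 3, 3))

  # duplicating every site leaves the normalized SFDS unchanged
  g2 <- genotype_matrix(cbind(fig_example_matrix()$dosages,
                              fig_example_matrix()$dosages), ploidy = 4)
  sfds2 <- empirical_sfds(g2, normalized = TRUE)
  expect_equal(sfds2$mass, sfds$mass)
  expect_equal(sfds2[names(sfds2) != "mass"], sfds[names(sfds) != "mass"],
               ignore_attr = TRUE)

  one <- empirical_sfds(genotype_matrix(matrix(c(1L, 2L, 0L, 1L), 4, 1), 4),
                        normalized = TRUE)
  expect_equal(nrow(one), 1)
  expect_equal(one$mass, 1)
})

test_that("SFDS marginals, SDS conditionals and DD completion are consistent", {
  set.seed(42)
  for (p in c(2L, 4L, 6L)) {
    n <- 5L
    G <- simulate_neutral_genotypes(8, n, p)
    sfs <- empirical_sfs(G)
    sfds <- empirical_sfds(G)
    # marginalizing the SFDS over DDs recovers the SFS exactly
    marg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(sfds), j),
                             count = sum(mass), .groups = "drop")
    expect_equal(marg$j, sfs$j)
    expect_equal(marg$count, as.numeric(sfs$count))
    expect_equal(sum(sfds$mass), attr(sfds, "n_segregating"))

    # implied homozygote counts are non-negative integers
    full <- complete_dd(sfds)
    expect_true(all(full$I0 >= 0L))
    expect_true(all(full[[paste0("I", p)]] >= 0L))

    # conditionals sum to one and, reweighted by the SFS, give back the SFDS
    for (j in unique(sfds$j)) {
      sds <- empirical_sds(sfds, j)
      expect_equal(sum(sds$prob), 1)
      back <- sds$prob * sfs$count[sfs$j == j]
      expect_equal(sort(back), sort(sfds$mass[sfds$j == j]))
    }
  }
})

test_that("conditioning on an absent frequency class is an error", {
  sfds <- empirical_sfds(fig_example_matrix())
  expect_error(empirical_sds(sfds, 3), "no sites")
  deg <- empirical_sds(sfds, 8)
  expect_equal(nrow(deg), 3)
})

test_that("sites with missing genotypes or unknown orientation are dropped", {
  d <- fig_example_matrix()$dosages
  d[2, 1] <- NA
  g <- genotype_matrix(d, 4)
  sfs <- empirical_sfs(g)
  expect_equal(sum(sfs$count), 2)
  expect_equal(attr(sfs, "n_dropped"), 1)

  g_fold <- genotype_matrix(fig_example_matrix()$dosages, 4,
                            ancestral_known = c(TRUE, FALSE, TRUE))
  expect_equal(sum(empirical_sfs(g_fold)$count), 2)
})

test_that("frequency uncertainty bound follows the quadratic-mean rule", {
  expect_equal(frequency_uncertainty_bound(25, 4), 0.1)
  expect_equal(frequency_uncertainty_bound(25, 8), 0.1)  # ploidy-free worst case
  expect_equal(frequency_uncertainty_bound(100, 4), 0.05)
  expect_equal(frequency_uncertainty_bound(10, 4, 0), 0)
  # quadratic mean, not arithmetic: per-individual SDs (0, 2) at p = 4
  expect_equal(frequency_uncertainty_bound(2, 4, c(0, 2)),
               sqrt(mean(c(0, 4))) / (4 * sqrt(2)))
  expect_error(frequency_uncertainty_bound(10, 4, 2.5), "dosage_sd")
})
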