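# Independent oracles used across the test files. Each recomputes a quantity
# by brute force, direct formula or simulation, never through the package
# path it checks.

# Finite-sample SDS by exhaustive enumeration of all C(pn, j) placements of
# derived alleles over pn chromosomes grouped into n individuals of p.
# Returns a named vector: key "I1,...,I{p-1}" -> probability.
oracle_sds_enum <- function(n, p, j) {
  slots <- utils::combn(n * p, j)
  if (j == 0) return(c(`0` = 1))
  keys <- apply(matrix(slots, nrow = j), 2L, function(s) {
    d <- tabulate(ceiling(s / p), nbins = n)
    dd <- tabulate(d + 1L, nbins = p + 1L)
    paste(dd[2:p], collapse = ",")
  })
  tab <- table(keys)
  stats::setNames(as.numeric(tab) / ncol(slots), names(tab))
}

# The diploid joint frequency-heterozygosity spectrum in its direct printed
# form: theta * 2^I1 * n! / (I1! ((j-I1)/2)! (n-(j+I1)/2)!) / (j * C(2n, j)),
# zero off the parity/support constraints.
oracle_joint_diploid <- function(theta, n, j, I1) {
  if ((j - I1) %% 2 != 0) return(0)
  I2 <- (j - I1) / 2
  I0 <- n - I1 - I2
  if (I1 < 0 || I2 < 0 || I0 < 0) return(0)
  theta * 2^I1 * exp(lfactorial(n) - lfactorial(I1) - lfactorial(I2) -
                       lfactorial(I0) - lchoose(2 * n, j)) / j
}

# Classical Tajima's D from a haploid-sample SFS (counts xi_d, d = 1..m-1).
oracle_classical_d <- function(xi, m) {
  d <- seq_len(m - 1)
  S <- sum(xi)
  if (S == 0) return(NA_real_)
  th_pi <- sum(d * (m - d) * xi) / choose(m, 2)
  a1 <- sum(1 / d)
  a2 <- sum(1 / d^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  (th_pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# One-generation individual-based mating Monte Carlo: difference between the
# offspring dosage distribution under pure selfing and under random
# outcrossing, both starting from exact Hardy-Weinberg parents. Equals the
# selfing perturbation at unit selfing rate, up to MC noise. Gametes are
# sampled as actual chromosome subsets, not through the package kernels.
oracle_selfing_mc <- function(p, f, n_draws = 2e5, disomic = FALSE) {
  self_off <- integer(n_draws)
  out_off <- integer(n_draws)
  half <- p / 2
  for (i in seq_len(n_draws)) {
    if (disomic) {
      # parent: p/2 pairs of iid Bernoulli(f) chromosomes
      chrom <- matrix(stats::rbinom(p, 1, f), nrow = 2)
      # each pair contributes one allele per gamete, independently per gamete
      g1 <- chrom[cbind(sample(1:2, half, replace = TRUE), seq_len(half))]
      g2 <- chrom[cbind(sample(1:2, half, replace = TRUE), seq_len(half))]
      self_off[i] <- sum(g1) + sum(g2)
      chrom_b <- matrix(stats::rbinom(p, 1, f), nrow = 2)
      g2b <- chrom_b[cbind(sample(1:2, half, replace = TRUE), seq_len(half))]
      out_off[i] <- sum(g1) + sum(g2b)
    } else {
      chrom <- stats::rbinom(p, 1, f)
      self_off[i] <- sum(chrom[sample.int(p, half)]) +
        sum(chrom[sample.int(p, half)])
      chrom_b <- stats::rbinom(p, 1, f)
      out_off[i] <- sum(chrom[sample.int(p, half)]) +
        sum(chrom_b[sample.int(p, half)])
    }
  }
  (tabulate(self_off + 1L, p + 1L) - tabulate(out_off + 1L, p + 1L)) / n_draws
}

# Deterministic iteration of the full selection + random-mating map from HW,
# re-based to the HW distribution at the drifted frequency: the quasi-steady
# deviation shape the linear solver should reproduce.
oracle_selection_iteration <- function(p, f0, s, gens = 3000) {
  gam <- sapply(0:p, function(kp) stats::dhyper(0:(p / 2), kp, p - kp, p / 2))
  off <- array(0, c(p + 1, p + 1, p + 1))
  for (kp in 0:p) for (kpp in 0:p) {
    o <- convolve(gam[, kp + 1], rev(gam[, kpp + 1]), type = "open")
    off[seq_along(o), kp + 1, kpp + 1] <- o
  }
  I <- stats::dbinom(0:p, p, f0)
  for (t in seq_len(gens)) {
    Iw <- I * (1 + s) / sum(I * (1 + s))
    I <- vapply(0:p, function(k) sum(outer(Iw, Iw) * off[k + 1, , ]), 0)
  }
  f <- sum((0:p) * I) / p
  list(delta = I - stats::dbinom(0:p, p, f), f = f)
}

# Shared simulation shortcut for estimator/test replicates.
sim_replicate <- function(theta, n, p, depth, depth_model = "poisson") {
  G <- simulate_neutral_genotypes(theta, n, p)
  simulate_reads(G, depth, depth_model = depth_model)
}
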