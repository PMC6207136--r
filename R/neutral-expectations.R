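## Closed-form neutral expectations for the SFS, SDS and SFDS.
##
## The finite-sample SDS is the multivariate-hypergeometric law of placing
## the j derived copies uniformly over the pn homologous chromosomes grouped
## into n blocks of p: P({I_d} | j) = multinomial(n; I_0..I_p) *
## prod_d C(p,d)^{I_d} / C(pn, j), with I_p = (j - sum_{d<p} d I_d)/p and
## I_0 = n - sum_{d>=1} I_d. Any key for which those implied counts are not
## non-negative integers has probability zero. Everything is computed in
## log-space (lfactorial/lchoose are exact enough far beyond pn = 40).

#' Hardy-Weinberg dosage distribution
#'
#' The probability that an individual of ploidy p carries dosage d of an
#' allele at population frequency f under random mating:
#' `choose(p, d) f^d (1-f)^(p-d)`.
#'
#' @param ploidy ploidy p.
#' @param f allele frequency in `[0, 1]`.
#' @return Numeric vector of length p+1, the fractions `i_0..i_p`.
#' @examples
#' hw_dosage_distribution(4, 0.5)
#' @export
hw_dosage_distribution <- function(ploidy, f) {
  check_ploidy(ploidy)
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  setNames(dbinom(0:ploidy, ploidy, f), paste0("i", 0:ploidy))
}

#' Expected neutral population SFS density
#'
#' Under the standard neutral model the density of sites with derived
#' frequency f is theta / f.
#'
#' @param theta population-scaled mutation rate (per locus or per site,
#'   the caller's convention).
#' @param f frequency in (0, 1); vectorized.
#' @return theta / f.
#' @export
expected_population_sfs <- function(theta, f) {
  stopifnot(theta >= 0)
  if (any(f <= 0 | f >= 1)) stop("f must lie in (0, 1)", call. = FALSE)
  theta / f
}

#' Expected infinite-population SFDS
#'
#' In an infinite population the SFDS factorizes: the SFS density theta/f
#' with the dosage distribution concentrated on its Hardy-Weinberg point.
#'
#' @inheritParams expected_population_sfs
#' @inheritParams hw_dosage_distribution
#' @return List with elements `density` (theta/f) and `dd`
#'   (the HW dosage distribution at f).
#' @export
expected_population_sfds <- function(theta, ploidy, f) {
  list(density = expected_population_sfs(theta, f),
       dd = hw_dosage_distribution(ploidy, f))
}

## Probability of one heterozygous DD key under the finite-sample neutral SDS.
sds_prob <- function(n, p, j, het) {
  het <- as.numeric(het)
  if (length(het) != p - 1L || any(het < 0) || any(het != floor(het)))
    return(0)
  wsum <- sum(seq_len(p - 1L) * het)
  rem <- j - wsum
  if (rem < 0 || rem %% p != 0) return(0)
  Ip <- rem / p
  I0 <- n - sum(het) - Ip
  if (I0 < 0) return(0)
  exp(lfactorial(n) - lfactorial(I0) - lfactorial(Ip) -
        sum(lfactorial(het)) + sum(het * lchoose(p, seq_len(p - 1L))) -
        lchoose(p * n, j))
}

#' Neutral finite-sample site dosage spectrum probability
#'
#' Probability of observing the heterozygous dosage distribution
#' `I = (I_1, ..., I_{p-1})` at a site with derived count j in a sample of n
#' individuals of ploidy p, under the standard neutral model (uniform
#' placement of the j derived copies over the pn chromosomes). Keys whose
#' implied homozygote counts are not non-negative integers -- in particular
#' when `j - sum(d * I_d)` is not a non-negative multiple of p -- have
#' probability 0.
#'
#' @param n sample size.
#' @param ploidy ploidy p.
#' @param j derived chromosome count, `1..p*n-1`.
#' @param het integer vector `I_1..I_{p-1}` of heterozygote counts.
#' @return A probability; the values over all valid keys at fixed j sum to 1.
#' @examples
#' expected_sds_finite(2, 2, 2, 2)  # both individuals heterozygous: 2/3
#' @export
expected_sds_finite <- function(n, ploidy, j, het) {
  check_ploidy(ploidy)
  if (j < 1 || j > ploidy * n - 1) stop("j out of range", call. = FALSE)
  sds_prob(n, ploidy, j, het)
}

#' All valid dosage distributions at a frequency class, with probabilities
#'
#' Enumerates the support of the finite-sample SDS at derived count j by a
#' bounded composition search with the divisibility constraint applied
#' first (the support is sparse).
#'
#' @inheritParams expected_sds_finite
#' @return Tibble of class `polysfs_sds` with columns `I1..I{p-1}` and
#'   `prob`.
#' @export
expected_sds <- function(n, ploidy, j) {
  check_ploidy(ploidy)
  if (j < 1 || j > ploidy * n - 1) stop("j out of range", call. = FALSE)
  keys <- enumerate_het_keys(n, ploidy, j)
  pr <- vapply(keys, function(h) sds_prob(n, ploidy, j, h), 0)
  out <- tibble::tibble(!!!setNames(
    lapply(seq_len(ploidy - 1L),
           function(d) vapply(keys, `[[`, 0L, d)),
    het_colnames(ploidy)))
  out$prob <- pr
  out <- dplyr::arrange(out, dplyr::desc(.data$prob))
  structure(out, class = c("polysfs_sds", class(out)),
            n = n, ploidy = ploidy, j = j)
}

## Heterozygous keys (I_1..I_{p-1}) with valid implied homozygote counts.
enumerate_het_keys <- function(n, p, j) {
  res <- list()
  rec <- function(d, het, used, wsum) {
    if (d == p) {
      rem <- j - wsum
      if (rem >= 0 && rem %% p == 0 && (n - used - rem %/% p) >= 0)
        res[[length(res) + 1L]] <<- het
      return(invisible())
    }
    hi <- min(n - used, (j - wsum) %/% d)
    for (v in 0:hi) rec(d + 1L, c(het, v), used + v, wsum + v * d)
  }
  rec(1L, integer(0), 0L, 0L)
  res
}

#' Expected neutral finite-sample SFDS
#'
#' Expected number of sites at derived count j with heterozygous dosage
#' distribution I, per unit theta: `(theta / j) * P(I | j)`. Summing over
#' all DDs at fixed j recovers the neutral SFS expectation theta / j.
#'
#' @inheritParams expected_sds_finite
#' @param theta population-scaled mutation rate per locus.
#' @return Expected site count.
#' @export
expected_sfds_finite <- function(theta, n, ploidy, j, het) {
  stopifnot(theta >= 0)
  (theta / j) * expected_sds_finite(n, ploidy, j, het)
}

#' Expected diploid joint frequency-heterozygosity spectrum
#'
#' The diploid special case: the expected number of sites with derived count
#' j out of 2n chromosomes and I1 heterozygous individuals. Zero whenever
#' `j - I1` is odd or the implied homozygote counts are negative.
#'
#' @param theta population-scaled mutation rate per locus.
#' @param n number of diploid individuals.
#' @param j derived count, `1..2n-1`.
#' @param I1 number of heterozygotes.
#' @return Expected site count; equals
#'   `expected_sfds_finite(theta, n, 2, j, I1)`.
#' @export
expected_joint_diploid <- function(theta, n, j, I1) {
  expected_sfds_finite(theta, n, 2L, j, I1)
}

#' Tabulate the expected finite-sample SFDS
#'
#' @param theta population-scaled mutation rate per locus.
#' @param n sample size.
#' @param ploidy ploidy p.
#' @param j frequency classes to include (default all `1..p*n-1`).
#' @return Tibble with columns `j`, `I1..I{p-1}`, `expected`.
#' @export
expected_sfds_table <- function(theta, n, ploidy, j = NULL) {
  j <- j %||% seq_len(ploidy * n - 1L)
  purrr::map_dfr(j, function(jj) {
    tab <- expected_sds(n, ploidy, jj)
    out <- tibble::as_tibble(tab[, het_colnames(ploidy)])
    out <- tibble::add_column(out, j = jj, .before = 1L)
    out$expected <- (theta / jj) * tab$prob
    out
  })
}
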