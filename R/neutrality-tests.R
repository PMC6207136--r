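## SFS-based neutrality tests for read-count data.
##
## Numerators come from the unbiased read-count estimators; denominators use
## the classical neutral variance formulas with the haploid sample size
## replaced by the read-based effective sample size (an approximation: the
## exact finite-depth variance is intractable). All coefficients are
## continued to real-valued sample sizes via digamma/trigamma so the
## statistics vary smoothly with depth; theta and theta^2 inside the
## variances use the standard unbiased plug-ins S/a_n and
## S(S-1)/(a_n^2 + b_n).

new_neutrality_test <- function(statistic_name, numerator, denominator,
                                n_eff, components) {
  structure(list(statistic = numerator / denominator,
                 statistic_name = statistic_name,
                 numerator = numerator, denominator = denominator,
                 n_eff = n_eff, components = components),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf("<neutrality_test> %s = %.4f (num %.4g / den %.4g), n_eff = %.2f\n",
              x$statistic_name, x$statistic, x$numerator, x$denominator,
              x$n_eff))
  invisible(x)
}

## Classical Tajima variance of (theta_pi - theta_W), real-valued m.
tajima_variance <- function(S, m) {
  a1 <- harmonic_a(m)
  a2 <- harmonic_b(m)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  e1 * S + e2 * S * (S - 1)
}

## Variance of (theta_pi - theta_L) under neutrality (normalized Fay-Wu H),
## real-valued m; theta plug-ins from S.
fay_wu_variance <- function(S, m) {
  a1 <- harmonic_a(m)
  bn <- harmonic_b(m)
  bn1 <- trigamma(1) - trigamma(m + 1)  # sum_{i=1}^{m} 1/i^2
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + bn)
  v1 <- (m - 2) / (6 * (m - 1))
  v2 <- (18 * m^2 * (3 * m + 2) * bn1 - (88 * m^3 + 9 * m^2 - 13 * m + 6)) /
    (9 * m * (m - 1)^2)
  v1 * th + v2 * th2
}

#' Tajima's D for polyploid read-count data
#'
#' Difference between the pairwise diversity estimator ([theta_pi()]) and
#' Watterson's estimator computed from the observed segregating sites, over
#' the classical neutral standard deviation evaluated at the read-based
#' effective sample size ([effective_sample_size()]). Near zero under the
#' stationary neutral model; negative under an excess of rare variants,
#' positive under an excess of intermediate-frequency variants.
#'
#' @param rc a [read_counts()] object with at least one observed
#'   segregating site.
#' @return A `neutrality_test` object.
#' @export
tajima_d <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  S <- sum(segregating_sites(rc))
  if (S == 0L) stop("undefined test: no segregating sites", call. = FALSE)
  m <- effective_sample_size(rc)
  if (m <= 1) stop("effective sample size must exceed 1", call. = FALSE)
  tp <- theta_pi(rc)
  tw <- theta_watterson(S, m)
  den <- sqrt(tajima_variance(S, m))
  new_neutrality_test("D", tp$value - tw$value, den, m,
                      components = list(theta_pi = tp$value,
                                        theta_w = tw$value, S = S))
}

#' Normalized Fay-Wu H for polyploid read-count data
#'
#' Contrast of pairwise diversity against the frequency-weighted estimator
#' [theta_zeng()], numerator `2 (theta_pi - theta_L)` (equivalently
#' `theta_pi - theta_H` with `theta_H = 2 theta_L - theta_pi`), normalized
#' by the neutral standard deviation at the effective sample size. Requires
#' derived orientation. Strongly negative under an excess of high-frequency
#' derived variants.
#'
#' @param rc a [read_counts()] object with at least one observed
#'   segregating site.
#' @return A `neutrality_test` object; `theta_H` is reported in the
#'   components for audit.
#' @export
fay_wu_h <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  S <- sum(segregating_sites(rc))
  if (S == 0L) stop("undefined test: no segregating sites", call. = FALSE)
  m <- effective_sample_size(rc)
  if (m <= 1) stop("effective sample size must exceed 1", call. = FALSE)
  tp <- theta_pi(rc)
  tl <- theta_zeng(rc)
  num <- 2 * (tp$value - tl$value)
  den <- 2 * sqrt(fay_wu_variance(S, m))
  new_neutrality_test("H", num, den, m,
                      components = list(theta_pi = tp$value,
                                        theta_l = tl$value,
                                        theta_h = 2 * tl$value - tp$value,
                                        S = S))
}
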