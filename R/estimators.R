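## Estimators of theta from per-individual read counts.
##
## The pairwise estimators are built from two unbiased per-site units:
##   within individual j:  U_j = (p/(p-1)) * 2 c (r - c) / (r (r - 1)),
##   between j and k:      pi_jk = (c_j (r_k - c_k) + c_k (r_j - c_j)) / (r_j r_k),
## each of which estimates the population heterozygosity 2 f (1 - f) at the
## site without bias under binomial read sampling from the dosage; the
## p/(p-1) factor converts read pairs (drawn with replacement from the p
## chromosomes) to chromosome pairs drawn without replacement. A theta
## estimate is a weighted average of these units, renormalized per site over
## the units actually available there (within terms need r >= 2, cross terms
## need both depths >= 1); without the per-site renormalization, low-coverage
## sites would enter as structural zeros and bias the estimate downward.
## With every unit present, the equal-weight average is
## (1/n^2) [ (p/(p-1)) sum_j pi_j + 2 sum_{j<k} pi_jk ].

new_theta_estimate <- function(value, estimator, rc = NULL, components = list()) {
  structure(list(value = value, estimator = estimator,
                 n = if (!is.null(rc)) nrow(rc$depth) else NA_integer_,
                 ploidy = if (!is.null(rc)) rc$ploidy else NA_integer_,
                 components = components),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("<theta_estimate> %s: theta = %.6g\n", x$estimator, x$value))
  invisible(x)
}

#' Watterson's estimator of theta
#'
#' `theta_W = S / a_n` with `a_n = sum_{j=1}^{n-1} 1/j`, continued to
#' non-integer haploid sample sizes (such as the read-based effective sample
#' size) through the digamma function. Note that S, and hence this
#' estimator, is highly sensitive to sequencing errors, which masquerade as
#' low-frequency segregating sites; prefer the pairwise estimators when the
#' error rate is non-negligible, or mask low-frequency variants first.
#'
#' @param S number of segregating sites (post filtering).
#' @param n_chrom haploid sample size; may be non-integer (e.g.
#'   [effective_sample_size()]).
#' @return A `theta_estimate`.
#' @export
theta_watterson <- function(S, n_chrom) {
  stopifnot(S >= 0)
  if (n_chrom <= 1) stop("n_chrom must exceed 1", call. = FALSE)
  a <- harmonic_a(n_chrom)
  new_theta_estimate(S / a, "watterson",
                     components = list(S = S, n_chrom = n_chrom, a_n = a))
}

#' Within-individual pairwise read diversity at a site
#'
#' Average difference between pairs of reads from one individual,
#' `2 c (r - c) / (r (r - 1))`; zero (no information) when fewer than two
#' reads. Multiplied by `p/(p-1)` this is unbiased for the individual's
#' chromosome-pair heterozygosity.
#'
#' @param depth,derived read depth(s) r and derived count(s) c; vectorized.
#' @return Per-site contributions, same length as the inputs.
#' @export
pi_within <- function(depth, derived) {
  if (any(derived > depth)) stop("derived count exceeds depth", call. = FALSE)
  ifelse(depth >= 2, 2 * derived * (depth - derived) /
           (depth * pmax(depth - 1, 1)), 0)
}

#' Between-individual pairwise read diversity at a site
#'
#' Probability that one read from individual j and one from individual k
#' differ: `(c_j (r_k - c_k) + c_k (r_j - c_j)) / (r_j r_k)`. Zero when
#' either individual has no reads.
#'
#' @param depth_j,derived_j,depth_k,derived_k depths and derived counts for
#'   the two individuals; vectorized over sites.
#' @return Per-site contributions.
#' @export
pi_between <- function(depth_j, derived_j, depth_k, derived_k) {
  if (any(derived_j > depth_j) || any(derived_k > depth_k))
    stop("derived count exceeds depth", call. = FALSE)
  ifelse(depth_j >= 1 & depth_k >= 1,
         (derived_j * (depth_k - derived_k) + derived_k * (depth_j - derived_j)) /
           pmax(depth_j * depth_k, 1), 0)
}

## Shared engine: per-site weighted average of available pair units.
## v: length-n within weights; u: n x n symmetric cross weights.
theta_pi_engine <- function(rc, v, u) {
  r <- rc$depth; cc <- rc$derived; p <- rc$ploidy
  n <- nrow(r); L <- ncol(r)
  if (n < 2) stop("need at least two individuals", call. = FALSE)
  if (all(r == 0L)) stop("undefined estimate: all depths are zero", call. = FALSE)
  up <- upper.tri(u)
  corr <- p / (p - 1)
  total <- 0
  pi_j <- numeric(n)
  pi_jk <- matrix(0, n, n, dimnames = list(rownames(r), rownames(r)))
  for (x in seq_len(L)) {
    rx <- r[, x]; cx <- cc[, x]
    win <- rx >= 2L
    cov <- rx >= 1L
    Ux <- numeric(n)
    if (any(win))
      Ux[win] <- 2 * cx[win] * (rx[win] - cx[win]) / (rx[win] * (rx[win] - 1))
    q <- ifelse(cov, cx / pmax(rx, 1L), 0)
    Bx <- outer(q, 1 - q); Bx <- Bx + t(Bx)
    avail <- outer(cov, cov) & up
    W <- sum(v[win]) + sum(u[avail])
    if (W <= 0) next
    total <- total + (sum(v[win] * corr * Ux[win]) + sum(u[avail] * Bx[avail])) / W
    pi_j <- pi_j + Ux
    pi_jk[avail] <- pi_jk[avail] + Bx[avail]
  }
  list(value = total, pi_j = setNames(pi_j, rownames(r)), pi_jk = pi_jk)
}

#' Unbiased pairwise nucleotide diversity from polyploid read counts
#'
#' Estimates theta (per locus) as the equally weighted average of the
#' within- and between-individual read-pair diversity units, corrected by
#' `p/(p-1)` for within-individual read pairs and renormalized per site over
#' the terms observable there. Unbiased at any depth, including depths below
#' the ploidy, and robust to sequencing errors relative to Watterson's
#' estimator because low-frequency alleles get negligible weight.
#'
#' @param rc a [read_counts()] object (n >= 2 individuals).
#' @return A `theta_estimate` with audit components `pi_j` (per-individual
#'   within sums) and `pi_jk` (between-pair sums).
#' @export
theta_pi <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  n <- nrow(rc$depth)
  v <- rep(1, n)
  u <- matrix(2, n, n)
  res <- theta_pi_engine(rc, v, u)
  new_theta_estimate(res$value, "pi", rc,
                     components = list(pi_j = res$pi_j, pi_jk = res$pi_jk,
                                       weights = list(v = v, u = u)))
}

#' Variance-weighted pairwise diversity (approximate MVUE)
#'
#' Same unbiased units as [theta_pi()], weighted by the inverse of their
#' approximate variances: `1/(4/rbar_j + 4/p)` for the within unit of an
#' individual with mean depth `rbar_j`, and `1/(1/rbar_j + 1/rbar_k + 2/p)`
#' for a cross pair. When all mean depths are equal the cross weight is
#' exactly twice the within weight and the estimator coincides with
#' [theta_pi()]; with heterogeneous coverage it down-weights noisy
#' low-coverage individuals and has smaller variance.
#'
#' @param rc a [read_counts()] object.
#' @return A `theta_estimate`.
#' @export
theta_pi_mvue <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  p <- rc$ploidy
  rbar <- rc$mean_depth
  if (any(rbar == 0)) {
    warning("excluding ", sum(rbar == 0),
            " individual(s) with zero mean depth")
    keep <- rbar > 0
    rc <- read_counts(rc$depth[keep, , drop = FALSE],
                      rc$derived[keep, , drop = FALSE], p)
    rbar <- rc$mean_depth
  }
  v <- 1 / (4 / rbar + 4 / p)
  u <- 1 / (outer(1 / rbar, 1 / rbar, "+") + 2 / p)
  res <- theta_pi_engine(rc, v, u)
  new_theta_estimate(res$value, "pi_mvue", rc,
                     components = list(pi_j = res$pi_j, pi_jk = res$pi_jk,
                                       weights = list(v = v, u = u)))
}

#' Effective haploid sample size of a read-count experiment
#'
#' The average number of distinct homologous chromosomes actually sequenced
#' per site: each individual with depth r contributes
#' `p * (1 - (1 - 1/p)^r)` chromosomes in expectation. Lies between 0 and
#' n*p; equals n when every individual has exactly one read, and approaches
#' n*p at high depth. Used as the plug-in sample size in the neutrality-test
#' denominators.
#'
#' @param rc a [read_counts()] object with at least one site.
#' @return A (generally non-integer) effective sample size.
#' @export
effective_sample_size <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  p <- rc$ploidy
  L <- ncol(rc$depth)
  if (L == 0L) stop("no sites", call. = FALSE)
  mean(colSums(p * (1 - (1 - 1 / p)^rc$depth)))
}

#' Zeng-type normalization factor for a site's depth profile
#'
#' For the frequency-weighted estimator [theta_zeng()], the per-site factor
#' `N_L = sum_{k=1}^{pn-1} [ 1/(pn) - A_k / k ]` where `A_k` is the
#' probability that every read at the site carries the derived allele given
#' k derived copies placed uniformly over the pn chromosomes
#' (`A_k = E[ prod_i (k_i/p)^{r_i} ]` over the multivariate hypergeometric
#' dosage assignment). It is the factor by which the expected per-site
#' derived read fraction, accumulated over the neutral frequency mix of
#' segregating sites that remain visible as polymorphisms, differs from
#' theta per site: dividing by it makes the estimator unbiased and exactly
#' recovers Zeng's `sum_j j xi_j / (pn - 1)` in the infinite-depth limit.
#' Computed by dynamic programming over the convolution of per-individual
#' count distributions; non-decreasing in every depth.
#'
#' @param depths integer vector of per-individual read depths at the site.
#' @param ploidy ploidy p.
#' @return The scalar normalization factor.
#' @export
zeng_normalizer <- function(depths, ploidy) {
  check_ploidy(ploidy)
  p <- ploidy
  n <- length(depths)
  m <- n * p
  poly <- 1
  logscale <- 0
  for (ri in depths) {
    coeff <- choose(p, 0:p) * ((0:p) / p)^ri  # 0^0 = 1 covers ri = 0
    poly <- convolve_coeffs(poly, coeff)
    mx <- max(poly)
    if (mx > 1e250) { poly <- poly / mx; logscale <- logscale + log(mx) }
  }
  k <- seq_len(m - 1L)
  A <- exp(log(pmax(poly[k + 1L], 0)) + logscale - lchoose(m, k))
  sum(1 / m - A / k)
}

convolve_coeffs <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
  res
}

#' Frequency-weighted (Zeng-type) theta estimator from read counts
#'
#' Sums, over sites whose reads show both alleles, the pooled derived read
#' fraction divided by the site's [zeng_normalizer()]. Weighting segregating
#' sites linearly in derived frequency, it is the high-frequency-sensitive
#' component of the Fay-Wu style test; requires derived orientation.
#'
#' @param rc a [read_counts()] object.
#' @return A `theta_estimate` with per-site contributions in the components.
#' @export
theta_zeng <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  p <- rc$ploidy
  seg <- segregating_sites(rc)
  if (!any(seg))
    return(new_theta_estimate(0, "zeng", rc,
                              components = list(S = 0L, per_site = numeric())))
  tot_r <- colSums(rc$depth)[seg]
  tot_c <- colSums(rc$derived)[seg]
  if (any(tot_r == 0L)) {  # cannot happen for observed-segregating sites
    warning("skipping segregating site(s) with zero total depth")
    keep <- tot_r > 0L
    tot_r <- tot_r[keep]; tot_c <- tot_c[keep]
    seg[seg][!keep] <- FALSE
  }
  nl <- apply(rc$depth[, seg, drop = FALSE], 2L, zeng_normalizer, ploidy = p)
  per_site <- (tot_c / tot_r) / nl
  new_theta_estimate(sum(per_site), "zeng", rc,
                     components = list(S = sum(seg), per_site = per_site,
                                       normalizer = nl))
}
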