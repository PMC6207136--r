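## Neutral synthetic data: dosage genotypes drawn from the finite-sample
## neutral SFDS, read counts from a binomial depth/error model, and a
## two-deme mixture exhibiting the Wahlund homozygote excess.

#' Simulate neutral autopolyploid dosage genotypes
#'
#' Draws a genotype matrix from the standard neutral model: the number of
#' segregating sites is Poisson with mean `theta * a_pn`
#' (`a_pn = sum 1/j`), each site's derived count j is drawn proportionally
#' to 1/j on `1..pn-1`, and the j derived copies are placed uniformly at
#' random over the pn chromosomes -- which samples the dosage distribution
#' exactly from its neutral finite-sample law and assigns dosages to
#' individuals exchangeably.
#'
#' @param theta population-scaled mutation rate per locus.
#' @param n_ind number of individuals n.
#' @param ploidy ploidy p.
#' @param seed optional integer; if given, sets the RNG seed first.
#' @return A [genotype_matrix()] whose columns are the segregating sites.
#' @examples
#' g <- simulate_neutral_genotypes(5, 10, 4, seed = 1)
#' empirical_sfs(g)
#' @export
simulate_neutral_genotypes <- function(theta, n_ind, ploidy, seed = NULL) {
  check_ploidy(ploidy)
  stopifnot(theta >= 0, n_ind >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- n_ind * ploidy
  S <- rpois(1, theta * harmonic_a(m))
  if (S == 0)
    return(genotype_matrix(matrix(0L, n_ind, 0), ploidy))
  js <- sample.int(m - 1L, S, replace = TRUE, prob = 1 / seq_len(m - 1L))
  d <- vapply(js, function(j)
    tabulate(ceiling(sample.int(m, j) / ploidy), nbins = n_ind),
    integer(n_ind))
  genotype_matrix(matrix(d, nrow = n_ind), ploidy)
}

#' Simulate per-individual read counts from dosage genotypes
#'
#' Depths are fixed or Poisson per individual; given depth r and dosage d,
#' the derived read count is Binomial(r, d/p), then each read is flipped to
#' the other allele independently with probability `error_rate`.
#'
#' @param G a [genotype_matrix()].
#' @param mean_depth scalar or per-individual vector of mean depths.
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @param error_rate per-read symmetric error probability in `[0, 0.5)`.
#' @param seed optional integer RNG seed.
#' @return A [read_counts()] object.
#' @export
simulate_reads <- function(G, mean_depth, depth_model = c("poisson", "fixed"),
                           error_rate = 0, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  depth_model <- match.arg(depth_model)
  stopifnot(error_rate >= 0, error_rate < 0.5, all(mean_depth >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G$dosages); L <- ncol(G$dosages); p <- G$ploidy
  mu <- rep_len(mean_depth, n)
  r <- if (depth_model == "poisson")
    matrix(rpois(n * L, mu), n, L)
  else
    matrix(as.integer(round(mu)), n, L)
  cc <- matrix(rbinom(n * L, as.vector(r), as.vector(G$dosages) / p), n, L)
  if (error_rate > 0)
    cc <- matrix(rbinom(n * L, as.vector(cc), 1 - error_rate) +
                   rbinom(n * L, as.vector(r - cc), error_rate), n, L)
  dimnames(r) <- dimnames(cc) <-
    list(rownames(G$dosages), colnames(G$dosages))
  read_counts(r, cc, p)
}

#' Simulate a pooled sample from two diverged demes (Wahlund effect)
#'
#' Per site, an ancestral frequency is drawn from the neutral 1/f density
#' and deme frequencies from a Balding-Nichols Beta around it with
#' divergence parameter `divergence` (0 = identical demes). Individuals are
#' Hardy-Weinberg *within* their deme; the pooled sample then carries a
#' homozygote excess relative to HW at the pooled frequency whenever the
#' demes have diverged.
#'
#' @param n_ind total individuals in the pooled sample.
#' @param ploidy ploidy p (2 for the classical diploid illustration).
#' @param n_sites number of sites to draw.
#' @param divergence Balding-Nichols F in `[0, 1)`; 0 gives identical deme
#'   frequencies.
#' @param mix fraction of the sample from deme 1.
#' @param seed optional integer RNG seed.
#' @return A [genotype_matrix()] with a `deme` attribute giving each
#'   individual's deme.
#' @export
simulate_two_deme_mixture <- function(n_ind, ploidy, n_sites = 100,
                                      divergence = 0.2, mix = 0.5,
                                      seed = NULL) {
  check_ploidy(ploidy)
  stopifnot(divergence >= 0, divergence < 1, mix > 0, mix < 1, n_ind >= 2)
  if (!is.null(seed)) set.seed(seed)
  n1 <- max(1L, round(mix * n_ind))
  n2 <- n_ind - n1
  grid <- seq(0.02, 0.98, length.out = 193)
  f0 <- sample(grid, n_sites, replace = TRUE, prob = 1 / grid)
  draw_deme_freq <- function(f0) {
    if (divergence == 0) return(f0)
    a <- f0 * (1 - divergence) / divergence
    b <- (1 - f0) * (1 - divergence) / divergence
    stats::rbeta(length(f0), a, b)
  }
  f1 <- draw_deme_freq(f0); f2 <- draw_deme_freq(f0)
  d <- rbind(
    matrix(rbinom(n1 * n_sites, ploidy, rep(f1, each = n1)), n1, n_sites),
    matrix(rbinom(n2 * n_sites, ploidy, rep(f2, each = n2)), n2, n_sites)
  )
  g <- genotype_matrix(d, ploidy)
  attr(g, "deme") <- rep(c(1L, 2L), c(n1, n2))
  g
}
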