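## Empirical spectra computed from dosage genotype matrices.
##
## Frequency classes are indexed by the integer derived chromosome count j
## (1..pn-1), never by floating-point frequency, so that spectrum keys are
## exact. SFDS keys store only the heterozygous dosage counts I_1..I_{p-1};
## the homozygote counts are implied by (n, j) and recovered on demand.

usable_sites <- function(G, need_orientation = TRUE) {
  d <- G$dosages
  ok <- !apply(d, 2L, anyNA)
  if (need_orientation) ok <- ok & G$ancestral_known
  ok
}

#' Empirical site frequency spectrum of a polyploid sample
#'
#' Counts segregating sites by derived allele count j out of the `p * n`
#' homologous chromosomes in the sample. Monomorphic (j = 0) and fixed
#' (j = pn) sites are excluded, as are sites with any missing genotype or
#' unknown ancestral orientation.
#'
#' @param G a [genotype_matrix()].
#' @return A tibble of class `polysfs_sfs` with columns `j` and `count`
#'   (only classes with positive count), and attributes `n`, `ploidy`,
#'   `n_segregating` and `n_dropped` (sites removed by the missing-data /
#'   orientation rule).
#' @examples
#' g <- genotype_matrix(cbind(c(4, 1, 0, 3), c(1, 2, 2, 3), c(2, 2, 2, 2)),
#'                      ploidy = 4)
#' empirical_sfs(g)  # all three SNPs at j = 8
#' @export
empirical_sfs <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- G$ploidy
  n <- nrow(G$dosages)
  keep <- usable_sites(G)
  j <- colSums(G$dosages[, keep, drop = FALSE])
  j <- j[j > 0L & j < p * n]
  tab <- table(j)
  out <- tibble::tibble(j = as.integer(names(tab)), count = as.integer(tab))
  structure(out, class = c("polysfs_sfs", class(out)),
            n = n, ploidy = p, n_segregating = length(j),
            n_dropped = sum(!keep))
}

het_colnames <- function(p) paste0("I", seq_len(p - 1L))

#' Empirical joint site frequency/dosage spectrum (SFDS)
#'
#' The most general single-site summary of a polyploid sample: the number (or
#' fraction) of segregating sites with derived count j *and* heterozygous
#' dosage distribution (I_1, ..., I_{p-1}). The homozygote counts I_0 and I_p
#' are implied by n and j and are not part of the key.
#'
#' @param G a [genotype_matrix()].
#' @param normalized if `TRUE`, masses are fractions of segregating sites
#'   (summing to 1); otherwise site counts.
#' @return A tibble of class `polysfs_sfds` with columns `j`, `I1..I{p-1}`
#'   and `mass`, plus attributes `n`, `ploidy`, `normalized`,
#'   `n_segregating`.
#' @examples
#' g <- genotype_matrix(cbind(c(4, 1, 0, 3), c(1, 2, 2, 3), c(2, 2, 2, 2)),
#'                      ploidy = 4)
#' empirical_sfds(g, normalized = TRUE)  # mass 1/3 on each of three classes
#' @export
empirical_sfds <- function(G, normalized = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- G$ploidy
  n <- nrow(G$dosages)
  keep <- usable_sites(G)
  d <- G$dosages[, keep, drop = FALSE]
  j <- colSums(d)
  seg <- j > 0L & j < p * n
  d <- d[, seg, drop = FALSE]
  j <- j[seg]
  if (ncol(d) == 0L) {
    out <- tibble::tibble(j = integer())
    for (nm in het_colnames(p)) out[[nm]] <- integer()
    out$mass <- numeric()
  } else {
    het <- apply(d, 2L, function(col) tabulate(col + 1L, nbins = p + 1L)[2:p])
    het <- matrix(het, nrow = p - 1L)  # p = 2 gives a 1-row matrix
    key <- paste(j, apply(het, 2L, paste, collapse = ","), sep = ";")
    tab <- table(key)
    parts <- strsplit(names(tab), ";", fixed = TRUE)
    jj <- as.integer(vapply(parts, `[[`, "", 1L))
    hh <- vapply(parts,
                 function(x) as.integer(strsplit(x[[2L]], ",")[[1L]]),
                 integer(p - 1L))
    hh <- t(matrix(hh, nrow = p - 1L))  # vapply drops to a vector when p = 2
    out <- tibble::tibble(j = jj)
    for (i in seq_len(p - 1L)) out[[het_colnames(p)[i]]] <- hh[, i]
    out$mass <- as.numeric(tab)
    if (normalized) out$mass <- out$mass / sum(out$mass)
    out <- dplyr::arrange(out, .data$j)
  }
  structure(out, class = c("polysfs_sfds", class(out)),
            n = n, ploidy = p, normalized = normalized,
            n_segregating = sum(seg), n_dropped = sum(!keep))
}

#' Site dosage spectrum at a fixed frequency class
#'
#' Conditions the SFDS on a derived count j: the distribution of heterozygous
#' dosage distributions among the sites at that frequency.
#'
#' @param sfds a `polysfs_sfds` tibble from [empirical_sfds()].
#' @param j derived chromosome count to condition on.
#' @return A tibble of class `polysfs_sds` with the heterozygous DD columns
#'   and `prob` (summing to 1).
#' @export
empirical_sds <- function(sfds, j) {
  stopifnot(inherits(sfds, "polysfs_sfds"))
  sub <- sfds[sfds$j == j, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no sites at frequency class j = ", j, call. = FALSE)
  out <- tibble::as_tibble(sub[, setdiff(names(sub), c("j", "mass"))])
  out$prob <- sub$mass / sum(sub$mass)
  structure(out, class = c("polysfs_sds", class(out)),
            n = attr(sfds, "n"), ploidy = attr(sfds, "ploidy"), j = j)
}

#' Recover full dosage distributions from SFDS keys
#'
#' Adds the implied homozygote counts `I0 = n - sum(I_d) - Ip` and
#' `Ip = (j - sum(d * I_d)) / p` to an SFDS (or SDS) table.
#'
#' @param x a `polysfs_sfds` or `polysfs_sds` tibble.
#' @param j frequency class, only needed for an SDS (taken from the
#'   attribute by default).
#' @return The input with integer columns `I0` and `Ip` prepended/appended.
#' @export
complete_dd <- function(x, j = attr(x, "j")) {
  p <- attr(x, "ploidy")
  n <- attr(x, "n")
  het <- as.matrix(x[, het_colnames(p), drop = FALSE])
  jj <- if ("j" %in% names(x)) x$j else rep(j, nrow(x))
  wsum <- as.vector(het %*% seq_len(p - 1L))
  Ip <- (jj - wsum) / p
  I0 <- n - rowSums(het) - Ip
  if (any(Ip != floor(Ip)) || any(Ip < 0) || any(I0 < 0))
    stop("inconsistent SFDS key: implied homozygote counts invalid",
         call. = FALSE)
  x$I0 <- as.integer(I0)
  x[[paste0("I", p)]] <- as.integer(Ip)
  x
}

#' Worst-case uncertainty of an allele frequency estimated from dosages
#'
#' The sample frequency is the mean dosage over n individuals divided by p,
#' so its standard deviation is the quadratic mean of the per-individual
#' dosage standard deviations divided by `p * sqrt(n)`. With the worst
#' possible dosage uncertainty of p/2 per individual this is `1/(2*sqrt(n))`,
#' independent of ploidy: 25 individuals bound the frequency error near 0.1
#' no matter how poor the dosage calls are.
#'
#' @param n number of individuals.
#' @param ploidy ploidy p.
#' @param dosage_sd per-individual dosage standard deviation(s); a scalar is
#'   recycled. Must lie in `[0, p/2]`. Default is the worst case p/2.
#' @return Standard deviation of the estimated allele frequency.
#' @examples
#' frequency_uncertainty_bound(25, 4)        # 0.1
#' frequency_uncertainty_bound(100, 6)       # 0.05
#' @export
frequency_uncertainty_bound <- function(n, ploidy, dosage_sd = ploidy / 2) {
  check_ploidy(ploidy)
  stopifnot(n >= 1)
  dosage_sd <- rep_len(dosage_sd, n)
  if (any(dosage_sd < 0 | dosage_sd > ploidy / 2))
    stop("dosage_sd must lie in [0, ploidy/2]", call. = FALSE)
  sqrt(mean(dosage_sd^2)) / (ploidy * sqrt(n))
}
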