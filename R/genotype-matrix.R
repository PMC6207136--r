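#' Dosage genotype matrix for a sample of autopolyploid individuals
#'
#' A thin container for per-individual, per-site allelic dosages: the number
#' of copies of the derived allele (0..p) carried by each of n individuals of
#' ploidy p at each site. Rows are individuals, columns are sites. `NA`
#' encodes a missing genotype call; sites containing any missing call are
#' excluded from spectra.
#'
#' @param dosages integer matrix (individuals x sites) with entries in
#'   `0..ploidy` or `NA`. A vector is treated as a single site.
#' @param ploidy even positive integer, the ploidy p.
#' @param ancestral_known logical, one value or one per site: whether the
#'   derived orientation is known. Sites with unknown orientation are kept in
#'   the matrix but the unfolded spectra refuse to use them.
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(rbind(c(4, 1, 2), c(1, 2, 2), c(0, 2, 2), c(3, 3, 2)),
#'                      ploidy = 4)
#' g
#' @export
genotype_matrix <- function(dosages, ploidy, ancestral_known = TRUE) {
  if (is.vector(dosages)) dosages <- matrix(dosages, ncol = 1)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  check_ploidy(ploidy)
  bad <- !is.na(dosages) & (dosages < 0L | dosages > ploidy)
  if (any(bad)) {
    stop("invalid genotype: dosage outside [0, ", ploidy, "] at ",
         sum(bad), " entr", if (sum(bad) == 1L) "y" else "ies", call. = FALSE)
  }
  if (nrow(dosages) < 1L) stop("need at least one individual", call. = FALSE)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)) && ncol(dosages) > 0L)
    colnames(dosages) <- paste0("site", seq_len(ncol(dosages)))
  ancestral_known <- rep_len(as.logical(ancestral_known), max(ncol(dosages), 1L))
  structure(list(dosages = dosages, ploidy = as.integer(ploidy),
                 ancestral_known = ancestral_known[seq_len(ncol(dosages))]),
            class = "genotype_matrix")
}

check_ploidy <- function(ploidy) {
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy < 2 || ploidy %% 2 != 0)
    stop("ploidy must be a positive even integer >= 2", call. = FALSE)
  invisible(ploidy)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites, ploidy %d\n",
              nrow(x$dosages), ncol(x$dosages), x$ploidy))
  print(head(x$dosages[, seq_len(min(ncol(x$dosages), 8L)), drop = FALSE]))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return A tibble with columns `site_id`, `individual_id`, `dosage`.
#' @method as_tibble genotype_matrix
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  tibble::tibble(
    site_id = rep(colnames(d), each = nrow(d)),
    individual_id = rep(rownames(d), times = ncol(d)),
    dosage = as.integer(d)
  )
}

#' Build a genotype matrix from a long table
#'
#' Inverse of [as_tibble.genotype_matrix()]: takes one row per
#' (site, individual) pair.
#'
#' @param tbl data frame with columns `site_id`, `individual_id`, `dosage`.
#' @param ploidy ploidy p.
#' @return A [genotype_matrix()].
#' @export
as_genotype_matrix <- function(tbl, ploidy) {
  stopifnot(all(c("site_id", "individual_id", "dosage") %in% names(tbl)))
  inds <- unique(tbl$individual_id)
  sites <- unique(tbl$site_id)
  m <- matrix(NA_integer_, length(inds), length(sites),
              dimnames = list(inds, sites))
  m[cbind(match(tbl$individual_id, inds), match(tbl$site_id, sites))] <-
    as.integer(tbl$dosage)
  genotype_matrix(m, ploidy)
}

#' Dosage distribution (DD) at a single site
#'
#' Counts the individuals at each allelic dosage class 0..p at one site: the
#' per-site "internal spectrum" of the sample. The counts always satisfy
#' `sum(I) = n` and `sum(d * I_d) = j`, the derived allele count out of the
#' `p * n` homologous chromosomes.
#'
#' @param dosages integer vector of per-individual dosages at one site.
#' @param ploidy ploidy p.
#' @return An object of class `dosage_distribution`: a list with `counts`
#'   (named vector `I0..Ip`), `n`, `derived_count` (j) and `ploidy`.
#' @examples
#' dd_at_site(c(4, 1, 0, 3), ploidy = 4)  # j = 8, DD (1,1,0,1,1)
#' @export
dd_at_site <- function(dosages, ploidy) {
  check_ploidy(ploidy)
  dosages <- as.integer(dosages)
  if (anyNA(dosages)) stop("invalid genotype: missing dosage", call. = FALSE)
  if (any(dosages < 0L | dosages > ploidy))
    stop("invalid genotype: dosage outside [0, ", ploidy, "]", call. = FALSE)
  counts <- tabulate(dosages + 1L, nbins = ploidy + 1L)
  names(counts) <- paste0("I", 0:ploidy)
  structure(list(counts = counts, n = length(dosages),
                 derived_count = sum(dosages), ploidy = as.integer(ploidy)),
            class = "dosage_distribution")
}

#' @export
print.dosage_distribution <- function(x, ...) {
  cat(sprintf("<dosage_distribution> n = %d, ploidy = %d, derived count j = %d\n",
              x$n, x$ploidy, x$derived_count))
  print(x$counts)
  invisible(x)
}

#' @method tidy dosage_distribution
#' @export
tidy.dosage_distribution <- function(x, ...) {
  tibble::tibble(dosage = 0:x$ploidy, count = as.integer(x$counts),
                 fraction = x$counts / x$n)
}
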