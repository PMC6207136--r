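#' Per-individual read counts at candidate SNP sites
#'
#' Container for the sequencing summary the HTS estimators work from: for
#' each individual i and site x, the read depth `r_i(x)` and the number of
#' those reads carrying the derived allele, `c_i(x)`. Sites filtered out
#' during SNP calling are represented with all derived counts set to zero
#' (they then contribute nothing to any estimator).
#'
#' @param depth integer matrix (individuals x sites) of read depths.
#' @param derived integer matrix of derived-allele read counts,
#'   `0 <= derived <= depth` elementwise.
#' @param ploidy ploidy p of every individual.
#' @return An object of class `read_counts` with elements `depth`,
#'   `derived`, `ploidy` and `mean_depth` (per-individual average depth
#'   over sites).
#' @export
read_counts <- function(depth, derived, ploidy) {
  check_ploidy(ploidy)
  depth <- as.matrix(depth); derived <- as.matrix(derived)
  storage.mode(depth) <- "integer"; storage.mode(derived) <- "integer"
  if (!identical(dim(depth), dim(derived)))
    stop("depth and derived must have identical dimensions", call. = FALSE)
  if (any(depth < 0L) || any(derived < 0L))
    stop("read counts must be non-negative", call. = FALSE)
  if (any(derived > depth))
    stop("derived count exceeds depth at ",
         sum(derived > depth), " entries", call. = FALSE)
  if (is.null(rownames(depth)))
    rownames(depth) <- rownames(derived) <- paste0("ind", seq_len(nrow(depth)))
  if (is.null(colnames(depth)) && ncol(depth) > 0L)
    colnames(depth) <- colnames(derived) <- paste0("site", seq_len(ncol(depth)))
  structure(list(depth = depth, derived = derived,
                 ploidy = as.integer(ploidy),
                 mean_depth = rowMeans(depth)),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf(
    "<read_counts> %d individuals x %d sites, ploidy %d, mean depth %.2f\n",
    nrow(x$depth), ncol(x$depth), x$ploidy, mean(x$depth)))
  invisible(x)
}

#' @export
dim.read_counts <- function(x) dim(x$depth)

#' Long-format view of a read-count matrix
#'
#' @param x a [read_counts()] object.
#' @param ... unused.
#' @return Tibble with columns `site_id`, `individual_id`, `depth`,
#'   `derived_count`.
#' @method as_tibble read_counts
#' @export
as_tibble.read_counts <- function(x, ...) {
  tibble::tibble(
    site_id = rep(colnames(x$depth), each = nrow(x$depth)),
    individual_id = rep(rownames(x$depth), times = ncol(x$depth)),
    depth = as.integer(x$depth),
    derived_count = as.integer(x$derived)
  )
}

#' Build a read-count matrix from a long table
#'
#' @param tbl data frame with columns `site_id`, `individual_id`, `depth`,
#'   `derived_count`.
#' @param ploidy ploidy p.
#' @return A [read_counts()] object.
#' @export
as_read_counts <- function(tbl, ploidy) {
  stopifnot(all(c("site_id", "individual_id", "depth", "derived_count")
                %in% names(tbl)))
  inds <- unique(tbl$individual_id)
  sites <- unique(tbl$site_id)
  r <- matrix(0L, length(inds), length(sites), dimnames = list(inds, sites))
  cc <- r
  idx <- cbind(match(tbl$individual_id, inds), match(tbl$site_id, sites))
  r[idx] <- as.integer(tbl$depth)
  cc[idx] <- as.integer(tbl$derived_count)
  read_counts(r, cc, ploidy)
}

#' Sites whose reads show both alleles
#'
#' A site counts as observed-segregating when the pooled reads contain at
#' least one derived and one ancestral allele. Sites whose reads are all
#' derived look like fixed differences and are excluded (the Zeng-type
#' estimator corrects for this exclusion via its normalization factor).
#'
#' @param rc a [read_counts()] object.
#' @return Logical vector over sites.
#' @export
segregating_sites <- function(rc) {
  stopifnot(inherits(rc, "read_counts"))
  tot_c <- colSums(rc$derived)
  tot_a <- colSums(rc$depth - rc$derived)
  tot_c > 0L & tot_a > 0L
}
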