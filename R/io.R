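## Plain-text interchange formats and VCF ingestion.
##
## Dosage TSV: '#'-prefixed header "#site_id<TAB>ind...", one row per site.
## Read-count TSV: '#'-prefixed header, long format
## site_id / individual_id / depth / derived_count.

#' Write / read a dosage matrix as TSV
#'
#' One row per site: `site_id` followed by the n integer dosages; header
#' line prefixed with `#`. Missing genotypes are written as `NA`.
#'
#' @param G a [genotype_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  header <- paste(c("#site_id", rownames(d)), collapse = "\t")
  body <- vapply(seq_len(ncol(d)), function(x)
    paste(c(colnames(d)[x], d[, x]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param ploidy ploidy p of the stored genotypes.
#' @export
read_dosage_tsv <- function(path, ploidy) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  inds <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(body) == 0)
    return(genotype_matrix(matrix(NA_integer_, length(inds), 0), ploidy))
  sites <- vapply(body, `[[`, "", 1L)
  d <- vapply(body, function(x) suppressWarnings(as.integer(x[-1])),
              integer(length(inds)))
  d <- matrix(d, nrow = length(inds), dimnames = list(inds, sites))
  genotype_matrix(d, ploidy)
}

#' Write / read per-individual read counts as TSV
#'
#' Long format with a `#`-prefixed header:
#' `site_id / individual_id / depth / derived_count`.
#'
#' @param rc a [read_counts()] object.
#' @param path file path.
#' @return `write_readcount_tsv` returns `path` invisibly;
#'   `read_readcount_tsv` returns a [read_counts()] object.
#' @export
write_readcount_tsv <- function(rc, path) {
  stopifnot(inherits(rc, "read_counts"))
  tbl <- as_tibble(rc)
  lines <- c("#site_id\tindividual_id\tdepth\tderived_count",
             sprintf("%s\t%s\t%d\t%d", tbl$site_id, tbl$individual_id,
                     tbl$depth, tbl$derived_count))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_readcount_tsv
#' @param ploidy ploidy p.
#' @export
read_readcount_tsv <- function(path, ploidy) {
  tbl <- utils::read.delim(path, header = FALSE, comment.char = "",
                           skip = 1L, col.names = c("site_id",
                                                    "individual_id",
                                                    "depth",
                                                    "derived_count"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  as_read_counts(tibble::as_tibble(tbl), ploidy)
}

## -- VCF ingestion (via vcfR) ------------------------------------------

vcf_basics <- function(path, ploidy) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning("skipping ", sum(multi), " multi-allelic record(s)")
  info <- vcf@fix[, "INFO"]
  aa <- sub(".*(?:^|;)AA=([^;]+).*", "\\1", info)
  aa[!grepl("(^|;)AA=", info)] <- NA_character_
  list(vcf = vcf, fix = fix, keep = !multi, aa = toupper(aa),
       site_id = paste(fix[, "CHROM"], fix[, "POS"], sep = ":"))
}

## Orientation: +1 if ALT is derived, -1 if REF is derived (AA == ALT),
## NA if unknown.
vcf_orientation <- function(basics) {
  ref <- toupper(basics$fix[, "REF"]); alt <- toupper(basics$fix[, "ALT"])
  out <- rep(NA_integer_, length(ref))
  out[!is.na(basics$aa) & basics$aa == ref] <- 1L
  out[!is.na(basics$aa) & basics$aa == alt] <- -1L
  out
}

#' Read dosage genotypes from a VCF
#'
#' Extracts per-individual allelic dosages from genotype (GT) fields of
#' uniform ploidy p. The derived allele is identified from the ancestral
#' allele INFO tag (default `AA`); records without it, or where it matches
#' neither allele, are dropped with a message. Multi-allelic records are
#' skipped with a warning; a missing or partially missing genotype becomes
#' `NA` (such sites are excluded from spectra downstream). Mixed ploidy in
#' GT is a hard error.
#'
#' @param path VCF file (plain or gzipped).
#' @param ploidy expected uniform ploidy p.
#' @param ancestral_tag INFO key carrying the ancestral allele.
#' @return A [genotype_matrix()]; site ids are `CHROM:POS`.
#' @export
read_vcf_dosages <- function(path, ploidy, ancestral_tag = "AA") {
  check_ploidy(ploidy)
  b <- vcf_basics(path, ploidy)
  gt <- vcfR::extract.gt(b$vcf, element = "GT")
  orient <- vcf_orientation(b)
  no_aa <- b$keep & is.na(orient)
  if (any(no_aa))
    message("dropping ", sum(no_aa),
            " record(s) without usable ancestral-allele annotation")
  keep <- b$keep & !is.na(orient)
  gt <- gt[keep, , drop = FALSE]
  orient <- orient[keep]
  ids <- b$site_id[keep]
  n_alt <- function(g, record) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != ploidy)
      stop("mixed ploidy: record ", record, " has GT of ploidy ",
           length(al), ", expected ", ploidy, call. = FALSE)
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  d <- matrix(NA_integer_, ncol(gt), nrow(gt),
              dimnames = list(colnames(gt), ids))
  for (x in seq_len(nrow(gt))) {
    alt_count <- vapply(gt[x, ], n_alt, integer(1), record = ids[x])
    d[, x] <- if (orient[x] == 1L) alt_count else ploidy - alt_count
  }
  genotype_matrix(d, ploidy)
}

#' Read per-individual read counts from a VCF
#'
#' Uses the allelic-depth (AD) FORMAT field: depth is the sum of the two
#' components, the derived count is the component of the derived allele
#' (oriented with the ancestral-allele INFO tag). Records whose site QUAL
#' is below `min_qual` are retained but with all derived counts zeroed, the
#' convention for filtered SNPs. A VCF without AD is a hard error (supply a
#' read-count TSV instead).
#'
#' @inheritParams read_vcf_dosages
#' @param min_qual PHRED site-quality threshold below which a record's
#'   derived counts are zeroed (default 15).
#' @return A [read_counts()] object.
#' @export
read_vcf_readcounts <- function(path, ploidy, ancestral_tag = "AA",
                                min_qual = 15) {
  check_ploidy(ploidy)
  b <- vcf_basics(path, ploidy)
  fmt <- b$vcf@gt[, 1]
  if (!any(grepl("(^|:)AD(:|$)", fmt)))
    stop("VCF has no per-sample AD field; provide a read-count TSV ",
         "(read_readcount_tsv) instead", call. = FALSE)
  ad <- vcfR::extract.gt(b$vcf, element = "AD")
  orient <- vcf_orientation(b)
  no_aa <- b$keep & is.na(orient)
  if (any(no_aa))
    message("dropping ", sum(no_aa),
            " record(s) without usable ancestral-allele annotation")
  keep <- b$keep & !is.na(orient)
  ad <- ad[keep, , drop = FALSE]
  orient <- orient[keep]
  ids <- b$site_id[keep]
  qual <- suppressWarnings(as.numeric(b$fix[keep, "QUAL"]))
  low_q <- !is.na(qual) & qual < min_qual
  parse_ad <- function(a) {
    if (is.na(a)) return(c(0L, 0L))
    parts <- suppressWarnings(as.integer(strsplit(a, ",")[[1]]))
    if (length(parts) < 2 || anyNA(parts)) return(c(0L, 0L))
    parts[1:2]
  }
  n_ind <- ncol(ad)
  r <- cc <- matrix(0L, n_ind, nrow(ad), dimnames = list(colnames(ad), ids))
  for (x in seq_len(nrow(ad))) {
    parts <- vapply(ad[x, ], parse_ad, integer(2))
    r[, x] <- parts[1L, ] + parts[2L, ]
    der <- if (orient[x] == 1L) parts[2L, ] else parts[1L, ]
    cc[, x] <- if (low_q[x]) 0L else der
  }
  read_counts(r, cc, ploidy)
}
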