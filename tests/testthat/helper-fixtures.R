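# The four-tetraploid-individual genotype matrix with three SNPs of
# frequency 50% and heterozygous DDs (1,0,1), (1,2,1), (0,4,0).
fig_example_matrix <- function() {
  genotype_matrix(cbind(snp1 = c(4L, 1L, 0L, 3L),
                        snp2 = c(1L, 2L, 2L, 3L),
                        snp3 = c(2L, 2L, 2L, 2L)),
                  ploidy = 4)
}

# A small VCF text fixture written to a tempfile: tetraploid GT + AD fields,
# AA ancestral annotation, one low-quality record, one multi-allelic record,
# one record with a missing call and one without AA.
write_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    # ALT derived, high quality
    paste("chr1", "100", ".", "A", "G", "50", "PASS", "AA=A", "GT:DP:AD",
          "0/1/1/0:8:6,2", "0/0/0/0:6:6,0", sep = "\t"),
    # REF derived (AA == ALT): dosages flip
    paste("chr1", "200", ".", "C", "T", "50", "PASS", "AA=T", "GT:DP:AD",
          "0/1/1/1:10:3,7", "1/1/1/1:4:0,4", sep = "\t"),
    # low site quality: derived read counts zeroed
    paste("chr1", "300", ".", "G", "A", "5", "PASS", "AA=G", "GT:DP:AD",
          "0/0/0/1:9:7,2", "0/0/0/0:5:5,0", sep = "\t"),
    # multi-allelic: skipped with warning
    paste("chr1", "400", ".", "T", "A,C", "50", "PASS", "AA=T", "GT:DP:AD",
          "0/0/1/2:6:2,2,2", "0/0/0/0:6:6,0,0", sep = "\t"),
    # missing call in sample 2
    paste("chr1", "500", ".", "A", "C", "50", "PASS", "AA=A", "GT:DP:AD",
          "0/0/1/1:7:3,4", "./././.:0:0,0", sep = "\t"),
    # no ancestral annotation: dropped
    paste("chr1", "600", ".", "G", "T", "50", "PASS", "DP=4", "GT:DP:AD",
          "0/0/0/1:6:5,1", "0/0/0/0:4:4,0", sep = "\t")
  )
  writeLines(lines, path)
  path
}
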