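# Shared fixture builders (all data generated in code).

# The study-style pool layout: four recessive bulks of 5 plants and two
# dominant bulks of 6.
study_pools <- function() {
  data.frame(pool = c("M1", "M2", "M3", "M4", "W1", "W2"),
             class = rep(c("recessive", "dominant"), c(4, 2)),
             n = rep(c(5L, 6L), c(4, 2)))
}

two_locus_design <- function(rf, marker = "mk1") {
  cross_design(data.frame(name = c("causal", marker), rf = c(NA, rf)),
               causal = "causal")
}

# Six-record hand fixture for the variant filter: one failure per rule plus
# two clean records.
filter_fixture <- function() {
  libs <- c("parentM", "parentW", "M1", "W1")
  rec <- data.frame(snv = paste0("s", 1:6),
                    contig = "ctg1", pos = 1:6,
                    ref = c("A", "A", "A", "A", "A", "C"),
                    alt = c("G", "AT", "G", "G", "G", "T"),
                    qual = c(19.9, 60, 60, 60, 60, 60))
  depths <- list(
    parentM = cbind(ref = c(0, 0, 30, 0, 0, 0), alt = c(50, 50, 30, 50, 50, 50)),
    parentW = cbind(ref = c(60, 60, 60, 60, 60, 60), alt = c(0, 0, 0, 0, 0, 0)),
    M1 = cbind(ref = c(5, 5, 5, 4, 10, 12), alt = c(40, 40, 40, 35, 55, 50)),
    W1 = cbind(ref = c(30, 30, 30, 30, 30, 28), alt = c(15, 15, 15, 15, 15, 14)))
  for (lib in libs) {
    rec[[paste0(lib, ".ref")]] <- depths[[lib]][, "ref"]
    rec[[paste0(lib, ".alt")]] <- depths[[lib]][, "alt"]
  }
  roles <- list(parent_mut = "parentM", parent_wt = "parentW",
                pools = data.frame(pool = c("M1", "W1"),
                                   class = c("recessive", "dominant"),
                                   n = c(5L, 6L)))
  list(records = rec, roles = roles)
}

write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parentM", "parentW", "M1", "W1", sep = "\t"),
    paste("ctg1", "101", ".", "A", "G", "60", ".", ".", "GT:AD",
          "1/1:0,50", "0/0:48,0", "./.:10,30", "./.:20,21", sep = "\t"),
    paste("ctg2", "55", ".", "T", "TA", "60", ".", ".", "GT:AD",
          "1/1:0,44", "0/0:50,0", "./.:12,30", "./.:20,20", sep = "\t"),
    paste("ctg3", "7", ".", "C", "A", "12", ".", ".", "GT:AD",
          "1/1:0,44", "0/0:50,0", "./.:12,30", "./.:20,20", sep = "\t"))
  writeLines(lines, path)
  path
}

table3_path <- function() {
  system.file("extdata", "f2_markers.tsv", package = "poollink")
}
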