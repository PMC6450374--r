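# Variant ingestion and the three exclusion rules: minimum site quality,
# biallelic single-nucleotide substitutions with assignable parental origin,
# and minimum coverage in every library. Records carry per-library (ref, alt)
# allele depths in columns "<library>.ref" / "<library>.alt".

.depth_cols <- function(lib) paste0(lib, c(".ref", ".alt"))

.check_roles <- function(records, roles) {
  stopifnot(is.list(roles),
            all(c("parent_mut", "parent_wt", "pools") %in% names(roles)),
            all(c("pool", "class", "n") %in% names(roles$pools)))
  libs <- c(roles$parent_mut, roles$parent_wt, roles$pools$pool)
  for (lib in libs) {
    miss <- setdiff(.depth_cols(lib), names(records))
    if (length(miss)) {
      stop("records lack depth column(s) for library '", lib, "': ",
           paste(miss, collapse = ", "))
    }
  }
  invisible(libs)
}

#' Assign the parental origin of a biallelic SNV
#'
#' The mutant-parent allele is the allele carried (near-)homozygously by the
#' mutant-parent library. Assignment fails — the variant counts as novel —
#' when either parent library shows its minor allele above the
#' heterozygosity tolerance, has no counted reads, or when both parents
#' carry the same major allele (no inter-parent polymorphism).
#'
#' @param parent_mut,parent_wt Length-2 numeric vectors of (ref, alt) depths
#'   for the mutant-parent and wild-type-parent libraries.
#' @param het_tol Maximum tolerated minor-allele depth fraction per parent.
#' @return `"ref"` or `"alt"` (the mutant-parent allele), or `NA_character_`
#'   when unassignable.
#' @examples
#' assign_origin(c(0, 60), c(50, 0))   # "alt"
#' assign_origin(c(50, 0), c(55, 0))   # NA: parents agree
#' @export
assign_origin <- function(parent_mut, parent_wt, het_tol = 0.1) {
  major <- function(d) {
    tot <- sum(d)
    if (tot == 0) return(NA_character_)
    if (min(d) / tot > het_tol) return(NA_character_)
    if (d[1L] >= d[2L]) "ref" else "alt"
  }
  am <- major(as.numeric(parent_mut))
  aw <- major(as.numeric(parent_wt))
  if (is.na(am) || is.na(aw) || am == aw) NA_character_ else am
}

#' Filter called variants by the pooled-mapping exclusion rules
#'
#' Applies, in this fixed precedence, the rules: (1) `qual` — site QUAL
#' below `min_qual`; (2) `not_snv` — ref or alt is not a single nucleotide
#' (indels, multi-allelic records); (3) `novel` — parental origin not
#' assignable (the variant is not a clean homozygous difference between the
#' parents); (4) `coverage` — total counted depth below `min_cov` in any
#' library, parents and pools alike. Each rejected record carries exactly
#' the first reason that applies.
#'
#' @param records Data frame with columns `snv`, `ref`, `alt`, `qual` and
#'   per-library depth columns `<library>.ref` / `<library>.alt`.
#' @param roles List with `parent_mut`, `parent_wt` (library names) and
#'   `pools` (data frame `pool`, `class`, `n`).
#' @param min_qual,min_cov Thresholds of rules (1) and (4).
#' @param het_tol Parental heterozygosity tolerance, see [assign_origin()].
#' @return A list: `retained` (with a `mut_allele` column) and `rejected`
#'   (with a `reason` column). Every input record lands in exactly one of
#'   the two.
#' @export
filter_snvs <- function(records, roles, min_qual = 20, min_cov = 40,
                        het_tol = 0.1) {
  libs <- .check_roles(records, roles)
  nrec <- nrow(records)
  reason <- rep(NA_character_, nrec)
  mut_allele <- rep(NA_character_, nrec)

  is_snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    grepl("^[ACGT]$", records$ref) & grepl("^[ACGT]$", records$alt)
  for (i in seq_len(nrec)) {
    if (records$qual[i] < min_qual) {
      reason[i] <- "qual"
      next
    }
    if (!is_snv[i]) {
      reason[i] <- "not_snv"
      next
    }
    ori <- assign_origin(
      as.numeric(records[i, .depth_cols(roles$parent_mut)]),
      as.numeric(records[i, .depth_cols(roles$parent_wt)]),
      het_tol = het_tol)
    if (is.na(ori)) {
      reason[i] <- "novel"
      next
    }
    depths <- vapply(libs, function(lib) {
      sum(as.numeric(records[i, .depth_cols(lib)]))
    }, numeric(1L))
    if (any(depths < min_cov)) {
      reason[i] <- "coverage"
      next
    }
    mut_allele[i] <- ori
  }
  keep <- is.na(reason)
  retained <- records[keep, , drop = FALSE]
  retained$mut_allele <- mut_allele[keep]
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = retained, rejected = rejected)
}

#' Per-SNV, per-pool mutant-parent read counts
#'
#' For each retained SNV and each pool library, `m` is the depth of the
#' mutant-parent allele and `c = m +` the depth of the wild-type-parent
#' allele; reads of any other allele are not counted. Pools with `c = 0`
#' are flagged uninformative.
#'
#' @param retained Retained records from [filter_snvs()] (must carry
#'   `mut_allele`).
#' @param roles Role mapping as in [filter_snvs()].
#' @return Long data frame `snv`, `pool`, `class`, `n`, `m`, `c`,
#'   `uninformative` — ready for [estimate_rf_all()].
#' @export
pool_counts <- function(retained, roles) {
  stopifnot("mut_allele" %in% names(retained))
  .check_roles(retained, roles)
  out <- list()
  for (j in seq_len(nrow(roles$pools))) {
    p <- roles$pools$pool[j]
    ref <- as.numeric(retained[[paste0(p, ".ref")]])
    alt <- as.numeric(retained[[paste0(p, ".alt")]])
    m <- ifelse(retained$mut_allele == "alt", alt, ref)
    cc <- ref + alt
    out[[j]] <- data.frame(snv = retained$snv, pool = p,
                           class = roles$pools$class[j],
                           n = roles$pools$n[j], m = m, c = cc,
                           uninformative = cc == 0)
  }
  res <- do.call(rbind, out)
  res[order(res$snv, res$pool), , drop = FALSE]
}

#' Read variant records from a VCF
#'
#' Extracts CHROM/POS/REF/ALT, site QUAL and the per-sample AD allele depths
#' into the flat record table used by [filter_snvs()]. Multi-allelic records
#' keep their comma-separated ALT string (and only the first two AD fields),
#' and are subsequently rejected by the `not_snv` rule.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param roles Role mapping; library names must match VCF sample names.
#' @return Record data frame with one row per variant.
#' @export
read_snv_vcf <- function(path, roles) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  rec <- data.frame(snv = paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                    contig = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    qual = as.numeric(fix[, "QUAL"]),
                    row.names = NULL)
  libs <- c(roles$parent_mut, roles$parent_wt, roles$pools$pool)
  miss <- setdiff(libs, colnames(ad))
  if (length(miss)) {
    stop("VCF lacks sample(s): ", paste(miss, collapse = ", "))
  }
  for (lib in libs) {
    parts <- strsplit(ifelse(is.na(ad[, lib]), "0,0", ad[, lib]), ",")
    rec[[paste0(lib, ".ref")]] <- as.integer(vapply(parts, `[`, "", 1L))
    rec[[paste0(lib, ".alt")]] <- as.integer(vapply(parts, function(x) {
      if (length(x) >= 2L) x[2L] else "0"
    }, ""))
  }
  rec
}
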