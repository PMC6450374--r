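# CAPS marker screening: IUPAC restriction-motif matching on both strands,
# fragment-pattern comparison between the two alleles of an amplicon, and
# coding-consequence reports for substitutions and single-base deletions.
# Motif start positions stand in for cleavage sites; enzyme-specific cut
# offsets are not modelled (a documented approximation — diagnosis needs
# only pattern differences, not exact fragment boundaries).

.IUPAC_RE <- "^[ACGTRYSWKMBDHVN]+$"

.check_dna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]+$", seq)) stop(what, " must use the ACGTN alphabet")
  seq
}

#' Find restriction-motif matches on both strands
#'
#' Matches an IUPAC-ambiguity motif (case-insensitive; `N` matches any
#' base) against the forward strand and against the reverse complement,
#' reporting 1-based start positions in forward-strand coordinates.
#' Overlapping matches are reported; a palindromic motif matches both
#' strands at the same position and is counted once.
#'
#' @param seq DNA sequence (ACGTN).
#' @param motif Recognition motif in IUPAC code, e.g. `"CCNNGG"`.
#' @return Sorted integer vector of match start positions.
#' @examples
#' find_sites("GGTTAAC", "TTAA")      # 3
#' find_sites("ACCATGGA", "CCNNGG")   # 2
#' @export
find_sites <- function(seq, motif) {
  seq <- .check_dna(seq)
  motif <- toupper(motif)
  if (!nzchar(motif) || !grepl(.IUPAC_RE, motif)) {
    stop("invalid IUPAC character in motif")
  }
  subject <- Biostrings::DNAString(seq)
  hit <- function(pat) {
    Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = "subject"))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  sort(unique(c(hit(motif), hit(rc))))
}

# Fragment-length multiset of a digest, with cuts placed at the motif start
# (a cut at position p separates p-1 from p; a match at position 1 cuts
# nothing off).
.fragment_lengths <- function(seq, motif) {
  p <- find_sites(seq, motif)
  p <- p[p > 1L]
  sort(diff(c(1L, p, nchar(seq) + 1L)))
}

#' Screen an allele pair for diagnostic restriction enzymes
#'
#' An enzyme is diagnostic for a CAPS assay when the multiset of digest
#' fragment lengths differs between the two allele sequences — this covers
#' both gained/lost sites and sites shifted by an indel while the site
#' count stays equal.
#'
#' @param allele_a,allele_b The amplicon sequence of each parental allele.
#' @param panel Data frame of candidate enzymes with columns `name` and
#'   `motif` (IUPAC).
#' @return Data frame per enzyme: `name`, `motif`, `sites_a`, `sites_b`,
#'   `diagnostic`, and list columns `frags_a`, `frags_b` with the fragment
#'   lengths. Symmetric in the allele order up to column naming.
#' @export
screen_caps <- function(allele_a, allele_b, panel) {
  stopifnot(all(c("name", "motif") %in% names(panel)))
  allele_a <- .check_dna(allele_a, "allele_a")
  allele_b <- .check_dna(allele_b, "allele_b")
  if (allele_a == allele_b) stop("allele sequences are identical")
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    fa <- .fragment_lengths(allele_a, panel$motif[i])
    fb <- .fragment_lengths(allele_b, panel$motif[i])
    data.frame(name = panel$name[i], motif = panel$motif[i],
               sites_a = length(find_sites(allele_a, panel$motif[i])),
               sites_b = length(find_sites(allele_b, panel$motif[i])),
               diagnostic = !identical(fa, fb),
               frags_a = I(list(fa)), frags_b = I(list(fb)))
  })
  do.call(rbind, rows)
}

.translate_to_stop <- function(s) {
  ncod <- nchar(s) %/% 3L
  if (ncod == 0L) return(list(protein = "", stop_found = FALSE, term_nt = 0L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, 3L * ncod)), if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(protein = substr(aa, 1L, stop_at - 1L), stop_found = TRUE,
         term_nt = 3L * stop_at)
  } else {
    list(protein = aa, stop_found = FALSE, term_nt = nchar(s))
  }
}

#' Coding consequence of a substitution or single-base deletion
#'
#' Applies a variant in a minimal HGVS-like coding notation (`"c.C319T"`
#' for a substitution, `"c.C319del"` for a single-base deletion) to a CDS,
#' translates reference and mutant up to the first stop codon, and
#' summarises the protein change.
#'
#' @param cds Reference coding sequence starting at the start codon; its
#'   length must be a multiple of 3.
#' @param variant Variant string; the stated reference base must match the
#'   CDS at the given 1-based position.
#' @return A list: `protein_ref`, `protein_mut`, `ref_length`,
#'   `mut_length`, `frameshift`, `premature_stop` (mutant protein strictly
#'   shorter than reference), `stop_found_mut` (whether the mutant frame
#'   still reaches a stop codon) and `n_erroneous` (mutant residues from
#'   the first differing position onward).
#' @examples
#' variant_effect("ATGAAATAA", "c.A4del")$protein_mut   # "MN"
#' @export
variant_effect <- function(cds, variant) {
  cds <- .check_dna(cds, "cds")
  if (nchar(cds) %% 3L != 0L) stop("reference CDS length must be a multiple of 3")
  m <- regmatches(variant, regexec("^c\\.([ACGT])([0-9]+)(del|[ACGT])$", variant))[[1L]]
  if (length(m) == 0L) {
    stop("variant must look like 'c.C319T' (substitution) or 'c.C319del' (deletion)")
  }
  ref_base <- m[2L]
  pos <- as.integer(m[3L])
  op <- m[4L]
  if (pos < 1L || pos > nchar(cds)) stop("variant position out of CDS range")
  if (substr(cds, pos, pos) != ref_base) {
    stop(sprintf("reference base mismatch at position %d: CDS has %s, variant states %s",
                 pos, substr(cds, pos, pos), ref_base))
  }
  mut <- if (op == "del") {
    paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + 1L, nchar(cds)))
  } else {
    paste0(substr(cds, 1L, pos - 1L), op, substr(cds, pos + 1L, nchar(cds)))
  }
  tr_ref <- .translate_to_stop(cds)
  tr_mut <- .translate_to_stop(mut)
  pr <- tr_ref$protein
  pm <- tr_mut$protein
  shared <- min(nchar(pr), nchar(pm))
  first_diff <- NA_integer_
  for (i in seq_len(shared)) {
    if (substr(pr, i, i) != substr(pm, i, i)) {
      first_diff <- i
      break
    }
  }
  if (is.na(first_diff) && nchar(pm) != nchar(pr)) first_diff <- shared + 1L
  n_err <- if (is.na(first_diff)) 0L else max(0L, nchar(pm) - first_diff + 1L)
  list(protein_ref = pr,
       protein_mut = pm,
       ref_length = nchar(pr),
       mut_length = nchar(pm),
       frameshift = op == "del",
       premature_stop = nchar(pm) < nchar(pr),
       stop_found_mut = tr_mut$stop_found,
       n_erroneous = n_err)
}
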