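# Candidate reporting: ranking SNVs/genes by estimated recombination
# fraction, building a candidate genomic interval around anchor homologs,
# and intersecting it with an externally computed differential-expression
# table. Differential expression itself is consumed, never computed here.

#' Rank recombination-fraction estimates
#'
#' Orders estimates ascending by the point estimate; ties are broken by LOD
#' (descending) and then by identifier. SNVs flagged by the exclusion test
#' are listed separately, not ranked.
#'
#' @param estimates Data frame with columns `snv` (or `id`), `alpha_hat`,
#'   optionally `lod` and `excluded` — e.g. the output of
#'   [estimate_rf_all()].
#' @return List with `ranked` and `excluded` data frames; together they are
#'   a permutation of the input rows.
#' @export
rank_by_rf <- function(estimates) {
  id_col <- if ("snv" %in% names(estimates)) "snv" else "id"
  stopifnot(id_col %in% names(estimates), "alpha_hat" %in% names(estimates))
  lod <- if ("lod" %in% names(estimates)) estimates$lod else rep(0, nrow(estimates))
  lod[is.na(lod)] <- -Inf
  excl <- if ("excluded" %in% names(estimates)) {
    estimates$excluded %in% TRUE
  } else {
    rep(FALSE, nrow(estimates))
  }
  keep <- estimates[!excl, , drop = FALSE]
  ord <- order(keep$alpha_hat, -lod[!excl], keep[[id_col]])
  list(ranked = keep[ord, , drop = FALSE],
       excluded = estimates[excl, , drop = FALSE])
}

#' Expand anchor positions into a candidate interval
#'
#' Takes the span of the anchor genes' homolog positions and lengthens it
#' by `factor` times the span on each side, clipped at zero; the interval
#' is half-open `[start, end)` in base pairs.
#'
#' @param positions Numeric anchor positions (>= 2) on one chromosome.
#' @param chrom Optional chromosome name, carried through.
#' @param factor Per-side expansion as a multiple of the anchor span.
#' @return List with `chrom`, `start`, `end`.
#' @examples
#' define_interval(c(10000, 12000))   # [4000, 18000)
#' @export
define_interval <- function(positions, chrom = NULL, factor = 3) {
  stopifnot(length(positions) >= 2, all(positions >= 0), factor >= 0)
  if (!is.null(chrom) && length(unique(chrom)) > 1L) {
    stop("anchor positions lie on different chromosomes")
  }
  span <- max(positions) - min(positions)
  list(chrom = if (is.null(chrom)) NA_character_ else unique(chrom),
       start = max(0, min(positions) - factor * span),
       end = max(positions) + factor * span)
}

#' Filter candidate genes by interval and differential expression
#'
#' Keeps genes whose homolog position falls inside the half-open interval
#' and whose adjusted p-value is strictly below `alpha`, splitting them by
#' expression direction (sign of the log2 fold change). In-interval genes
#' with a missing adjusted p-value are reported separately as
#' "not calculated".
#'
#' @param genes Data frame with columns `id`, `pos`, `log2fc`, `padj`
#'   (`NA` allowed) and optionally `chrom`.
#' @param interval Interval from [define_interval()] (or any list with
#'   `chrom`, `start`, `end`).
#' @param alpha Adjusted-p-value threshold (strict inequality).
#' @return List with `significant` (plus a `direction` column, `"up"` /
#'   `"down"`) and `not_calculated`.
#' @export
candidate_filter <- function(genes, interval, alpha = 0.05) {
  stopifnot(all(c("id", "pos", "log2fc", "padj") %in% names(genes)),
            is.numeric(alpha), length(alpha) == 1L)
  if (!is.null(genes$padj) && any(!is.na(genes$padj) &
                                  (genes$padj < 0 | genes$padj > 1))) {
    stop("adjusted p-values must lie in [0, 1]")
  }
  inside <- genes$pos >= interval$start & genes$pos < interval$end
  if ("chrom" %in% names(genes) && !is.na(interval$chrom)) {
    inside <- inside & genes$chrom == interval$chrom
  }
  hit <- inside & !is.na(genes$padj) & genes$padj < alpha
  sig <- genes[hit, , drop = FALSE]
  sig$direction <- ifelse(sig$log2fc >= 0, "up", "down")
  list(significant = sig,
       not_calculated = genes[inside & is.na(genes$padj), , drop = FALSE])
}
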