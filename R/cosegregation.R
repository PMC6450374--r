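# Exact two-point linkage statistics on individually genotyped F2 plants:
# six-cell marker-genotype x phenotype tables, multinomial ML recombination
# fractions, LOD scores, joint-segregation chi-square, pairwise marker RF
# matrices and exhaustive linear ordering of a handful of loci.

#' Build a six-cell F2 segregation table
#'
#' Counts of marker genotype by phenotype class for one codominant marker
#' scored on an F2 population. `A` denotes the allele inherited from the
#' wild-type parent (in coupling with the dominant causal allele); `dom` /
#' `rec` are the dominant- and recessive-phenotype classes.
#'
#' @param counts Numeric vector of six non-negative counts in the order
#'   `dom_AA, dom_Aa, dom_aa, rec_AA, rec_Aa, rec_aa`.
#' @return Named numeric vector of class `segregation_table`.
#' @examples
#' segregation_table(c(30, 47, 0, 0, 1, 30))
#' @export
segregation_table <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 6L, all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("segregation table is empty")
  names(counts) <- c("dom_AA", "dom_Aa", "dom_aa", "rec_AA", "rec_Aa", "rec_aa")
  class(counts) <- "segregation_table"
  counts
}

.as_segtable <- function(x) {
  if (inherits(x, "segregation_table")) x else segregation_table(x)
}

#' Six-cell probabilities of the coupling-phase F2 model
#'
#' Joint probabilities (summing to 1) of marker genotype and phenotype class
#' for a codominant marker at recombination fraction `alpha` from a
#' recessive causal locus, both mutant alleles in coupling: dominant class
#' \eqn{(1-\alpha^2)/4}, \eqn{(1-\alpha+\alpha^2)/2},
#' \eqn{\alpha(2-\alpha)/4}; recessive class \eqn{\alpha^2/4},
#' \eqn{\alpha(1-\alpha)/2}, \eqn{(1-\alpha)^2/4}.
#'
#' @param alpha Recombination fraction in \[0, 0.5\].
#' @return Named numeric vector over the six cells.
#' @export
f2_cell_probs <- function(alpha) {
  stopifnot(alpha >= 0, alpha <= 0.5)
  c(dom_AA = (1 - alpha^2) / 4,
    dom_Aa = (1 - alpha + alpha^2) / 2,
    dom_aa = alpha * (2 - alpha) / 4,
    rec_AA = alpha^2 / 4,
    rec_Aa = alpha * (1 - alpha) / 2,
    rec_aa = (1 - alpha)^2 / 4)
}

.segtable_loglik <- function(alpha, counts) {
  p <- f2_cell_probs(alpha)
  pos <- counts > 0
  if (any(pos & p == 0)) return(-Inf)
  sum(counts[pos] * log(p[pos]))
}

# Repulsion guard: the coupling model is asserted, not inferred. Only a
# decisive repulsion signal (allele labels swapped fit better by >= 3 LOD
# while the coupling fit is at the 0.5 cap) is treated as an error.
.check_phase <- function(counts, rf, loglik_at_rf) {
  if (rf < 0.5 - 1e-6) return(invisible(TRUE))
  flipped <- counts[c(3L, 2L, 1L, 6L, 5L, 4L)]
  g <- seq(0, 0.5, by = 1e-3)
  llf <- vapply(g, .segtable_loglik, 0, counts = flipped)
  lodf <- (max(llf) - llf[length(llf)]) / log(10)
  if (lodf >= 3) {
    stop("table appears to be in repulsion phase (allele labels swapped): ",
         "relabel the marker alleles so that 'A' is the wild-type-parent allele")
  }
  invisible(TRUE)
}

#' Goodness of fit of phenotype counts to 3:1 segregation
#'
#' Pearson chi-square (1 df, no continuity correction) of observed
#' dominant:recessive counts against the Mendelian 3:1 expectation.
#'
#' @param n_dom,n_rec Observed counts of dominant- and recessive-phenotype
#'   plants.
#' @return List with `chi2`, `df`, `p`.
#' @examples
#' phenotype_chi2(77, 31)$chi2   # 0.79
#' @export
phenotype_chi2 <- function(n_dom, n_rec) {
  stopifnot(n_dom + n_rec > 0)
  ct <- suppressWarnings(chisq.test(c(n_dom, n_rec), p = c(3, 1) / 4))
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Joint-segregation chi-square of a six-cell table
#'
#' Pearson goodness of fit of the six observed cells to the joint
#' independence expectation `N * (3/16, 6/16, 3/16, 1/16, 2/16, 1/16)`
#' (3:1 phenotype times 1:2:1 marker, no linkage), without continuity
#' correction.
#'
#' @param table A [segregation_table()] or a vector of six counts.
#' @return List with `chi2`, `df` (5) and `p`.
#' @export
joint_chi2 <- function(table) {
  counts <- unclass(.as_segtable(table))
  ct <- suppressWarnings(chisq.test(counts, p = c(3, 6, 3, 1, 2, 1) / 16))
  list(chi2 = unname(ct$statistic), df = 5L, p = unname(ct$p.value))
}

#' Maximum-likelihood recombination fraction from a segregation table
#'
#' Maximises the multinomial log-likelihood of the six cells under
#' [f2_cell_probs()] over \[0, 0.5\] (dense grid plus local refinement);
#' estimates are capped at 0.5, the no-linkage boundary.
#'
#' @param table A [segregation_table()] or a vector of six counts.
#' @param grid_step Grid spacing of the likelihood scan.
#' @return The recombination-fraction estimate.
#' @examples
#' estimate_rf_ml(c(30, 47, 0, 0, 1, 30))   # 0.0092
#' @export
estimate_rf_ml <- function(table, grid_step = 1e-4) {
  counts <- unclass(.as_segtable(table))
  g <- seq(0, 0.5, by = grid_step)
  ll <- vapply(g, .segtable_loglik, 0, counts = counts)
  mx <- .refine_max(function(a) .segtable_loglik(a, counts), g, ll)
  .check_phase(counts, mx$alpha, mx$ll)
  mx$alpha
}

#' LOD score of a segregation table at a recombination fraction
#'
#' Log10 likelihood ratio between `rf` and independence (`alpha = 0.5`)
#' under the six-cell model. At `rf = 0.5` there is no linkage to score and
#' the LOD is reported as missing.
#'
#' @param table A [segregation_table()] or a vector of six counts.
#' @param rf Recombination fraction in \[0, 0.5\], typically from
#'   [estimate_rf_ml()].
#' @return The LOD score, or `NA` at `rf = 0.5`.
#' @export
lod_score <- function(table, rf) {
  stopifnot(rf >= 0, rf <= 0.5)
  if (rf >= 0.5 - 1e-9) return(NA_real_)
  counts <- unclass(.as_segtable(table))
  (.segtable_loglik(rf, counts) - .segtable_loglik(0.5, counts)) / log(10)
}

#' Two-point linkage summary for a set of markers
#'
#' Convenience wrapper producing, per marker, the six counts, the ML
#' recombination fraction, its LOD and the joint-segregation chi-square —
#' one row per marker, in input order.
#'
#' @param tables Named list of six-count vectors or [segregation_table()]s.
#' @return Data frame with columns `marker`, the six cells, `rf`, `lod`,
#'   `chi2`.
#' @export
linkage_report <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  rows <- lapply(names(tables), function(nm) {
    tb <- .as_segtable(tables[[nm]])
    rf <- estimate_rf_ml(tb)
    data.frame(marker = nm, t(unclass(tb)), rf = rf,
               lod = lod_score(tb, rf), chi2 = joint_chi2(tb)$chi2)
  })
  do.call(rbind, rows)
}

# 3x3 two-locus genotype probabilities of an F2 in coupling phase: cell
# (i, j) is P(i mutant-parent alleles at locus 1, j at locus 2), from the
# four gamete types at frequencies ((1-a)/2, a/2, a/2, (1-a)/2).
.two_locus_probs <- function(a) {
  gam <- matrix(c((1 - a) / 2, a / 2, a / 2, (1 - a) / 2), 2, 2)
  # gam[x + 1, y + 1]: gamete with x, y mutant-parent alleles at loci 1, 2
  P <- matrix(0, 3, 3)
  for (x1 in 0:1) for (y1 in 0:1) for (x2 in 0:1) for (y2 in 0:1) {
    P[x1 + x2 + 1L, y1 + y2 + 1L] <- P[x1 + x2 + 1L, y1 + y2 + 1L] +
      gam[x1 + 1L, y1 + 1L] * gam[x2 + 1L, y2 + 1L]
  }
  P
}

.two_locus_loglik <- function(a, tab) {
  P <- .two_locus_probs(a)
  pos <- tab > 0
  if (any(pos & P == 0)) return(-Inf)
  sum(tab[pos] * log(P[pos]))
}

#' Pairwise recombination fractions among individually genotyped loci
#'
#' Marker-marker recombination fractions by maximum likelihood on the 3x3
#' codominant two-locus F2 table; entries against the phenotype column (if
#' supplied) use the six-cell dominant/recessive model of
#' [estimate_rf_ml()]. Monomorphic loci are flagged with a warning and `NA`
#' entries.
#'
#' @param genotypes Plants x loci matrix or data frame, coded 0/1/2 copies
#'   of the mutant-parent allele.
#' @param phenotype Optional per-plant phenotype
#'   (`"dominant"`/`"recessive"`); adds a `phenotype` row/column.
#' @param grid_step Grid spacing of the likelihood scans.
#' @return List of two symmetric matrices, `rf` (0 diagonal) and `lod`
#'   (`NA` diagonal; `NA` where `rf = 0.5`).
#' @export
pairwise_rf_matrix <- function(genotypes, phenotype = NULL, grid_step = 1e-4) {
  G <- as.matrix(genotypes)
  stopifnot(ncol(G) >= 2 || !is.null(phenotype), all(G %in% 0:2))
  mono <- apply(G, 2L, function(x) length(unique(x)) == 1L)
  if (any(mono)) {
    warning("monomorphic locus flagged: ",
            paste(colnames(G)[mono], collapse = ", "))
  }
  loci <- colnames(G)
  nms <- c(loci, if (!is.null(phenotype)) "phenotype")
  k <- length(nms)
  rf <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  lod <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(rf) <- 0
  grid <- seq(0, 0.5, by = grid_step)
  for (i in seq_along(loci)) {
    for (j in seq_along(loci)[-seq_len(i)]) {
      if (mono[i] || mono[j]) next
      tab <- table(factor(G[, i], 0:2), factor(G[, j], 0:2))
      ll <- vapply(grid, .two_locus_loglik, 0, tab = tab)
      mx <- .refine_max(function(a) .two_locus_loglik(a, tab), grid, ll)
      rf[i, j] <- rf[j, i] <- mx$alpha
      lod[i, j] <- lod[j, i] <- if (mx$alpha >= 0.5 - 1e-9) NA_real_ else {
        (mx$ll - .two_locus_loglik(0.5, tab)) / log(10)
      }
    }
  }
  if (!is.null(phenotype)) {
    stopifnot(length(phenotype) == nrow(G),
              all(phenotype %in% c("dominant", "recessive")))
    for (i in seq_along(loci)) {
      if (mono[i]) next
      # 'A' is the wild-parent allele: 0 mutant-parent copies -> AA
      cnt <- numeric(6L)
      for (ph in 1:2) for (gg in 0:2) {
        cls <- c("dominant", "recessive")[ph]
        cnt[(ph - 1L) * 3L + gg + 1L] <- sum(phenotype == cls & G[, i] == gg)
      }
      tb <- segregation_table(cnt)
      r <- estimate_rf_ml(tb, grid_step = grid_step)
      rf[i, k] <- rf[k, i] <- r
      lod[i, k] <- lod[k, i] <- lod_score(tb, r)
    }
  }
  list(rf = rf, lod = lod)
}

#' Order loci into a linear map
#'
#' Exhaustively searches locus orderings (with branch-and-bound pruning)
#' for the one minimising the sum of adjacent recombination fractions.
#' Orientation is made canonical (first locus name lexicographically before
#' the last); among equal-cost orders the lexicographically smallest wins.
#' Distances are reported as centimorgans equal to 100 times the adjacent
#' recombination fraction (no mapping function).
#'
#' @param rf Symmetric recombination-fraction matrix with locus dimnames,
#'   e.g. from [pairwise_rf_matrix()]. At most 10 loci.
#' @return Data frame `locus`, `position_cM` (cumulative).
#' @export
order_loci <- function(rf) {
  stopifnot(is.matrix(rf), nrow(rf) == ncol(rf), nrow(rf) >= 2)
  if (nrow(rf) > 10L) {
    stop("exhaustive ordering is limited to 10 loci")
  }
  if (any(is.na(rf[upper.tri(rf)]))) stop("rf matrix contains NA entries")
  ord0 <- order(rownames(rf))
  rf <- rf[ord0, ord0, drop = FALSE]  # name order => deterministic tie-break
  k <- nrow(rf)
  best <- NULL
  bestcost <- Inf
  perm <- integer(k)
  used <- logical(k)
  recurse <- function(depth, cost) {
    if (cost > bestcost + 1e-15) return()
    if (depth > k) {
      if (cost < bestcost - 1e-15) {
        bestcost <<- cost
        best <<- perm
      }
      return()
    }
    for (i in seq_len(k)) {
      if (used[i]) next
      used[i] <<- TRUE
      perm[depth] <<- i
      add <- if (depth == 1L) 0 else rf[perm[depth - 1L], i]
      recurse(depth + 1L, cost + add)
      used[i] <<- FALSE
    }
  }
  recurse(1L, 0)
  nms <- rownames(rf)[best]
  if (nms[1L] > nms[length(nms)]) {
    best <- rev(best)
    nms <- rev(nms)
  }
  adj <- rf[cbind(best[-k], best[-1L])]
  data.frame(locus = nms, position_cM = cumsum(c(0, 100 * adj)))
}
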