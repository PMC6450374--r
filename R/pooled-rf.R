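# Pooled-read recombination-frequency likelihood.
#
# Notation: a bulk of n F2 plants of known phenotype class is sequenced as one
# library; at a biallelic SNV, m of c counted reads carry the mutant-parent
# allele. G (0..2n) is the unknown number of mutant-parent alleles among the
# bulk members; alpha is the recombination fraction between the SNV and the
# causal locus, searched on [0, 0.5] (coupling phase).

#' Marker genotype class probabilities inside a phenotype bulk
#'
#' Probability that a plant drawn into a bulk of the given phenotype class
#' carries 2, 1 or 0 copies of the mutant-parent allele at a marker located
#' at recombination fraction `alpha` from the causal locus (coupling phase,
#' recessive mutant phenotype).
#'
#' For a recessive-phenotype plant (homozygous mutant at the causal locus)
#' the probabilities are \eqn{(1-\alpha)^2}, \eqn{2\alpha(1-\alpha)},
#' \eqn{\alpha^2}. For a dominant-phenotype plant they follow from
#' enumerating the 16 equiprobable gamete pairings conditioned on carrying
#' at least one wild-type causal allele:
#' \eqn{\alpha(2-\alpha)/3}, \eqn{2(1-\alpha+\alpha^2)/3},
#' \eqn{(1-\alpha^2)/3}.
#'
#' @param alpha Recombination fraction in \[0, 0.5\].
#' @param pool_class `"recessive"` or `"dominant"`.
#' @return Named numeric vector `(p_LL, p_Ll, p_ll)` (2, 1, 0 mutant-parent
#'   alleles); sums to 1.
#' @examples
#' genotype_class_probs(0, "recessive")   # (1, 0, 0)
#' genotype_class_probs(0, "dominant")    # (0, 2/3, 1/3)
#' @export
genotype_class_probs <- function(alpha, pool_class = c("recessive", "dominant")) {
  pool_class <- match.arg(pool_class)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 0.5) {
    stop("'alpha' must be a single value in [0, 0.5]")
  }
  p <- if (pool_class == "recessive") {
    c((1 - alpha)^2, 2 * alpha * (1 - alpha), alpha^2)
  } else {
    c(alpha * (2 - alpha) / 3, 2 * (1 - alpha + alpha^2) / 3, (1 - alpha^2) / 3)
  }
  names(p) <- c("p_LL", "p_Ll", "p_ll")
  p
}

# Vectorised class probabilities over a grid of alpha values.
# Returns a length(alpha) x 3 matrix with columns (p_LL, p_Ll, p_ll).
.class_prob_grid <- function(alpha, pool_class) {
  if (pool_class == "recessive") {
    cbind((1 - alpha)^2, 2 * alpha * (1 - alpha), alpha^2)
  } else {
    cbind(alpha * (2 - alpha) / 3, 2 * (1 - alpha + alpha^2) / 3, (1 - alpha^2) / 3)
  }
}

#' Distribution of the mutant-parent allele count in a bulk
#'
#' Probability mass function of G, the number of mutant-parent alleles among
#' `n` diploid bulk members, given the per-plant genotype class probabilities.
#' Computed by n-fold convolution of the per-plant distribution, which is
#' numerically identical to the direct trinomial sum over all `(k, h)` with
#' `2k + h = g`.
#'
#' @param n Number of plants in the bulk.
#' @param probs Per-plant class probabilities `(p_LL, p_Ll, p_ll)`, e.g. from
#'   [genotype_class_probs()].
#' @return Numeric vector of length `2n + 1`, probabilities over `G = 0..2n`.
#' @export
pmf_G <- function(n, probs) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n), length(probs) == 3L)
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9) {
    stop("'probs' must be non-negative and sum to 1")
  }
  per <- c(probs[[3L]], probs[[2L]], probs[[1L]])  # over g = 0, 1, 2
  out <- per
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      nw <- numeric(length(out) + 2L)
      for (g in 0:2) {
        idx <- seq_along(out) + g
        nw[idx] <- nw[idx] + out * per[g + 1L]
      }
      out <- nw
    }
  }
  out
}

# pmf_G for every row of a class-probability matrix (grid of alphas).
# P: nalpha x 3 (p_LL, p_Ll, p_ll). Returns nalpha x (2n + 1).
.pmfG_grid <- function(n, P) {
  per <- P[, c(3L, 2L, 1L), drop = FALSE]
  out <- per
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      nw <- matrix(0, nrow(P), ncol(out) + 2L)
      for (g in 0:2) {
        idx <- seq_len(ncol(out)) + g
        nw[, idx] <- nw[, idx] + out * per[, g + 1L]
      }
      out <- nw
    }
  }
  out
}

#' Beta-binomial read likelihood given the bulk allele count
#'
#' Probability of observing `m` mutant-parent reads among `c` counted reads
#' when the bulk carries `G` of `2n` mutant-parent alleles. The library
#' allele concentration is Beta-distributed with shapes
#' `(G * xi, (2n - G) * xi)`; marginalising the binomial read draw gives the
#' beta-binomial. At the boundaries `G = 0` and `G = 2n` the concentration is
#' a point mass at 0 or 1 (the Beta limit as one shape parameter vanishes),
#' so the probability is the indicator of `m = 0` or `m = c`.
#'
#' @param m Observed mutant-parent read count(s).
#' @param c Total counted read depth(s).
#' @param G Mutant-parent allele count(s) in the bulk, `0..2n`.
#' @param n Bulk size (plants).
#' @param xi Mixing accuracy coefficient (> 0); larger values mean more even
#'   tissue mixing and less extra-binomial variance.
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities), recycled to the common
#'   length of `m`, `c` and `G`.
#' @export
read_likelihood <- function(m, c, G, n, xi, log = FALSE) {
  stopifnot(xi > 0, n >= 1, all(G >= 0), all(G <= 2 * n),
            all(m >= 0), all(c >= 0), all(m <= rep_len(c, length(m))))
  k <- max(length(m), length(c), length(G))
  m <- rep_len(as.numeric(m), k)
  c <- rep_len(as.numeric(c), k)
  G <- rep_len(as.numeric(G), k)
  ll <- numeric(k)
  lo <- G == 0
  hi <- G == 2 * n
  mid <- !(lo | hi)
  ll[lo] <- ifelse(m[lo] == 0, 0, -Inf)
  ll[hi] <- ifelse(m[hi] == c[hi], 0, -Inf)
  if (any(mid)) {
    a <- G[mid] * xi
    b <- (2 * n - G[mid]) * xi
    ll[mid] <- lchoose(c[mid], m[mid]) +
      lbeta(m[mid] + a, c[mid] - m[mid] + b) - lbeta(a, b)
  }
  if (log) ll else exp(ll)
}

.check_pools <- function(pools) {
  need <- c("class", "n", "m", "c")
  miss <- setdiff(need, names(pools))
  if (length(miss)) stop("pool table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(pools) < 1L) stop("at least one pool observation is required")
  if (!all(pools$class %in% c("recessive", "dominant"))) {
    stop("pool class must be 'recessive' or 'dominant'")
  }
  stopifnot(all(pools$n >= 1), all(pools$m >= 0), all(pools$m <= pools$c))
  pools
}

#' Log-likelihood of pooled read counts at a recombination fraction
#'
#' Sum over pools of the log of the G-marginalised read probability:
#' `sum_G P(G | alpha, class, n) * P(m | c, G, n, xi)`. Pools with zero
#' counted depth contribute nothing.
#'
#' @param alpha Recombination fraction in \[0, 0.5\].
#' @param pools Data frame with one row per pool and columns `class`
#'   (`"recessive"`/`"dominant"`), `n`, `m`, `c`.
#' @param xi Mixing accuracy coefficient.
#' @return Log-likelihood (may be `-Inf` if some pool is impossible under
#'   every G, e.g. wrong-parent reads at `alpha = 0`).
#' @export
snv_log_likelihood <- function(alpha, pools, xi = 10) {
  pools <- .check_pools(pools)
  tot <- 0
  for (i in seq_len(nrow(pools))) {
    n <- pools$n[i]
    pg <- pmf_G(n, genotype_class_probs(alpha, pools$class[i]))
    rl <- read_likelihood(pools$m[i], pools$c[i], 0:(2 * n), n, xi)
    tot <- tot + log(sum(pg * rl))
  }
  tot
}

# Grid log-likelihood: returns length(alpha) vector. PG matrices can be
# passed in via 'cache' (a list keyed by "class/n") to share work across SNVs.
.grid_loglik <- function(pools, xi, alpha, cache = NULL) {
  ll <- numeric(length(alpha))
  for (i in seq_len(nrow(pools))) {
    n <- pools$n[i]
    key <- paste0(pools$class[i], "/", n)
    PG <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      .pmfG_grid(n, .class_prob_grid(alpha, pools$class[i]))
    }
    rl <- read_likelihood(pools$m[i], pools$c[i], 0:(2 * n), n, xi)
    ll <- ll + log(as.vector(PG %*% rl))
  }
  ll
}

.pg_cache <- function(pools, alpha) {
  keys <- unique(paste0(pools$class, "/", pools$n))
  cache <- list()
  for (k in keys) {
    parts <- strsplit(k, "/", fixed = TRUE)[[1L]]
    cache[[k]] <- .pmfG_grid(as.integer(parts[2L]),
                             .class_prob_grid(alpha, parts[1L]))
  }
  cache
}

# Refine a grid maximum with a local golden-section/parabolic search.
.refine_max <- function(f, alpha, ll) {
  i <- which.max(ll)
  if (!is.finite(ll[i])) return(list(alpha = NA_real_, ll = -Inf))
  lo <- alpha[max(1L, i - 1L)]
  hi <- alpha[min(length(alpha), i + 1L)]
  best <- list(alpha = alpha[i], ll = ll[i])
  if (hi > lo) {
    o <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-9)
    if (is.finite(o$objective) && o$objective > best$ll) {
      best <- list(alpha = o$maximum, ll = o$objective)
    }
  }
  best
}

# Profile-likelihood interval {alpha : 2 (ll_max - ll(alpha)) <= q} as the
# connected component of the grid containing the maximum, with endpoints
# sharpened by root finding between grid points.
.profile_ci <- function(f, alpha, ll, ll_max, level) {
  q <- qchisq(level, df = 1)
  thr <- ll_max - q / 2
  ok <- is.finite(ll) & (ll >= thr)
  i <- which.max(ll)
  left <- i
  while (left > 1L && ok[left - 1L]) left <- left - 1L
  right <- i
  while (right < length(ll) && ok[right + 1L]) right <- right + 1L
  lo <- alpha[left]
  hi <- alpha[right]
  g <- function(a) f(a) - thr
  if (left > 1L) {
    glo <- g(alpha[left - 1L])
    if (is.finite(glo) && glo < 0 && g(lo) > 0) {
      lo <- uniroot(g, c(alpha[left - 1L], lo), tol = 1e-8)$root
    }
  }
  if (right < length(ll)) {
    ghi <- g(alpha[right + 1L])
    if (is.finite(ghi) && ghi < 0 && g(hi) > 0) {
      hi <- uniroot(g, c(hi, alpha[right + 1L]), tol = 1e-8)$root
    }
  }
  c(max(0, lo), min(0.5, hi))
}

#' Maximum-likelihood recombination fraction from pooled read counts
#'
#' Maximises [snv_log_likelihood()] over the coupling-phase search space
#' \[0, 0.5\] by a dense grid followed by local refinement, and reports the
#' profile-likelihood confidence interval (chi-square with 1 df; the default
#' 80% level uses the quantile 1.642), the LOD score against independence
#' (`alpha = 0.5`), and, optionally, the improbable-allele-ratio exclusion
#' flag from [improbable_ratio_test()].
#'
#' @param pools Data frame of pool observations: `class`, `n`, `m`, `c`.
#' @param xi Mixing accuracy coefficient (the study-design parameter of the
#'   beta mixing model; it is not estimated).
#' @param grid_step Grid spacing for the likelihood scan.
#' @param ci_level Confidence level of the profile-likelihood interval.
#' @param exclude Run the exclusion test and attach its result?
#' @param p_threshold Tail-probability threshold for the exclusion test.
#' @return An object of class `rf_estimate`: a list with `alpha_hat`, `ci`
#'   (lower/upper, truncated to \[0, 0.5\]), `lod`, `loglik`, `excluded`,
#'   `exclusion` (test detail or `NULL`) and the inputs. If every pool has
#'   zero counted depth the estimate is undefined (`alpha_hat = NA`,
#'   `undefined = TRUE`).
#' @export
estimate_rf <- function(pools, xi = 10, grid_step = 1e-4, ci_level = 0.8,
                        exclude = TRUE, p_threshold = 1e-3) {
  pools <- .check_pools(pools)
  if (all(pools$c == 0)) {
    out <- list(alpha_hat = NA_real_, ci = c(NA_real_, NA_real_),
                lod = NA_real_, loglik = NA_real_, excluded = FALSE,
                exclusion = NULL, undefined = TRUE, pools = pools, xi = xi)
    class(out) <- "rf_estimate"
    return(out)
  }
  alpha <- seq(0, 0.5, by = grid_step)
  ll <- .grid_loglik(pools, xi, alpha)
  f <- function(a) snv_log_likelihood(a, pools, xi)
  mx <- .refine_max(f, alpha, ll)
  ci <- .profile_ci(f, alpha, ll, mx$ll, ci_level)
  lod <- (mx$ll - ll[length(ll)]) / log(10)
  excl <- NULL
  if (exclude) {
    excl <- improbable_ratio_test(pools, xi = xi, p_threshold = p_threshold)
  }
  out <- list(alpha_hat = mx$alpha, ci = ci, lod = lod, loglik = mx$ll,
              excluded = if (is.null(excl)) FALSE else excl$excluded,
              exclusion = excl, undefined = FALSE, pools = pools, xi = xi)
  class(out) <- "rf_estimate"
  out
}

#' @export
print.rf_estimate <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("RF estimate undefined: all pools have zero counted depth\n")
    return(invisible(x))
  }
  cat(sprintf("RF estimate: alpha_hat = %.4f, %d%% CI [%.4f, %.4f], LOD = %.3f\n",
              x$alpha_hat, 80L, x$ci[1L], x$ci[2L], x$lod))
  if (isTRUE(x$excluded)) cat("flagged: improbable allele ratio in >= 1 pool\n")
  invisible(x)
}

#' Recombination-fraction estimates for a table of SNVs
#'
#' Applies [estimate_rf()] to every SNV in a long counts table, sharing the
#' grid of bulk-allele-count distributions across SNVs with the same pool
#' structure. The result is sorted ascending by the point estimate (ties by
#' LOD, then identifier) — the natural ranking for candidate screening.
#'
#' @param counts Data frame with columns `snv`, `pool`, `class`, `n`, `m`, `c`.
#' @param xi,grid_step,ci_level,exclude,p_threshold See [estimate_rf()].
#' @return Data frame with one row per SNV: `snv`, `alpha_hat`, `ci_low`,
#'   `ci_high`, `lod`, `excluded`, `n_pools`.
#' @export
estimate_rf_all <- function(counts, xi = 10, grid_step = 1e-4, ci_level = 0.8,
                            exclude = TRUE, p_threshold = 1e-3) {
  stopifnot(all(c("snv", "class", "n", "m", "c") %in% names(counts)))
  alpha <- seq(0, 0.5, by = grid_step)
  cache <- .pg_cache(counts, alpha)
  ids <- unique(counts$snv)
  res <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pools <- counts[counts$snv == ids[k], , drop = FALSE]
    pools <- .check_pools(pools)
    if (all(pools$c == 0)) {
      res[[k]] <- data.frame(snv = ids[k], alpha_hat = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             lod = NA_real_, excluded = FALSE, n_pools = nrow(pools))
      next
    }
    ll <- .grid_loglik(pools, xi, alpha, cache = cache)
    f <- function(a) snv_log_likelihood(a, pools, xi)
    mx <- .refine_max(f, alpha, ll)
    ci <- .profile_ci(f, alpha, ll, mx$ll, ci_level)
    lod <- (mx$ll - ll[length(ll)]) / log(10)
    exc <- if (exclude) {
      improbable_ratio_test(pools, xi = xi, p_threshold = p_threshold)$excluded
    } else FALSE
    res[[k]] <- data.frame(snv = ids[k], alpha_hat = mx$alpha,
                           ci_low = ci[1L], ci_high = ci[2L], lod = lod,
                           excluded = exc, n_pools = nrow(pools))
  }
  out <- do.call(rbind, res)
  out[order(out$alpha_hat, -out$lod, out$snv), , drop = FALSE]
}

#' Exclusion test for implausible pooled allele ratios
#'
#' Screens an SNV for library allele ratios that no recombination fraction
#' can explain. For each pool and each `alpha` on a grid over \[0, 0.5\], the
#' two-sided exact tail probability of the observed `m` is computed under
#' the G-marginalised read model (the sum of the probabilities of all
#' outcomes no more probable than the observed one). The SNV is excluded
#' when at every grid `alpha` at least one pool falls below `p_threshold` —
#' i.e. no single recombination fraction makes all libraries plausible
#' simultaneously.
#'
#' With small bulks this test is deliberately conservative: the bulk
#' composition variance (the chance that a bulk happens to contain a
#' recombinant plant) places a floor under every tail probability, so
#' moderate single-library contamination is statistically indistinguishable
#' from loose linkage and is retained. See the package vignette.
#'
#' @param pools Data frame of pool observations: `class`, `n`, `m`, `c`.
#' @param xi Mixing accuracy coefficient.
#' @param p_threshold Tail-probability threshold below which a pool counts
#'   as implausible.
#' @param grid_step Spacing of the `alpha` scan used for the test.
#' @return A list: `excluded` (logical), `max_min_tail` (the largest, over
#'   `alpha`, of the per-alpha minimum pool tail — the SNV is excluded iff
#'   this is below `p_threshold`), `alpha_best` (the `alpha` attaining it),
#'   `pool_tails` (per-pool tails at `alpha_best`), and the scanned
#'   `alpha_grid` with the per-alpha minimum tails `min_tail`.
#' @export
improbable_ratio_test <- function(pools, xi = 10, p_threshold = 1e-3,
                                  grid_step = 0.01) {
  pools <- .check_pools(pools)
  alpha <- seq(0, 0.5, by = grid_step)
  np <- nrow(pools)
  tails <- matrix(1, length(alpha), np)
  for (j in seq_len(np)) {
    n <- pools$n[j]
    cc <- pools$c[j]
    if (cc == 0) next  # uninformative pool: never implausible
    G <- 0:(2 * n)
    RL <- vapply(G, function(g) read_likelihood(0:cc, cc, g, n, xi),
                 numeric(cc + 1L))
    PG <- .pmfG_grid(n, .class_prob_grid(alpha, pools$class[j]))
    PM <- PG %*% t(RL)                     # nalpha x (cc + 1) marginal pmfs
    obs <- PM[, pools$m[j] + 1L]
    tails[, j] <- rowSums(PM * (PM <= obs * (1 + 1e-12)))
  }
  min_tail <- apply(tails, 1L, min)
  best <- which.max(min_tail)
  list(excluded = all(min_tail < p_threshold),
       max_min_tail = min_tail[best],
       alpha_best = alpha[best],
       pool_tails = tails[best, ],
       alpha_grid = alpha,
       min_tail = min_tail)
}
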