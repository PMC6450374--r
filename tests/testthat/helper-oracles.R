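# Independent oracles: brute-force enumerations kept deliberately separate
# from the package's own computational paths.

# Marker-class probabilities by enumerating the 16 equiprobable gamete
# pairings of an F2 (gamete = causal allele x marker allele, coupling
# phase), conditioning on the pool's phenotype class.
oracle_class_probs <- function(alpha, pool_class) {
  # gamete: (causal mutant? marker mutant?) with probabilities
  gam <- list(c(1, 1, (1 - alpha) / 2), c(1, 0, alpha / 2),
              c(0, 1, alpha / 2), c(0, 0, (1 - alpha) / 2))
  acc <- c(0, 0, 0)  # P(marker mutant copies = 2, 1, 0 & class)
  pcls <- 0
  for (g1 in gam) for (g2 in gam) {
    pr <- g1[3] * g2[3]
    recessive <- (g1[1] + g2[1]) == 2
    if ((pool_class == "recessive") == recessive) {
      mk <- g1[2] + g2[2]
      acc[3 - mk] <- acc[3 - mk] + pr
      pcls <- pcls + pr
    }
  }
  acc / pcls
}

# Direct trinomial sum for the bulk allele-count distribution.
oracle_pmf_G <- function(n, probs) {
  p2 <- probs[1]; p1 <- probs[2]; p0 <- probs[3]
  out <- numeric(2 * n + 1)
  for (k in 0:n) for (h in 0:(n - k)) {
    g <- 2 * k + h
    out[g + 1] <- out[g + 1] +
      exp(lfactorial(n) - lfactorial(k) - lfactorial(h) - lfactorial(n - k - h)) *
      p2^k * p1^h * p0^(n - k - h)
  }
  out
}

# Beta-binomial pmf written independently (direct dbeta integration on a
# fine grid would be sloppy; use the exact ratio-of-Beta-functions form but
# through gamma functions, with explicit boundary handling).
oracle_bb <- function(m, c, a, b) {
  exp(lgamma(c + 1) - lgamma(m + 1) - lgamma(c - m + 1) +
      lgamma(m + a) + lgamma(c - m + b) - lgamma(c + a + b) +
      lgamma(a + b) - lgamma(a) - lgamma(b))
}

# Pool log-likelihood by exhaustive enumeration of all 3^n genotype
# configurations of the n bulk members (feasible for n <= 4).
oracle_pool_loglik <- function(alpha, pools, xi) {
  tot <- 0
  for (i in seq_len(nrow(pools))) {
    n <- pools$n[i]
    cls <- oracle_class_probs(alpha, pools$class[i])  # P(2, 1, 0 copies)
    configs <- expand.grid(rep(list(0:2), n))
    psum <- 0
    for (r in seq_len(nrow(configs))) {
      geno <- as.numeric(configs[r, ])
      pg <- prod(cls[3 - geno])
      G <- sum(geno)
      pread <- if (G == 0) {
        as.numeric(pools$m[i] == 0)
      } else if (G == 2 * n) {
        as.numeric(pools$m[i] == pools$c[i])
      } else {
        oracle_bb(pools$m[i], pools$c[i], G * xi, (2 * n - G) * xi)
      }
      psum <- psum + pg * pread
    }
    tot <- tot + log(psum)
  }
  tot
}

# Six-cell F2 probabilities by gamete-pairing enumeration ('A' = wild-parent
# marker allele, dominant phenotype = at least one wild causal allele).
oracle_cell_probs <- function(alpha) {
  gam <- list(c(1, 1, (1 - alpha) / 2), c(1, 0, alpha / 2),
              c(0, 1, alpha / 2), c(0, 0, (1 - alpha) / 2))
  out <- numeric(6)
  for (g1 in gam) for (g2 in gam) {
    pr <- g1[3] * g2[3]
    dominant <- (g1[1] + g2[1]) < 2          # carries a wild causal allele
    n_wild_marker <- (1 - g1[2]) + (1 - g2[2])  # copies of the 'A' allele
    idx <- (if (dominant) 0 else 3) + (3 - n_wild_marker)
    out[idx] <- out[idx] + pr
  }
  names(out) <- c("dom_AA", "dom_Aa", "dom_aa", "rec_AA", "rec_Aa", "rec_aa")
  out
}

oracle_segtable_loglik <- function(alpha, counts) {
  p <- oracle_cell_probs(alpha)
  ll <- 0
  for (i in 1:6) {                      # per-plant product, written as a loop
    if (counts[i] > 0) {
      if (p[[i]] == 0) return(-Inf)
      for (rep in seq_len(counts[i])) ll <- ll + log(p[[i]])
    }
  }
  ll
}

# Golden-section maximiser independent of stats::optimize.
oracle_golden_max <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}
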