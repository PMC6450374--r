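test_that("bulk genotype-class probabilities match the gamete enumeration", {
  expect_equal(genotype_class_probs(0, "recessive"), c(p_LL = 1, p_Ll = 0, p_ll = 0))
  expect_equal(unname(genotype_class_probs(0, "dominant")), c(0, 2 / 3, 1 / 3))
  expect_equal(unname(genotype_class_probs(0.5, "dominant")), c(0.25, 0.5, 0.25))
  for (a in seq(0, 0.5, by = 0.05)) {
    for (cls in c("recessive", "dominant")) {
      p <- genotype_class_probs(a, cls)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(unname(p), oracle_class_probs(a, cls), tolerance = 1e-12)
    }
  }
  expect_error(genotype_class_probs(0.6, "recessive"), "alpha")
})

test_that("the bulk allele-count pmf equals the direct trinomial sum", {
  expect_equal(pmf_G(1, genotype_class_probs(0, "recessive")), c(0, 0, 1))
  expect_equal(pmf_G(1, genotype_class_probs(0.5, "recessive")),
               c(0.25, 0.5, 0.25))
  p <- pmf_G(2, genotype_class_probs(0.1, "recessive"))
  expect_equal(p[5], 0.6561, tolerance = 1e-10)  # P(G = 4) = ((1-a)^2)^2
  expect_equal(p[4], 0.2916, tolerance = 1e-10)
  for (n in c(1, 3, 5)) {
    for (a in c(0, 0.07, 0.3, 0.5)) {
      for (cls in c("recessive", "dominant")) {
        probs <- genotype_class_probs(a, cls)
        conv <- pmf_G(n, probs)
        expect_equal(sum(conv), 1, tolerance = 1e-10)
        expect_equal(conv, oracle_pmf_G(n, probs), tolerance = 1e-10)
      }
    }
  }
})

test_that("the read likelihood is a normalised beta-binomial with hard boundaries", {
  n <- 5
  expect_equal(read_likelihood(10, 10, 2 * n, n, 3), 1)
  expect_equal(read_likelihood(9, 10, 2 * n, n, 3), 0)
  expect_equal(read_likelihood(0, 10, 0, n, 3), 1)
  # beta-binomial converges to the binomial as mixing noise vanishes
  expect_equal(read_likelihood(5, 10, n, n, 1e6), 0.24609375, tolerance = 1e-3)
  # a single read picks the mutant allele with probability G / 2n (beta mean)
  for (G in 1:9) {
    expect_equal(read_likelihood(1, 1, G, n, 0.37), G / (2 * n), tolerance = 1e-12)
  }
  # normalisation over m for interior G, several depths
  for (G in c(1, 4, 9)) {
    for (cc in c(1, 7, 40)) {
      expect_equal(sum(read_likelihood(0:cc, cc, G, n, 2.5)), 1, tolerance = 1e-10)
    }
  }
})

test_that("the pooled log-likelihood matches exhaustive genotype enumeration", {
  one <- data.frame(class = "recessive", n = 1, m = 1, c = 1)
  expect_equal(snv_log_likelihood(0.1, one, xi = 7),
               log((1 - 0.1)^2 + 0.1 * (1 - 0.1)), tolerance = 1e-12)
  perfect <- data.frame(class = "recessive", n = 5, m = 12, c = 12)
  expect_equal(snv_log_likelihood(0, perfect, xi = 10), 0)

  set.seed(41)
  for (rep in 1:6) {
    n <- sample(1:4, 1)
    pools <- data.frame(class = sample(c("recessive", "dominant"), 3, TRUE),
                        n = n, c = sample(5:30, 3))
    pools$m <- vapply(pools$c, function(cc) sample(0:cc, 1), 0L)
    xi <- runif(1, 0.5, 20)
    for (a in c(0.03, 0.2, 0.5)) {
      expect_equal(snv_log_likelihood(a, pools, xi),
                   oracle_pool_loglik(a, pools, xi), tolerance = 1e-8)
    }
  }
})

test_that("likelihood decreases with alpha when every read is mutant-parent", {
  pools <- data.frame(class = "recessive", n = 5,
                      m = c(100, 100, 100, 100), c = 100)
  grid <- seq(0.01, 0.5, by = 0.01)
  ll <- vapply(grid, snv_log_likelihood, 0, pools = pools, xi = 10)
  expect_true(all(diff(ll) < 0))
})

test_that("complete linkage is estimated at the alpha = 0 boundary", {
  pools <- rbind(data.frame(class = "recessive", n = 5, m = 100, c = 100)[rep(1, 4), ],
                 data.frame(class = "dominant", n = 6, m = 40, c = 120)[rep(1, 2), ])
  est <- estimate_rf(pools, xi = 10, exclude = FALSE)
  expect_equal(est$alpha_hat, 0)
  expect_equal(est$ci[1], 0)
  expect_gt(est$lod, 3)
  expect_lt(est$ci[2], 0.1)
})

test_that("counts at independence expectations estimate alpha = 0.5 with zero LOD", {
  pools <- rbind(data.frame(class = "recessive", n = 5, m = 50, c = 100)[rep(1, 4), ],
                 data.frame(class = "dominant", n = 6, m = 60, c = 120)[rep(1, 2), ])
  est <- estimate_rf(pools, xi = 10, exclude = FALSE)
  expect_equal(est$alpha_hat, 0.5, tolerance = 1e-6)
  expect_equal(est$lod, 0, tolerance = 1e-6)
  expect_equal(est$ci[2], 0.5)
})

test_that("the estimate ignores pool order and empty pools", {
  pools <- data.frame(class = c("recessive", "recessive", "dominant"),
                      n = c(5, 5, 6), m = c(90, 97, 45), c = c(100, 100, 120))
  e1 <- estimate_rf(pools, xi = 10, exclude = FALSE)
  e2 <- estimate_rf(pools[c(3, 1, 2), ], xi = 10, exclude = FALSE)
  expect_equal(e2$alpha_hat, e1$alpha_hat, tolerance = 1e-6)
  expect_equal(e2$lod, e1$lod, tolerance = 1e-6)
  padded <- rbind(pools, data.frame(class = "recessive", n = 5, m = 0, c = 0))
  e3 <- estimate_rf(padded, xi = 10, exclude = FALSE)
  expect_equal(e3$alpha_hat, e1$alpha_hat, tolerance = 1e-6)
  expect_equal(e3$ci, e1$ci, tolerance = 1e-7)

  allzero <- data.frame(class = "recessive", n = 5, m = 0, c = 0)
  e4 <- estimate_rf(allzero)
  expect_true(e4$undefined)
  expect_true(is.na(e4$alpha_hat))
})

test_that("the profile interval is ordered, covers the estimate and respects bounds", {
  set.seed(42)
  for (rep in 1:5) {
    pools <- data.frame(class = "recessive", n = 5,
                        m = rbinom(4, 100, 0.85), c = 100)
    est <- estimate_rf(pools, xi = 10, exclude = FALSE)
    expect_lte(est$ci[1], est$alpha_hat + 1e-9)
    expect_gte(est$ci[2], est$alpha_hat - 1e-9)
    expect_gte(est$ci[1], 0)
    expect_lte(est$ci[2], 0.5)
    # the likelihood drop at the reported endpoints is the chi-square bound
    for (end in est$ci) {
      if (end > 0 && end < 0.5) {
        drop <- 2 * (est$loglik - snv_log_likelihood(end, pools, 10))
        expect_equal(drop, qchisq(0.8, 1), tolerance = 1e-3)
      }
    }
  }
})

test_that("batch estimation equals per-SNV estimation and sorts by the estimate", {
  set.seed(43)
  counts <- do.call(rbind, lapply(1:5, function(k) {
    data.frame(snv = sprintf("s%02d", k), pool = paste0("M", 1:4),
               class = "recessive", n = 5,
               m = rbinom(4, 100, c(0.99, 0.85, 0.7, 0.55, 0.5)[k]), c = 100)
  }))
  batch <- estimate_rf_all(counts, xi = 10, exclude = FALSE)
  expect_equal(nrow(batch), 5L)
  expect_true(!is.unsorted(batch$alpha_hat))
  for (i in seq_len(nrow(batch))) {
    single <- estimate_rf(counts[counts$snv == batch$snv[i], ],
                          xi = 10, exclude = FALSE)
    expect_equal(batch$alpha_hat[i], single$alpha_hat, tolerance = 1e-9)
    expect_equal(batch$lod[i], single$lod, tolerance = 1e-9)
    expect_equal(c(batch$ci_low[i], batch$ci_high[i]), single$ci,
                 tolerance = 1e-7)
  }
})

test_that("the exclusion test keeps SNVs that some alpha explains", {
  # pools exactly at their expected counts for alpha = 0.2
  a <- 0.2
  gdom <- sum(c(2, 1, 0) * genotype_class_probs(a, "dominant")) / 2
  pools <- rbind(data.frame(class = "recessive", n = 5, m = 80, c = 100)[rep(1, 2), ],
                 data.frame(class = "dominant", n = 6, m = round(120 * gdom), c = 120))
  t1 <- improbable_ratio_test(pools, xi = 10)
  expect_false(t1$excluded)
  expect_gt(t1$max_min_tail, 0.5)
  # tails are probabilities
  expect_true(all(t1$pool_tails >= 0 & t1$pool_tails <= 1))

  # perfectly linked counts are plausible at alpha = 0
  clean <- data.frame(class = "recessive", n = 5, m = 100, c = 100)
  expect_false(improbable_ratio_test(clean, xi = 10)$excluded)
})

test_that("mutually contradictory pools are flagged once composition noise allows", {
  pools <- rbind(data.frame(class = "recessive", n = 5, m = 0, c = 200),
                 data.frame(class = "recessive", n = 5, m = 200, c = 200)[rep(1, 3), ])
  res <- improbable_ratio_test(pools, xi = 10)
  # the chance that a recessive bulk of 5 is all-wild at the marker
  # (P(G = 0) = alpha^10 ~ 1e-3 at alpha = 0.5) floors the tails: the
  # default 1e-3 threshold does not exclude, a 5% threshold does
  expect_false(res$excluded)
  expect_gt(res$max_min_tail, 1e-3)
  expect_lt(res$max_min_tail, 0.05)
  expect_true(improbable_ratio_test(pools, xi = 10, p_threshold = 0.05)$excluded)
  # larger bulks beat the composition floor even at the strict threshold
  big <- rbind(data.frame(class = "recessive", n = 120, m = 0, c = 50),
               data.frame(class = "recessive", n = 120, m = 50, c = 50))
  expect_true(improbable_ratio_test(big, xi = 10)$excluded)
})

test_that("simulated counts at a known alpha recover it", {
  set.seed(44)
  pools <- study_pools()
  design <- two_locus_design(0.1)
  counts <- do.call(rbind, lapply(1:40, function(k) {
    e <- simulate_bsa_experiment(design, 200, pools, xi = 10, coverage = 100)
    cc <- e$counts
    cc$snv <- sprintf("rep%03d", k)
    cc
  }))
  est <- estimate_rf_all(counts, xi = 10, grid_step = 5e-4, exclude = FALSE)
  expect_equal(mean(est$alpha_hat), 0.1, tolerance = 0.25)
  expect_true(all(abs(est$alpha_hat - 0.1) < 0.2))
})
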