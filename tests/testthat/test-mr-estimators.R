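test_that("Wald ratio matches the delta formula", {
  h1 <- make_harmonized(1, 0.5, 0.05, 0.1)
  w <- wald_ratio(h1)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$std_error, 0.1)
  h2 <- make_harmonized(0.2, 0.1, 0.01, 0.02)
  w2 <- wald_ratio(h2)
  expect_equal(w2$estimate, 0.5)
  expect_equal(w2$std_error, 0.1)
  expect_error(wald_ratio(make_harmonized(0, 0.1, 0.01, 0.02)), "zero")
})

test_that("IVW matches the closed form and an independent meta-analysis", {
  h <- make_harmonized(beta_exposure = c(0.1, 0.2, 0.15),
                       beta_outcome = c(0.05, 0.09, 0.08),
                       se_exposure = rep(0.01, 3),
                       se_outcome = rep(0.01, 3))
  res <- mr_ivw(h)
  # brute-force weighted quotient, equal weights
  expect_equal(res$estimate,
               sum(c(0.1, 0.2, 0.15) * c(0.05, 0.09, 0.08)) /
                 sum(c(0.1, 0.2, 0.15)^2),
               tolerance = 1e-12)
  expect_equal(res$estimate, 0.035 / 0.0725, tolerance = 1e-12)
  # independent oracle: fixed-effect meta-analysis of Wald ratios with
  # first-order weights reproduces the IVW point estimate
  meta <- metafor::rma(yi = h$ratio, sei = h$ratio_se, method = "FE")
  expect_equal(res$estimate, as.numeric(meta$beta), tolerance = 1e-10)
  expect_equal(res$Q_df, 2L)
})

test_that("IVW reduces to the Wald ratio at k = 1 and respects the SE floor", {
  h1 <- make_harmonized(0.2, 0.1, 0.01, 0.02)
  expect_equal(mr_ivw(h1)$estimate, wald_ratio(h1)$estimate)
  expect_equal(mr_ivw(h1)$std_error, wald_ratio(h1)$std_error)
  # exact-fit data: Q = 0 and the multiplicative scale is floored at 1,
  # so the SE equals the fixed-effect SE
  bx <- c(0.1, 0.2, 0.3)
  h0 <- make_harmonized(bx, 0.5 * bx, rep(0.01, 3), rep(0.02, 3))
  r0 <- mr_ivw(h0)
  expect_equal(r0$estimate, 0.5, tolerance = 1e-12)
  expect_equal(r0$Q, 0)
  expect_equal(r0$std_error, 1 / sqrt(sum(bx^2 / 0.02^2)))
})

test_that("IVW is invariant to joint sign-flips of single variants", {
  h <- simulate_harmonized(k = 30, theta = 0.2, seed = 57)
  base <- mr_ivw(h)
  flipped <- h
  flipped$beta_exposure[c(3, 11)] <- -flipped$beta_exposure[c(3, 11)]
  flipped$beta_outcome[c(3, 11)] <- -flipped$beta_outcome[c(3, 11)]
  expect_equal(mr_ivw(flipped)$estimate, base$estimate, tolerance = 1e-14)
  expect_equal(mr_ivw(flipped)$Q, base$Q, tolerance = 1e-12)
})

test_that("Egger recovers directional pleiotropy and agrees with IVW when clean", {
  h <- simulate_harmonized(k = 100, theta = 0.2, seed = 59,
                           pleiotropy_mode = "directional", mu_alpha = 0.05)
  eg <- mr_egger(h)
  int <- eg[eg$method == "egger_intercept", ]
  expect_equal(int$estimate, 0.05, tolerance = 3 * int$std_error / 0.05)
  expect_lt(abs(int$estimate - 0.05), 0.03)
  # clean strong instruments: slope close to IVW
  hc <- simulate_harmonized(k = 100, theta = 0.2, seed = 61)
  egc <- mr_egger(hc)
  expect_equal(egc$estimate[egc$method == "egger"], mr_ivw(hc)$estimate,
               tolerance = 0.05)
  # boundary: skipped below 3 instruments
  expect_message(out <- mr_egger(hc[1:2, ]), "skipped")
  expect_null(out)
})

test_that("weighted median interpolates ratios and tolerates invalid instruments", {
  # equal weights, odd k: exactly the middle ratio
  bx <- rep(1, 5)
  by <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h <- make_harmonized(bx, by, rep(0.01, 5), rep(0.05, 5))
  wm <- mr_weighted_median(h, bootstrap_draws = 50, seed = 1)
  expect_equal(wm$estimate, 0.3)
  # 60% valid (theta = 0.3), 40% invalid (ratio 1), precise stats
  k <- 50
  set.seed(63)
  bx2 <- runif(k, 0.1, 0.3)
  valid <- seq_len(k) <= 30
  by2 <- ifelse(valid, 0.3 * bx2, 1.0 * bx2)
  h2 <- make_harmonized(bx2, by2, rep(1e-4, k), rep(1e-4, k))
  wm2 <- mr_weighted_median(h2, bootstrap_draws = 100, seed = 2)
  expect_equal(wm2$estimate, 0.3, tolerance = 0.05 / 0.3)
  # determinism of the bootstrap SE
  expect_identical(mr_weighted_median(h2, bootstrap_draws = 100, seed = 2),
                   wm2)
  expect_message(expect_null(mr_weighted_median(h[1:2, ])), "skipped")
})

test_that("RAPS recovers the causal effect and detects overdispersion", {
  h <- simulate_harmonized(k = 60, theta = 0.3, seed = 67)
  r <- mr_raps(h)
  expect_equal(r$estimate, 0.3, tolerance = 0.1)
  expect_lt(r$overdispersion, 0.002)
  expect_true(r$converged)
  # balanced pleiotropy inflates the overdispersion estimate
  hb <- simulate_harmonized(k = 60, theta = 0.3, seed = 69,
                            pleiotropy_mode = "balanced", alpha_sd = 0.05)
  rb <- mr_raps(hb)
  expect_gt(rb$overdispersion, r$overdispersion)
  expect_gt(rb$overdispersion, 1e-4)
  # huber loss gives a comparable estimate on clean data
  rh <- mr_raps(h, loss = "huber")
  expect_equal(rh$estimate, r$estimate, tolerance = 0.05)
})

test_that("instrument strength is (beta/se)^2 with a median summary", {
  h <- make_harmonized(c(0.1, 0, 0.02, 0.0447213595, 0.1),
                       rep(0.01, 5), c(0.02, 0.01, 0.01, 0.02, 0.01),
                       rep(0.01, 5))
  s <- instrument_strength(h)
  expect_equal(s$per_variant$F[1], 25)
  expect_equal(s$per_variant$F[2], 0)
  # three variants with F {4, 5, 100} -> median 5
  h3 <- make_harmonized(c(0.02, 0.1, 0.1), rep(0.01, 3),
                        c(0.01, 0.1 / sqrt(5), 0.01), rep(0.01, 3))
  expect_equal(instrument_strength(h3)$median_f, 5, tolerance = 1e-10)
})

test_that("leave-one-out flags dominant outliers and handles k = 2", {
  h <- simulate_harmonized(k = 20, theta = 0.2, seed = 71)
  h$beta_outcome[7] <- h$beta_outcome[7] + 12 * h$se_outcome[7]
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 20)
  expect_true(loo$flagged[7])
  # identical instruments: all estimates equal the full one
  hi <- make_harmonized(rep(0.1, 4), rep(0.05, 4), rep(0.01, 4), rep(0.01, 4))
  looi <- leave_one_out(hi)
  expect_equal(looi$estimate, rep(0.5, 4))
  expect_false(any(looi$flagged))
  h2 <- make_harmonized(c(0.1, 0.2), c(0.05, 0.09), rep(0.01, 2), rep(0.01, 2))
  loo2 <- leave_one_out(h2)
  expect_equal(loo2$estimate, c(0.09 / 0.2, 0.05 / 0.1))
})

test_that("run_mr assembles the full bundle with the triangulation verdict", {
  tr <- gwas_truth(k_snps = 40, theta = -0.75, gamma = {
    set.seed(73); runif(40, 0.05, 0.2)
  }, palindromic_frac = 0, seed = 73)
  pair <- generate_gwas_pair(tr)
  res <- run_mr(pair$exposure, pair$outcome, already_selected = TRUE,
                binary_outcome = TRUE, weighted_median_draws = 100,
                presso_n_sim = 200, seed = 3)
  ivw <- res$methods[res$methods$method == "ivw", ]
  expect_equal(ivw$or, exp(-0.75), tolerance = 0.1)
  expect_equal(res$verdict, "significant")
  expect_true(all(c("ivw", "egger", "egger_intercept", "weighted_median",
                    "raps", "wald_ratio") %in% res$methods$method))
  expect_false(res$methods$estimable[res$methods$method == "wald_ratio"])
  expect_equal(nrow(res$leave_one_out), res$k)
  expect_s3_class(glance(res), "tbl_df")
  expect_identical(tidy(res), res$methods)
})

test_that("run_mr with a single instrument reports Wald only", {
  tr <- gwas_truth(k_snps = 1, theta = 0.4, gamma = 0.15,
                   palindromic_frac = 0, seed = 79)
  pair <- generate_gwas_pair(tr)
  res <- suppressMessages(run_mr(pair$exposure, pair$outcome,
                                 already_selected = TRUE, seed = 1))
  m <- res$methods
  expect_true(m$estimable[m$method == "wald_ratio"])
  expect_false(any(m$estimable[m$method %in%
                                 c("egger", "weighted_median", "raps")]))
  expect_equal(res$verdict, "not_assessable")
  expect_null(res$presso)
})

test_that("a null causal effect rarely yields a significant verdict", {
  verdicts <- vapply(1:40, function(r) {
    tr <- gwas_truth(k_snps = 20, theta = 0, gamma = {
      set.seed(120 + r); runif(20, 0.05, 0.2)
    }, palindromic_frac = 0, seed = 120 + r)
    pair <- generate_gwas_pair(tr)
    res <- suppressMessages(run_mr(pair$exposure, pair$outcome,
                                   already_selected = TRUE,
                                   weighted_median_draws = 50,
                                   presso_n_sim = 200, seed = r))
    res$verdict
  }, character(1))
  expect_gte(mean(verdicts == "not_significant"), 0.9)
})
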