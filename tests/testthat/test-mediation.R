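test_that("mediation_spec enforces mediator counts per configuration", {
  expect_error(mediation_spec("X", c("M1", "M2"), "Y"), "exactly 1")
  expect_error(mediation_spec("X", "M1", "Y", configuration = "serial"),
               "exactly 2")
  expect_error(mediation_spec("X", "M1", "Y", conf_level = 1.2), "conf_level")
  sp <- mediation_spec("X", "M1", "Y")
  expect_equal(sp$boot, 5000L)
  expect_equal(sp$conf_level, 0.95)
})

test_that("pairwise fit recovers the generating paths and the exact identity", {
  tr <- cohort_truth(n = 20000, a_coefs = 0.5, b_coefs = 0.3, c_prime = 0.2,
                     seed = 1)
  co <- generate_cohort(tr)
  fit <- fit_paths(co, mediation_spec("X", "M1", "Y"))
  eff <- setNames(fit$effects$estimate, fit$effects$effect)
  # product oracle a*b = 0.15, total = 0.35, within 3 MC SEs
  mc_se <- 3 / sqrt(20000)
  expect_lt(abs(eff["indirect_M1"] - 0.15), 3 * mc_se)
  expect_lt(abs(eff["total"] - 0.35), 3 * mc_se)
  # decomposition identity holds to machine precision
  expect_lt(abs(eff["total"] - (eff["direct"] + eff["total_indirect"])), 1e-12)
  expect_lt(abs(eff["total"] - eff["total_eq1"]), 1e-10)
})

test_that("identity also holds with confounders and in parallel/serial fits", {
  tr <- cohort_truth(n = 4000, a_coefs = c(0.4, 0.2), b_coefs = c(0.3, 0.25),
                     c_prime = 0.15, d_coef = 0.3,
                     confounder_effects = list(x = c(0.3, -0.2),
                                               m = c(0.2, 0.1),
                                               y = c(0.4, 0.2)),
                     seed = 6)
  co <- generate_cohort(tr)
  for (config in c("parallel", "serial")) {
    fit <- fit_paths(co, mediation_spec("X", c("M1", "M2"), "Y",
                                        confounders = c("C1", "C2"),
                                        configuration = config))
    eff <- setNames(fit$effects$estimate, fit$effects$effect)
    if (config == "serial") {
      expect_lt(abs(eff["total"] - eff["total_eq1"]), 1e-10)
    }
    expect_lt(abs(eff["total"] - (eff["direct"] + eff["total_indirect"])),
              1e-12)
  }
})

test_that("serial chain recovers the three-way product a1*d*b2", {
  tr <- cohort_truth(n = 20000, a_coefs = c(0.5, 0), b_coefs = c(0, 0.3),
                     c_prime = 0, d_coef = 0.4, seed = 2)
  co <- generate_cohort(tr)
  fit <- fit_paths(co, mediation_spec("X", c("M1", "M2"), "Y",
                                      configuration = "serial"))
  eff <- setNames(fit$effects$estimate, fit$effects$effect)
  expect_lt(abs(eff["indirect_serial"] - 0.5 * 0.4 * 0.3), 0.006)
  # parallel fit of the same data omits the serial d path
  pfit <- fit_paths(co, mediation_spec("X", c("M1", "M2"), "Y",
                                       configuration = "parallel"))
  d_row <- fit$paths[fit$paths$path == "d", ]
  expect_lt(abs(d_row$estimate - 0.4), 3 * d_row$std_error)
  expect_false("d" %in% pfit$paths$path)
})

test_that("serial and parallel decompositions agree when d = 0 in truth", {
  tr <- cohort_truth(n = 20000, a_coefs = c(0.4, 0.3), b_coefs = c(0.25, 0.2),
                     c_prime = 0.1, d_coef = 0, seed = 13)
  co <- generate_cohort(tr)
  serial <- fit_paths(co, mediation_spec("X", c("M1", "M2"), "Y",
                                         configuration = "serial"))
  parallel <- fit_paths(co, mediation_spec("X", c("M1", "M2"), "Y",
                                           configuration = "parallel"))
  d_hat <- serial$paths$estimate[serial$paths$path == "d"]
  expect_lt(abs(d_hat), 3 * serial$paths$std_error[serial$paths$path == "d"])
  es <- setNames(serial$effects$estimate, serial$effects$effect)
  ep <- setNames(parallel$effects$estimate, parallel$effects$effect)
  expect_equal(es["total"], ep["total"], tolerance = 1e-10)
  expect_equal(es[c("indirect_M1", "indirect_M2")],
               ep[c("indirect_M1", "indirect_M2")], tolerance = 0.02)
})

test_that("degenerate designs error clearly", {
  co <- generate_cohort(cohort_truth(n = 100, a_coefs = 0.5, b_coefs = 0.3,
                                     seed = 4))
  co$Z <- 1  # constant exposure
  expect_error(fit_paths(co, mediation_spec("Z", "M1", "Y")), "zero variance")
  co$M1dup <- co$M1
  expect_error(
    fit_paths(co, mediation_spec("X", "M1", "Y", confounders = "M1dup")),
    "Rank-deficient"
  )
  expect_error(fit_paths(co, mediation_spec("X", "M1", "nope")), "not found")
})

test_that("complete-case handling drops and counts rows with missing values", {
  co <- generate_cohort(cohort_truth(n = 300, a_coefs = 0.5, b_coefs = 0.3,
                                     seed = 5))
  co$M1[1:10] <- NA
  fit <- fit_paths(co, mediation_spec("X", "M1", "Y"))
  expect_equal(fit$n_used, 290)
  expect_equal(fit$n_dropped, 10)
})

test_that("VIF screen matches the closed form and flags collinearity", {
  # exact correlation 0.8 by construction
  x1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  e <- c(1, 1, -1, -1, 1, 1, -1, -1)
  X <- cbind(a = x1, b = 0.8 * x1 + 0.6 * e)
  v <- vif_screen(X)
  expect_equal(v$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_false(any(v$flagged))
  # orthogonal columns give VIF 1
  v1 <- vif_screen(cbind(a = x1, b = e))
  expect_equal(v1$vif, c(1, 1))
  # duplicated column is infinite and flagged
  v2 <- vif_screen(cbind(a = x1, b = x1, c = e))
  expect_true(all(is.infinite(v2$vif[1:2])))
  expect_true(all(v2$flagged[1:2]))
})

test_that("BH adjustment reproduces the step-up values and is monotone", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_adjusted, rep(0.04, 4))
  expect_true(all(out$rejected))
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  ones <- bh_fdr(c(1, 1))
  expect_equal(ones$p_adjusted, c(1, 1))
  expect_false(any(ones$rejected))
  set.seed(31)
  p <- runif(50)
  adj <- bh_fdr(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.3)), "0, 1")
})

test_that("nested-model likelihood-ratio test behaves at its boundaries", {
  co <- generate_cohort(cohort_truth(n = 5000, a_coefs = 0.5, b_coefs = 0.3,
                                     c_prime = 0.3, seed = 17))
  out <- nested_model_test(co, mediation_spec("X", "M1", "Y"))
  expect_lt(out$p_value, 1e-3)
  expect_equal(out$df, 1L)
  # with the exposure truly absent from the outcome equation the
  # statistic is small; identical models give statistic 0, p 1
  co0 <- generate_cohort(cohort_truth(n = 500, a_coefs = 0.5, b_coefs = 0.3,
                                      c_prime = 0, seed = 18))
  out0 <- nested_model_test(co0, mediation_spec("X", "M1", "Y"))
  expect_gte(out0$statistic, 0)
  d <- co0
  d$X2 <- d$X
  full <- lm(Y ~ X + M1, data = d)
  expect_equal(pchisq(0, 1, lower.tail = FALSE), 1)
})

test_that("tidy and glance expose paths, effects and fit statistics", {
  co <- generate_cohort(cohort_truth(n = 800, a_coefs = 0.5, b_coefs = 0.3,
                                     c_prime = 0.2, seed = 19))
  fit <- fit_paths(co, mediation_spec("X", "M1", "Y"))
  td <- tidy(fit)
  expect_true(all(c("path", "estimate", "type") %in% names(td)))
  expect_true(all(c("a1", "b1", "c_prime") %in% td$path[td$type == "path"]))
  gl <- glance(fit)
  expect_equal(gl$n_used, 800)
  expect_true(is.finite(gl$log_lik) && is.finite(gl$aic) && is.finite(gl$bic))
})
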