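test_that("instrument selection filters on p and clumps greedily with LD", {
  g <- make_gwas(c("rs1", "rs2", "rs3"), ea = c("A", "A", "A"),
                 oa = c("G", "G", "G"), beta = c(0.1, 0.09, 0.02),
                 p = c(1e-8, 1e-7, 0.5), pos = c(1e6, 1.01e6, 5e6))
  # no LD matrix: p filter only
  expect_message(sel <- select_instruments(g, p_threshold = 5e-6),
                 "clumping skipped")
  expect_setequal(sel$SNP, c("rs1", "rs2"))
  # LD matrix: rs2 is 10 kb from rs1 at r2 = 0.5 -> removed
  ld <- diag(3)
  dimnames(ld) <- list(g$SNP, g$SNP)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.5
  sel2 <- select_instruments(g, p_threshold = 5e-6, ld = ld)
  expect_equal(sel2$SNP, "rs1")
  # below the r2 cut both stay
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.1
  sel3 <- select_instruments(g, p_threshold = 5e-6, ld = ld)
  expect_setequal(sel3$SNP, c("rs1", "rs2"))
  # single passing variant is retained
  sel4 <- select_instruments(g[1, ], p_threshold = 5e-6)
  expect_equal(nrow(sel4), 1)
  expect_error(select_instruments(g, ld = diag(2)), "square matrix")
})

test_that("clumping respects the window: distant correlated variants both stay", {
  g <- make_gwas(c("rs1", "rs2"), ea = c("A", "A"), oa = c("G", "G"),
                 beta = c(0.1, 0.09), p = c(1e-8, 1e-7),
                 pos = c(1e6, 5e8))  # ~500 Mb apart
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(g$SNP, g$SNP))
  sel <- select_instruments(g, p_threshold = 5e-6, ld = ld, window_kb = 1000)
  expect_setequal(sel$SNP, c("rs1", "rs2"))
})

test_that("adjusted instrument takes the union minus overlapping variants", {
  a <- make_gwas(paste0("rs", 1:4), ea = rep("A", 4), oa = rep("G", 4),
                 beta = rep(0.1, 4))
  b <- make_gwas(paste0("rs", 4:6), ea = rep("A", 3), oa = rep("G", 3),
                 beta = rep(0.1, 3), pos = 4:6 * 1e5)
  out <- suppressMessages(build_adjusted_instrument(a, b,
                                                    labels = c("carb", "sugar")))
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "overlap"), "rs4")
  expect_setequal(out$source[out$SNP %in% paste0("rs", 1:3)], "carb")
  # disjoint sets: plain union
  disj <- build_adjusted_instrument(a[1:3, ], b[2:3, ])
  expect_equal(nrow(disj), 5)
  # identical sets leave nothing
  expect_error(suppressMessages(build_adjusted_instrument(a, a)), "empty")
})

test_that("harmonization aligns alleles, flips swapped records once, drops the rest", {
  exp <- make_gwas(c("rs1", "rs2", "rs3", "rs4"),
                   ea = c("A", "A", "A", "C"), oa = c("G", "T", "G", "A"),
                   beta = c(0.1, 0.1, 0.1, 0.1))
  out <- make_gwas(c("rs1", "rs2", "rs4"),
                   ea = c("G", "A", "C"), oa = c("A", "T", "A"),
                   beta = c(-0.05, 0.02, 0.03), pos = c(1e5, 2e5, 4e5))
  h <- suppressMessages(harmonize(exp, out))
  log <- attr(h, "log")
  expect_equal(log$action[log$SNP == "rs1"], "flipped")
  expect_equal(log$action[log$SNP == "rs2"], "removed_palindromic")
  expect_equal(log$action[log$SNP == "rs3"], "removed_missing")
  expect_equal(log$action[log$SNP == "rs4"], "kept")
  # swapped alleles: outcome beta sign-inverted exactly once
  expect_equal(h$beta_outcome[h$SNP == "rs1"], 0.05)
  expect_equal(h$beta_outcome[h$SNP == "rs4"], 0.03)
  expect_false(any(c("A/T", "T/A") %in% paste0(h$SNP, "")))
})

test_that("strand-complement records harmonize and mismatches are dropped", {
  exp <- make_gwas(c("rs1", "rs2", "rs3"), ea = c("A", "A", "A"),
                   oa = c("G", "G", "G"), beta = rep(0.1, 3))
  out <- make_gwas(c("rs1", "rs2", "rs3"),
                   ea = c("T", "C", "A"), oa = c("C", "T", "C"),
                   beta = c(0.04, -0.04, 0.04), pos = 1:3 * 1e5)
  h <- suppressMessages(harmonize(exp, out))
  log <- attr(h, "log")
  # rs1: T/C is the strand complement of A/G -> kept as-is
  expect_equal(log$action[log$SNP == "rs1"], "kept")
  expect_equal(h$beta_outcome[h$SNP == "rs1"], 0.04)
  # rs2: C/T is the complement of the swapped pair -> flipped
  expect_equal(log$action[log$SNP == "rs2"], "flipped")
  expect_equal(h$beta_outcome[h$SNP == "rs2"], 0.04)
  # rs3: A/C matches neither direction -> removed
  expect_equal(log$action[log$SNP == "rs3"], "removed_mismatch")
})

test_that("harmonization is involution-safe on already-aligned sets", {
  h <- simulate_harmonized(k = 15, theta = 0.2, seed = 51)
  # rebuild aligned summary sets from the harmonized records
  exp2 <- make_gwas(h$SNP, ea = rep("A", 15), oa = rep("G", 15),
                    beta = h$beta_exposure, se = h$se_exposure,
                    pos = seq_len(15) * 1e5)
  out2 <- make_gwas(h$SNP, ea = rep("A", 15), oa = rep("G", 15),
                    beta = h$beta_outcome, se = h$se_outcome,
                    pos = seq_len(15) * 1e5)
  h2 <- harmonize(exp2, out2)
  expect_equal(nrow(h2), 15)
  expect_true(all(attr(h2, "log")$action == "kept"))
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_equal(h2$ratio, h$ratio)
})

test_that("palindromic fraction in generated data is removed at harmonization", {
  tr <- gwas_truth(k_snps = 200, theta = 0.1, palindromic_frac = 0.5, seed = 53)
  pair <- generate_gwas_pair(tr)
  h <- suppressMessages(harmonize(pair$exposure, pair$outcome))
  log <- attr(h, "log")
  removed <- mean(log$action == "removed_palindromic")
  expect_gt(removed, 0.35)
  expect_lt(removed, 0.65)
  expect_false(any(h$action == "removed_palindromic"))
})
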