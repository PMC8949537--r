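# Shared fixture builders: everything is generated in code at test time.

# harmonized instrument set built directly from numeric vectors, for
# estimator tests that need exact control over betas and SEs
make_harmonized <- function(beta_exposure, beta_outcome, se_exposure,
                            se_outcome) {
  k <- length(beta_exposure)
  out <- tibble::tibble(
    SNP = sprintf("rs%03d", seq_len(k)),
    CHR = rep_len(1:22, k), POS = seq_len(k) * 2e6,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    action = "kept",
    ratio = beta_outcome / beta_exposure,
    ratio_se = se_outcome / abs(beta_exposure)
  )
  structure(out, class = c("harmonized_instruments", class(out)))
}

# tiny GWAS summary tibble with explicit alleles
make_gwas <- function(snp, ea, oa, beta, se = 0.02, p = NULL, chr = 1,
                      pos = seq_along(snp) * 1e5, eaf = 0.3, n = 1e5) {
  p <- p %||% 2 * stats::pnorm(-abs(beta / se))
  tibble::tibble(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa,
                 EAF = eaf, BETA = beta, SE = se, P = p, N = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized set drawn from the generator (no palindromic variants so k
# is exact), used by simulation-based estimator tests
simulate_harmonized <- function(k, theta, seed, gamma = NULL,
                                pleiotropy_mode = "none", mu_alpha = 0.05,
                                alpha_sd = 0.05,
                                n_exposure = 250000, n_outcome = 100000) {
  gamma <- gamma %||% { set.seed(seed + 10000L); runif(k, 0.03, 0.2) }
  tr <- gwas_truth(k_snps = k, theta = theta, gamma = gamma,
                   pleiotropy_mode = pleiotropy_mode, mu_alpha = mu_alpha,
                   alpha_sd = alpha_sd, n_exposure = n_exposure,
                   n_outcome = n_outcome, palindromic_frac = 0, seed = seed)
  pair <- generate_gwas_pair(tr)
  suppressMessages(harmonize(pair$exposure, pair$outcome))
}
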