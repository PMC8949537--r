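#' Ground truth for a synthetic two-sample GWAS summary pair
#'
#' Parameterizes paired exposure/outcome summary statistics for `k_snps`
#' independent variants: per-variant exposure effects `gamma`, a causal
#' effect `theta` of the exposure on the outcome, and per-variant direct
#' (pleiotropic) outcome effects `alpha`. Standard errors follow the usual
#' GWAS approximation `se = 1/sqrt(2 N maf (1-maf))`, so instrument
#' strength (F = (beta/se)^2) is controlled through the sample sizes.
#'
#' Pleiotropy regimes:
#' * `none` — all `alpha = 0` (valid instruments).
#' * `balanced` — `alpha ~ N(0, alpha_sd)` re-centered to exact mean 0.
#' * `directional` — `alpha ~ N(mu_alpha, alpha_sd)`, independent of
#'   `gamma` (the InSIDE assumption holds, so the MR-Egger intercept
#'   estimates `mu_alpha`).
#' * `inside_violating` — `alpha` correlated with `gamma`, breaking
#'   InSIDE.
#'
#' @param k_snps Number of instruments (>= 1).
#' @param theta True causal effect per unit of exposure.
#' @param gamma Per-variant exposure effects; scalar recycled or length
#'   `k_snps`.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param mu_alpha Mean direct effect under `directional` (default 0.05).
#' @param alpha_sd SD of direct effects where drawn (default 0.05).
#' @param n_exposure,n_outcome GWAS sample sizes (>= 1).
#' @param maf_range Effect-allele frequency bounds, within (0, 0.5].
#' @param palindromic_frac Expected fraction of A/T or C/G variants
#'   (default 0.1), to exercise harmonization filters.
#' @param seed Integer seed.
#' @return A `gwas_truth` list (includes the realized `alpha` draws).
#' @export
gwas_truth <- function(k_snps, theta = 0, gamma = 0.1,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       mu_alpha = 0.05, alpha_sd = 0.05,
                       n_exposure = 250000, n_outcome = 100000,
                       maf_range = c(0.05, 0.5), palindromic_frac = 0.1,
                       seed = 1) {
  check_number(k_snps, "k_snps", lower = 1)
  check_number(n_exposure, "n_exposure", lower = 1)
  check_number(n_outcome, "n_outcome", lower = 1)
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be increasing bounds within (0, 0.5].")
  }
  check_number(palindromic_frac, "palindromic_frac", lower = 0, upper = 1)
  k <- as.integer(k_snps)
  gamma <- rep_len(gamma, k)
  alpha <- with_seed(as.integer(seed) + 1L, switch(
    pleiotropy_mode,
    none = rep(0, k),
    balanced = { a <- rnorm(k, 0, alpha_sd); a - mean(a) },
    directional = rnorm(k, mu_alpha, alpha_sd),
    inside_violating = 0.5 * (gamma - mean(gamma)) + rnorm(k, 0, alpha_sd / 2)
  ))
  structure(
    list(k_snps = k, theta = theta, gamma = gamma, alpha = alpha,
         pleiotropy_mode = pleiotropy_mode, mu_alpha = mu_alpha,
         alpha_sd = alpha_sd, n_exposure = n_exposure, n_outcome = n_outcome,
         maf_range = maf_range, palindromic_frac = palindromic_frac,
         seed = as.integer(seed)),
    class = "gwas_truth"
  )
}

# allele pairs: non-palindromic vs palindromic (A/T, C/G)
.allele_pairs <- function(k, palindromic_frac) {
  non_pal <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
  pal <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                ncol = 2, byrow = TRUE)
  is_pal <- runif(k) < palindromic_frac
  idx_np <- sample(nrow(non_pal), k, replace = TRUE)
  idx_p <- sample(nrow(pal), k, replace = TRUE)
  ea <- ifelse(is_pal, pal[idx_p, 1], non_pal[idx_np, 1])
  oa <- ifelse(is_pal, pal[idx_p, 2], non_pal[idx_np, 2])
  list(ea = ea, oa = oa)
}

#' Generate a paired exposure/outcome GWAS summary set
#'
#' Exposure effects are drawn as `beta_X ~ N(gamma, se_X^2)` and outcome
#' effects as `beta_Y ~ N(theta * gamma + alpha, se_Y^2)`; two-sided
#' p-values come from the normal approximation. Variants are placed on
#' distinct chromosomes/positions (independent instruments; LD only via a
#' user-supplied matrix downstream).
#'
#' @param truth A [gwas_truth()] object.
#' @return List with tibbles `exposure` and `outcome` (columns `SNP`,
#'   `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`) and the
#'   `truth` used.
#' @export
#' @examples
#' pair <- generate_gwas_pair(gwas_truth(k_snps = 20, theta = 0.2, seed = 7))
#' head(pair$exposure)
generate_gwas_pair <- function(truth) {
  if (!inherits(truth, "gwas_truth")) abort("`truth` must be a `gwas_truth`.")
  with_seed(truth$seed, {
    k <- truth$k_snps
    maf <- runif(k, truth$maf_range[1], truth$maf_range[2])
    se_x <- 1 / sqrt(2 * truth$n_exposure * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * truth$n_outcome * maf * (1 - maf))
    beta_x <- rnorm(k, truth$gamma, se_x)
    beta_y <- rnorm(k, truth$theta * truth$gamma + truth$alpha, se_y)
    al <- .allele_pairs(k, truth$palindromic_frac)
    snp <- sprintf("rs%06d", seq_len(k))
    chr <- rep_len(1:22, k)
    pos <- 1e6L + 2e6L * (seq_len(k) - 1L)
    mk <- function(beta, se, n) tibble::tibble(
      SNP = snp, CHR = chr, POS = pos, EA = al$ea, OA = al$oa, EAF = maf,
      BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)), N = n
    )
    list(exposure = mk(beta_x, se_x, truth$n_exposure),
         outcome = mk(beta_y, se_y, truth$n_outcome),
         truth = truth)
  })
}

#' Write a GWAS summary set as TSV
#'
#' Standard tab-separated layout with header `SNP CHR POS EA OA EAF BETA
#' SE P N`; a sidecar JSON (`<path>.truth.json`) records the generating
#' truth when supplied.
#'
#' @param gwas Tibble in the summary-set layout.
#' @param path Output TSV path.
#' @param truth Optional [gwas_truth()] to record alongside.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path, truth = NULL) {
  readr::write_tsv(gwas, path)
  if (!is.null(truth)) {
    tj <- truth
    class(tj) <- NULL
    jsonlite::write_json(tj, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a GWAS summary set from TSV
#'
#' Requires columns `SNP`, `EA`, `OA`, `BETA`, `SE`, `P`; `CHR`, `POS`,
#' `EAF`, `N` are optional and filled with `NA` when absent.
#'
#' @param path TSV path with a header row.
#' @return Tibble in the summary-set layout.
#' @export
read_gwas_summary <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(g, c("SNP", "EA", "OA", "BETA", "SE", "P"), where = path)
  for (opt in c("CHR", "POS", "EAF", "N")) {
    if (!opt %in% names(g)) g[[opt]] <- NA_real_
  }
  validate_gwas_summary(g)
}

#' Validate a GWAS summary set
#'
#' Checks alleles are single A/C/G/T bases with effect != other allele,
#' `SE > 0`, `P` in \[0, 1\] and `EAF` in (0, 1) where present; variant
#' ids must be unique.
#'
#' @param gwas Tibble in the summary-set layout.
#' @return The validated tibble (column order normalized), or an error.
#' @export
validate_gwas_summary <- function(gwas) {
  check_columns(gwas, c("SNP", "EA", "OA", "BETA", "SE", "P"))
  if (anyDuplicated(gwas$SNP)) abort("Duplicate variant ids in summary set.")
  bases <- c("A", "C", "G", "T")
  if (!all(gwas$EA %in% bases) || !all(gwas$OA %in% bases)) {
    abort("Alleles must be single bases A/C/G/T.")
  }
  if (any(gwas$EA == gwas$OA)) abort("Effect and other allele must differ.")
  if (any(gwas$SE <= 0, na.rm = TRUE)) abort("`SE` must be positive.")
  if (any(gwas$P < 0 | gwas$P > 1, na.rm = TRUE)) abort("`P` must lie in [0, 1].")
  if (any(gwas$EAF <= 0 | gwas$EAF >= 1, na.rm = TRUE)) {
    abort("`EAF` must lie in (0, 1).")
  }
  tibble::as_tibble(gwas)
}
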