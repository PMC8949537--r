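#' Run the full two-sample MR pipeline
#'
#' Instrument selection, harmonization, the whole estimator battery and
#' its sensitivity diagnostics in one call: IVW (main analysis), MR-Egger
#' and weighted median (consistency), MR-RAPS (weak instruments),
#' MR-PRESSO (outliers), Cochran's Q, median F-statistic and
#' leave-one-out. With a single surviving instrument only the Wald ratio
#' is estimable and the other methods are marked not estimable. For
#' binary outcomes whose GWAS betas are log odds ratios, estimates are
#' additionally reported as odds ratios with exp-transformed intervals.
#'
#' The significance verdict follows a triangulation rule: an association
#' is called significant only if the IVW, weighted median and MR-Egger
#' estimates are directionally consistent, IVW p < 0.05, and the
#' MR-PRESSO global test shows no pleiotropy (p > 0.05).
#'
#' @param exposure,outcome GWAS summary tibbles.
#' @param p_threshold Instrument p-value threshold (default 5e-6).
#' @param ld Optional squared-correlation matrix for clumping.
#' @param r2_max,window_kb Clumping parameters (defaults 0.2, 1000).
#' @param binary_outcome Logical; report odds-ratio columns.
#' @param already_selected Logical; skip instrument selection.
#' @param weighted_median_draws,presso_n_sim Simulation sizes.
#' @param seed Integer seed for all stochastic components.
#' @return An `mr_result` with elements `methods` (tidy estimate table),
#'   `heterogeneity`, `presso`, `instrument_strength`, `leave_one_out`,
#'   `harmonized`, `k`, `verdict` and `counts`.
#' @export
run_mr <- function(exposure, outcome, p_threshold = 5e-6, ld = NULL,
                   r2_max = 0.2, window_kb = 1000, binary_outcome = FALSE,
                   already_selected = FALSE,
                   weighted_median_draws = 1000, presso_n_sim = 1000,
                   seed = 1) {
  selected <- if (already_selected) validate_gwas_summary(exposure) else {
    select_instruments(exposure, p_threshold = p_threshold, ld = ld,
                       r2_max = r2_max, window_kb = window_kb)
  }
  if (nrow(selected) == 0) abort("No instruments survive selection.")
  h <- harmonize(selected, outcome)
  k <- nrow(h)
  if (k == 0) abort("No instruments survive harmonization.")
  methods <- list()
  if (k == 1) {
    methods$wald <- wald_ratio(h)
  }
  methods$ivw <- mr_ivw(h)
  egger <- if (k >= 3) mr_egger(h) else {
    inform("MR-Egger not estimable with < 3 instruments."); NULL }
  wm <- if (k >= 3) {
    mr_weighted_median(h, bootstrap_draws = weighted_median_draws, seed = seed)
  } else NULL
  raps <- if (k >= 3) mr_raps(h) else NULL
  presso <- if (k >= 4) mr_presso(h, n_sim = presso_n_sim, seed = seed + 1) else {
    inform("MR-PRESSO not estimable with < 4 instruments."); NULL
  }
  tbl <- dplyr::bind_rows(c(methods, list(egger = egger, wm = wm, raps = raps)))
  # mark non-estimable methods explicitly (rendered as "-" downstream)
  all_methods <- c("ivw", "egger", "egger_intercept", "weighted_median",
                   "raps", "wald_ratio")
  missing_m <- setdiff(all_methods, tbl$method)
  if (length(missing_m)) {
    tbl <- dplyr::bind_rows(tbl, tibble::tibble(
      method = missing_m, estimate = NA_real_, std_error = NA_real_,
      ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
      n_snp = k
    ))
  }
  tbl$estimable <- !is.na(tbl$estimate)
  if (binary_outcome) {
    tbl$or <- exp(tbl$estimate)
    tbl$or_ci_lower <- exp(tbl$ci_lower)
    tbl$or_ci_upper <- exp(tbl$ci_upper)
    int <- tbl$method == "egger_intercept"
    tbl$or[int] <- NA_real_
    tbl$or_ci_lower[int] <- NA_real_
    tbl$or_ci_upper[int] <- NA_real_
  }
  het <- dplyr::filter(tbl, .data$method %in% c("ivw", "egger"),
                       !is.na(.data$estimate))
  heterogeneity <- tibble::tibble(method = het$method, Q = het$Q,
                                  Q_df = het$Q_df, Q_p = het$Q_p)
  strength <- instrument_strength(h)
  loo <- if (k >= 2) leave_one_out(h) else NULL
  verdict <- .mr_verdict(tbl, presso)
  log <- attr(h, "log")
  structure(
    list(methods = tbl, heterogeneity = heterogeneity, presso = presso,
         instrument_strength = strength, leave_one_out = loo,
         harmonized = h, k = k, binary_outcome = binary_outcome,
         verdict = verdict,
         counts = tibble::tibble(
           stage = c("input", "selected", "harmonized"),
           n = c(nrow(exposure), nrow(selected), k)
         ),
         seed = seed),
    class = "mr_result"
  )
}

# triangulated significance rule across IVW, weighted median and Egger
.mr_verdict <- function(tbl, presso) {
  get1 <- function(m) tbl[tbl$method == m, ][1, ]
  ivw <- get1("ivw")
  wm <- get1("weighted_median")
  egger <- get1("egger")
  if (!isTRUE(wm$estimable) || !isTRUE(egger$estimable)) {
    return("not_assessable")
  }
  consistent <- length(unique(sign(c(ivw$estimate, wm$estimate, egger$estimate)))) == 1
  sig <- isTRUE(ivw$p_value < 0.05)
  no_pleio <- is.null(presso) || isTRUE(presso$global_p > 0.05)
  if (consistent && sig && no_pleio) "significant" else "not_significant"
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("Two-sample MR: %d instrument(s), median F = %.1f, verdict: %s\n",
              x$k, x$instrument_strength$median_f, x$verdict))
  print(dplyr::select(dplyr::filter(x$methods, .data$estimable),
                      dplyr::any_of(c("method", "estimate", "std_error",
                                      "ci_lower", "ci_upper", "p_value", "or"))))
  invisible(x)
}

#' @export
tidy.mr_result <- function(x, ...) x$methods

#' @export
glance.mr_result <- function(x, ...) {
  ivw <- x$methods[x$methods$method == "ivw", ]
  tibble::tibble(
    k = x$k, median_f = x$instrument_strength$median_f,
    ivw_estimate = ivw$estimate, ivw_p = ivw$p_value,
    Q = ivw$Q, Q_p = ivw$Q_p,
    presso_global_p = if (is.null(x$presso)) NA_real_ else x$presso$global_p,
    verdict = x$verdict
  )
}
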