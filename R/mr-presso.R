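# leave-one-out IVW estimates, vectorized: theta_{-j} for every j
.loo_ivw <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy by comparing the observed weighted
#' residual sum of squares — each variant's outcome beta against the
#' prediction of the IVW model fitted without it — with its distribution
#' under a simulated no-pleiotropy null (parametric redraws of both beta
#' vectors). Three components:
#'
#' * global test: empirical p for the total RSS;
#' * outlier test: per-variant empirical p for its RSS contribution,
#'   Bonferroni-corrected across variants;
#' * distortion test: empirical p for the change in the IVW estimate
#'   after removing the flagged outliers, against random pseudo-outlier
#'   sets of the same size.
#'
#' The corrected estimate is the IVW fit on the non-outlying variants.
#'
#' @param h Harmonized instrument set (k >= 4).
#' @param n_sim Simulated null datasets (>= 100; default 1000).
#' @param seed Integer seed.
#' @param alpha Outlier-test significance level after Bonferroni
#'   (default 0.05).
#' @return An `mr_presso` list: `global_rss`, `global_p`, `outliers`
#'   (tibble with per-variant p), `outlier_indices`, `distortion_p`,
#'   `corrected` (IVW row or NULL), `n_sim`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1, alpha = 0.05) {
  .check_harmonized(h, 4, "mr_presso")
  if (n_sim < 100) abort("`n_sim` must be at least 100.")
  k <- nrow(h)
  bx <- h$beta_exposure; by <- h$beta_outcome
  sx <- h$se_exposure; sy <- h$se_outcome
  w <- 1 / sy^2
  theta_loo <- .loo_ivw(bx, by, w)
  contrib_obs <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(contrib_obs)
  with_seed(seed, {
    contrib_sim <- matrix(NA_real_, n_sim, k)
    for (s in seq_len(n_sim)) {
      bx_s <- rnorm(k, bx, sx)
      by_s <- rnorm(k, theta_loo * bx, sy)  # null: each variant fits its LOO model
      th_s <- .loo_ivw(bx_s, by_s, w)
      contrib_sim[s, ] <- w * (by_s - th_s * bx_s)^2
    }
    rss_sim <- rowSums(contrib_sim)
    global_p <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)
    p_out <- vapply(seq_len(k), function(j) {
      (sum(contrib_sim[, j] >= contrib_obs[j]) + 1) / (n_sim + 1)
    }, numeric(1))
    p_out_bonf <- pmin(1, p_out * k)
    outlier_idx <- which(p_out_bonf < alpha)
    outliers <- tibble::tibble(SNP = h$SNP, rss_contribution = contrib_obs,
                               p_value = p_out, p_bonferroni = p_out_bonf,
                               outlier = seq_len(k) %in% outlier_idx)
    distortion_p <- NA_real_
    corrected <- NULL
    if (length(outlier_idx) > 0 && length(outlier_idx) < k - 1) {
      full <- mr_ivw(h)
      corrected <- mr_ivw(h[-outlier_idx, , drop = FALSE])
      d_obs <- 100 * (full$estimate - corrected$estimate) /
        abs(corrected$estimate)
      d_sim <- vapply(seq_len(n_sim), function(s) {
        fake <- sample.int(k, length(outlier_idx))
        est_no <- mr_ivw(h[-fake, , drop = FALSE])$estimate
        100 * (full$estimate - est_no) / abs(est_no)
      }, numeric(1))
      distortion_p <- (sum(abs(d_sim) >= abs(d_obs)) + 1) / (n_sim + 1)
    }
    structure(
      list(global_rss = rss_obs, global_p = global_p,
           outliers = outliers, outlier_indices = outlier_idx,
           distortion_p = distortion_p, corrected = corrected,
           n_sim = n_sim, alpha = alpha),
      class = "mr_presso"
    )
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4g (%d sims)\n",
              x$global_rss, x$global_p, x$n_sim))
  n_out <- length(x$outlier_indices)
  if (n_out) {
    cat(sprintf("Outliers (%d): %s; distortion p = %.4g\n", n_out,
                paste(x$outliers$SNP[x$outlier_indices], collapse = ", "),
                x$distortion_p))
    cat(sprintf("Outlier-corrected IVW estimate: %.4f (SE %.4f)\n",
                x$corrected$estimate, x$corrected$std_error))
  } else {
    cat("No outliers detected.\n")
  }
  invisible(x)
}
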