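.check_harmonized <- function(h, min_k = 1, caller = "estimator") {
  if (!inherits(h, "harmonized_instruments")) {
    check_columns(h, c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome"),
                  where = "instruments")
  }
  if (nrow(h) < min_k) {
    abort(sprintf("%s requires at least %d instrument(s), got %d.",
                  caller, min_k, nrow(h)))
  }
  invisible(h)
}

.mr_row <- function(method, estimate, se, p = NULL, n_snp = NA_integer_) {
  p <- p %||% 2 * pnorm(-abs(estimate / se))
  tibble::tibble(method = method, estimate = estimate, std_error = se,
                 ci_lower = estimate - qnorm(0.975) * se,
                 ci_upper = estimate + qnorm(0.975) * se,
                 p_value = p, n_snp = as.integer(n_snp))
}

#' Wald ratio estimate from a single instrument
#'
#' `estimate = beta_outcome / beta_exposure`; the standard error is the
#' first-order delta approximation `se_outcome / |beta_exposure|`.
#'
#' @param h Harmonized instrument set with exactly one variant (or a
#'   one-row slice).
#' @return One-row tibble with `method = "wald_ratio"`.
#' @export
wald_ratio <- function(h) {
  .check_harmonized(h, 1, "wald_ratio")
  if (nrow(h) != 1) abort("wald_ratio expects exactly one variant.")
  if (h$beta_exposure == 0) abort("beta_exposure is zero: Wald ratio undefined.")
  .mr_row("wald_ratio", h$beta_outcome / h$beta_exposure,
          h$se_outcome / abs(h$beta_exposure), n_snp = 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_outcome^2`; equivalently the
#' inverse-variance-weighted average of per-variant Wald ratios. The
#' standard error uses multiplicative random effects with the residual
#' scale floored at 1, so it can never shrink below the fixed-effect SE.
#' Cochran's Q (k-1 df) quantifies heterogeneity. With one instrument
#' this reduces exactly to the Wald ratio.
#'
#' @param h Harmonized instrument set (k >= 1).
#' @return One-row tibble with estimate, SE, CI, p, `Q`, `Q_df`, `Q_p`.
#' @export
mr_ivw <- function(h) {
  .check_harmonized(h, 1, "mr_ivw")
  w <- 1 / h$se_outcome^2
  bx <- h$beta_exposure; by <- h$beta_outcome
  est <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- 1 / sqrt(sum(w * bx^2))
  k <- nrow(h)
  Q <- sum(w * (by - est * bx)^2)
  phi <- if (k > 1) max(1, Q / (k - 1)) else 1
  se <- se_fe * sqrt(phi)
  out <- .mr_row("ivw", est, se, n_snp = k)
  out$Q <- Q
  out$Q_df <- k - 1L
  out$Q_p <- if (k > 1) pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept (weights `1/se_outcome^2`), after orienting every variant so
#' its exposure beta is non-negative (required for the intercept to be
#' identifiable). Under the InSIDE assumption the intercept estimates the
#' average directional pleiotropic effect and the slope remains a
#' consistent causal estimate. The residual scale is floored at 1
#' (multiplicative random effects); Q is reported on k-2 df. Requires at
#' least 3 instruments; with fewer the method is skipped with a message.
#'
#' @param h Harmonized instrument set (k >= 3).
#' @return Two-row tibble (`egger` slope and `egger_intercept`) with Q
#'   diagnostics on the slope row, or `NULL` when k < 3.
#' @export
mr_egger <- function(h) {
  if (nrow(h) < 3) {
    inform(sprintf("MR-Egger skipped: %d instrument(s), need >= 3.", nrow(h)))
    return(NULL)
  }
  .check_harmonized(h, 3, "mr_egger")
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  k <- nrow(h)
  sm <- summary(fit)
  scale_up <- max(1, sm$sigma) / sm$sigma
  coefs <- sm$coefficients
  Q <- sum(w * residuals(fit)^2)
  slope <- .mr_row("egger", coefs["bx", 1], coefs["bx", 2] * scale_up, n_snp = k)
  slope$Q <- Q
  slope$Q_df <- k - 2L
  slope$Q_p <- pchisq(Q, k - 2, lower.tail = FALSE)
  intercept <- .mr_row("egger_intercept", coefs["(Intercept)", 1],
                       coefs["(Intercept)", 2] * scale_up, n_snp = k)
  intercept$Q <- NA_real_; intercept$Q_df <- NA_integer_; intercept$Q_p <- NA_real_
  dplyr::bind_rows(slope, intercept)
}

# weighted median of x with weights w (Bowden-style interpolation)
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(x[1])
  if (cum[length(cum)] <= 0.5) return(x[length(x)])
  below <- max(which(cum < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted median MR estimate
#'
#' Orders the per-variant Wald ratios and takes the inverse-variance
#' weighted median (linear interpolation at cumulative weight 0.5). The
#' estimate is consistent as long as variants contributing at least half
#' the weight are valid instruments. The standard error comes from a
#' seeded parametric bootstrap that redraws both beta vectors from their
#' sampling distributions.
#'
#' @param h Harmonized instrument set (k >= 3).
#' @param bootstrap_draws Parametric bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble, or `NULL` when k < 3.
#' @export
mr_weighted_median <- function(h, bootstrap_draws = 1000, seed = 1) {
  if (nrow(h) < 3) {
    inform(sprintf("Weighted median skipped: %d instrument(s), need >= 3.", nrow(h)))
    return(NULL)
  }
  .check_harmonized(h, 3, "mr_weighted_median")
  ratio <- h$beta_outcome / h$beta_exposure
  ratio_var <- h$se_outcome^2 / h$beta_exposure^2
  est <- .weighted_median(ratio, 1 / ratio_var)
  k <- nrow(h)
  boots <- with_seed(seed, {
    vapply(seq_len(bootstrap_draws), function(b) {
      bx <- rnorm(k, h$beta_exposure, h$se_exposure)
      by <- rnorm(k, h$beta_outcome, h$se_outcome)
      r <- by / bx
      v <- h$se_outcome^2 / bx^2
      .weighted_median(r, 1 / v)
    }, numeric(1))
  })
  .mr_row("weighted_median", est, sd(boots), n_snp = k)
}

# profile objective for RAPS: residual t = (by - theta*bx)/s with
# s^2 = se_y^2 + theta^2 se_x^2 + tau2; rho is squared-error or Huber
# with the Fisher-consistency constant for the log-variance term
.raps_objective <- function(par, bx, by, sx2, sy2, loss, c_huber) {
  theta <- par[1]; tau2 <- par[2]
  s2 <- sy2 + theta^2 * sx2 + tau2
  t <- (by - theta * bx) / sqrt(s2)
  if (loss == "squared") {
    sum(0.5 * t^2 + 0.5 * log(s2))
  } else {
    rho <- ifelse(abs(t) <= c_huber, 0.5 * t^2,
                  c_huber * abs(t) - 0.5 * c_huber^2)
    d_c <- 2 * pnorm(c_huber) - 1  # E[psi(Z) Z] for standard normal Z
    sum(rho + 0.5 * d_c * log(s2))
  }
}

#' Robust adjusted profile score (RAPS) MR estimate
#'
#' Maximizes the profile likelihood of the causal effect treating the
#' exposure betas as measured with error (errors in both variables) and
#' allowing systematic pleiotropy through an overdispersion variance
#' `tau^2 >= 0`; an optional Huber loss bounds the influence of outlying
#' variants. This weighting by both the effect and the precision of the
#' variant-exposure association keeps the estimator stable when
#' instruments are weak. The standard error comes from the sandwich
#' (robust) information of the profile score.
#'
#' @param h Harmonized instrument set (k >= 3).
#' @param loss `"squared"` or `"huber"`.
#' @param c_huber Huber tuning constant (default 1.345).
#' @return One-row tibble with `overdispersion` (`tau2`) and a
#'   `converged` flag; errors if the optimizer fails.
#' @export
mr_raps <- function(h, loss = c("squared", "huber"), c_huber = 1.345) {
  loss <- match.arg(loss)
  if (nrow(h) < 3) {
    inform(sprintf("MR-RAPS skipped: %d instrument(s), need >= 3.", nrow(h)))
    return(NULL)
  }
  .check_harmonized(h, 3, "mr_raps")
  bx <- h$beta_exposure; by <- h$beta_outcome
  sx2 <- h$se_exposure^2; sy2 <- h$se_outcome^2
  ivw0 <- mr_ivw(h)
  # nested golden-section searches: profile tau2 out for each theta, then
  # optimize theta over a wide bracket around the IVW estimate
  tau_upper <- 10 * stats::var(by - ivw0$estimate * bx) + 0.1
  inner <- function(theta) {
    op <- optimize(function(t2) .raps_objective(c(theta, t2), bx, by, sx2,
                                                sy2, loss, c_huber),
                   interval = c(0, tau_upper))
    at0 <- .raps_objective(c(theta, 0), bx, by, sx2, sy2, loss, c_huber)
    if (at0 <= op$objective) list(tau2 = 0, value = at0) else
      list(tau2 = op$minimum, value = op$objective)
  }
  half <- max(1, 10 * abs(ivw0$estimate), 50 * ivw0$std_error)
  outer <- optimize(function(th) inner(th)$value,
                    interval = ivw0$estimate + c(-half, half))
  par <- c(outer$minimum, inner(outer$minimum)$tau2)
  opt <- list(value = outer$objective)
  if (!all(is.finite(par)) || !is.finite(opt$value)) {
    abort("MR-RAPS did not converge: non-finite profile-likelihood optimum.")
  }
  # sandwich: per-variant numerical gradients + numerical Hessian
  eps <- c(1e-5 * max(1, abs(par[1])), 1e-6 * max(1, par[2]))
  obj_j <- function(p, j) {
    .raps_objective(p, bx[j], by[j], sx2[j], sy2[j], loss, c_huber)
  }
  k <- nrow(h)
  grads <- matrix(0, k, 2)
  for (j in seq_len(k)) {
    for (q in 1:2) {
      pp <- par; pm <- par
      pp[q] <- pp[q] + eps[q]
      pm[q] <- max(pm[q] - eps[q], if (q == 2) 0 else -Inf)
      grads[j, q] <- (obj_j(pp, j) - obj_j(pm, j)) / (pp[q] - pm[q])
    }
  }
  hess <- matrix(0, 2, 2)
  for (q in 1:2) for (r in 1:2) {
    pp <- par; pp[q] <- pp[q] + eps[q]; pp[r] <- pp[r] + eps[r]
    pq <- par; pq[q] <- pq[q] + eps[q]
    pr <- par; pr[r] <- pr[r] + eps[r]
    hess[q, r] <- (.raps_objective(pp, bx, by, sx2, sy2, loss, c_huber) -
                     .raps_objective(pq, bx, by, sx2, sy2, loss, c_huber) -
                     .raps_objective(pr, bx, by, sx2, sy2, loss, c_huber) +
                     opt$value) / (eps[q] * eps[r])
  }
  B <- crossprod(grads)
  se <- tryCatch({
    Ainv <- solve(hess)
    V <- Ainv %*% B %*% Ainv
    sqrt(V[1, 1])
  }, error = function(e) {
    tryCatch(sqrt(solve(hess)[1, 1]), error = function(e2) NA_real_)
  })
  if (!is.finite(se)) {
    abort("MR-RAPS standard error not computable (singular information).")
  }
  out <- .mr_row("raps", par[1], se, n_snp = nrow(h))
  out$overdispersion <- par[2]
  out$converged <- TRUE
  out
}

#' Per-variant and median instrument strength
#'
#' `F_j = (beta_exposure / se_exposure)^2`; the median across variants
#' summarizes the strength of the instrument set (low medians signal
#' weak-instrument bias).
#'
#' @param h Harmonized instrument set.
#' @return List with tibble `per_variant` (`SNP`, `F`) and `median_f`.
#' @export
instrument_strength <- function(h) {
  .check_harmonized(h, 1, "instrument_strength")
  if (any(h$se_exposure <= 0)) abort("se_exposure must be positive.")
  f <- (h$beta_exposure / h$se_exposure)^2
  list(per_variant = tibble::tibble(SNP = h$SNP, F = f),
       median_f = median(f))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect k times, omitting each variant in turn,
#' and flags variants whose omission moves the estimate by more than one
#' full-sample standard error.
#'
#' @param h Harmonized instrument set (k >= 2).
#' @return Tibble with `SNP_omitted`, `estimate`, `std_error`,
#'   `shift`, `flagged`.
#' @export
leave_one_out <- function(h) {
  .check_harmonized(h, 2, "leave_one_out")
  full <- mr_ivw(h)
  rows <- purrr::map_dfr(seq_len(nrow(h)), function(j) {
    sub <- mr_ivw(h[-j, , drop = FALSE])
    tibble::tibble(SNP_omitted = h$SNP[j], estimate = sub$estimate,
                   std_error = sub$std_error,
                   shift = sub$estimate - full$estimate)
  })
  rows$flagged <- abs(rows$shift) > full$std_error
  rows
}
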