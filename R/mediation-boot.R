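#' Bootstrap confidence intervals for mediation effects
#'
#' Nonparametric case-resampling bootstrap of the full path system:
#' whole participant rows are resampled with replacement (preserving the
#' exposure–mediator–outcome dependence), every equation is refitted, and
#' the effect decomposition recomputed per draw. Standard errors are the
#' SD across draws; confidence intervals are percentile intervals at the
#' declared level. Draws whose resampled design is degenerate (a constant
#' or collinear column) are skipped and counted; more than 10% skipped
#' aborts the run.
#'
#' @param data Data frame with the model variables.
#' @param spec A [mediation_spec()]; `spec$boot` draws, `spec$seed`.
#' @param B Override for the number of draws.
#' @param seed Override for the seed.
#' @return A `mediation_boot` object: the point-estimate fit plus a
#'   tibble `effects` with `estimate`, `std_error`, `ci_lower`,
#'   `ci_upper`, `p_value` (normal approximation), and counters.
#' @export
bootstrap_effects <- function(data, spec, B = NULL, seed = NULL) {
  if (!inherits(spec, "mediation_spec")) abort("`spec` must be a `mediation_spec`.")
  B <- as.integer(B %||% spec$boot)
  seed <- seed %||% spec$seed
  if (B < 1) abort("`B` must be at least 1.")
  fit <- fit_paths(data, spec)
  des <- .mediation_design(data, spec)
  eqs <- des$eqs
  n <- des$n_used
  eff_names <- fit$effects$effect
  draws <- matrix(NA_real_, nrow = B, ncol = length(eff_names),
                  dimnames = list(NULL, eff_names))
  n_skipped <- 0L
  with_seed(seed, {
    for (bi in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      coef_list <- vector("list", length(eqs))
      names(coef_list) <- names(eqs)
      ok <- TRUE
      for (enm in names(eqs)) {
        eq <- eqs[[enm]]
        cf <- .fit_one(eq$X[idx, , drop = FALSE], eq$y[idx], eq$family)
        if (is.null(cf)) { ok <- FALSE; break }
        coef_list[[enm]] <- cf
      }
      if (!ok) { n_skipped <- n_skipped + 1L; next }
      draws[bi, ] <- .effects_from_paths(.path_coefs(coef_list, spec), spec)
    }
  })
  if (n_skipped > 0) {
    inform(sprintf("%d of %d bootstrap draw(s) skipped (degenerate resample).",
                   n_skipped, B))
  }
  if (n_skipped > 0.1 * B) {
    abort("More than 10% of bootstrap draws degenerate; check the data.")
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  alpha <- 1 - spec$conf_level
  low_precision <- nrow(draws) < ceiling(2 / alpha)
  if (low_precision) {
    warn(sprintf("Only %d usable draws: percentile CIs are low-precision.",
                 nrow(draws)))
  }
  se <- if (nrow(draws) >= 2) apply(draws, 2, sd) else rep(NA_real_, ncol(draws))
  ci <- apply(draws, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  est <- fit$effects$estimate
  bad <- !is.na(se) & (ci[1, ] > est | ci[2, ] < est)
  if (any(bad)) {
    warn(sprintf("Bootstrap CI does not bracket the point estimate for: %s.",
                 paste(eff_names[bad], collapse = ", ")))
  }
  structure(
    list(
      fit = fit, spec = spec, B = B, n_skipped = n_skipped,
      low_precision = low_precision,
      draws = draws,
      effects = tibble::tibble(
        effect = eff_names, estimate = est, std_error = unname(se),
        ci_lower = ci[1, ], ci_upper = ci[2, ],
        p_value = 2 * pnorm(-abs(est / se))
      )
    ),
    class = "mediation_boot"
  )
}

#' @export
print.mediation_boot <- function(x, ...) {
  cat(sprintf("Bootstrap mediation inference: %d draws (%d skipped), %.0f%% CIs\n",
              x$B, x$n_skipped, 100 * x$spec$conf_level))
  print(x$effects)
  invisible(x)
}

#' @export
tidy.mediation_boot <- function(x, ...) x$effects

#' @export
glance.mediation_boot <- function(x, ...) {
  tibble::tibble(B = x$B, n_skipped = x$n_skipped,
                 conf_level = x$spec$conf_level,
                 low_precision = x$low_precision,
                 n_used = x$fit$n_used)
}

#' Probability-scale mediation effects for binary outcomes
#'
#' Average causal mediation (indirect) and direct effects for a
#' binary-logistic outcome by the potential-outcomes simulation
#' estimator: coefficient vectors are drawn from their asymptotic normal
#' distribution, mediator values are simulated under exposure levels `x`
#' and `x + 1` (including mediator residual draws), the implied outcome
#' probabilities are computed per participant, and differences averaged
#' over participants and draws. Estimates are on the probability scale,
#' i.e. the change in outcome risk per unit exposure; the
#' linear-predictor-scale products from [fit_paths()] remain available
#' for transparency.
#'
#' @param data Data frame with the model variables.
#' @param spec A [mediation_spec()] with `outcome_family =
#'   "binary-logistic"`.
#' @param draws Number of coefficient draws (default 1000).
#' @param seed Integer seed.
#' @return Tibble with rows `indirect`, `direct`, `total` on the
#'   probability scale: `estimate`, `std_error`, `ci_lower`, `ci_upper`.
#' @export
indirect_binary_effects <- function(data, spec, draws = 1000, seed = 1) {
  if (!inherits(spec, "mediation_spec")) abort("`spec` must be a `mediation_spec`.")
  if (spec$outcome_family != "binary-logistic") {
    abort("`indirect_binary_effects()` requires a binary-logistic outcome.")
  }
  if (draws < 1) abort("`draws` must be at least 1.")
  fit <- fit_paths(data, spec)
  des <- .mediation_design(data, spec)
  d <- des$data
  n <- nrow(d)
  x_name <- spec$exposure; m <- spec$mediators
  two <- spec$configuration != "pairwise"
  serial <- spec$configuration == "serial"
  models <- fit$models
  sig1 <- summary(models$m1)$sigma
  sig2 <- if (two) summary(models$m2)$sigma else NULL
  draw_coefs <- function(model, k) {
    MASS::mvrnorm(k, mu = coef(model), Sigma = vcov(model))
  }
  # design pieces held fixed at observed confounders
  conf_part <- function(model, cf) {
    X <- model.matrix(model)
    drop_cols <- intersect(colnames(X), c(x_name, m))
    keep <- setdiff(colnames(X), drop_cols)
    drop(X[, keep, drop = FALSE] %*% cf[keep])
  }
  with_seed(seed, {
    cf1 <- draw_coefs(models$m1, draws)
    cf2 <- if (two) draw_coefs(models$m2, draws) else NULL
    cfo <- draw_coefs(models$out, draws)
    res <- matrix(NA_real_, draws, 3,
                  dimnames = list(NULL, c("indirect", "direct", "total")))
    x_obs <- d[[x_name]]
    for (s in seq_len(draws)) {
      c1 <- cf1[s, ]; co <- cfo[s, ]
      base1 <- conf_part(models$m1, c1)
      eps1 <- rnorm(n, 0, sig1)
      m1_0 <- base1 + c1[x_name] * x_obs + eps1
      m1_1 <- base1 + c1[x_name] * (x_obs + 1) + eps1
      if (two) {
        c2 <- cf2[s, ]
        base2 <- conf_part(models$m2, c2)
        eps2 <- rnorm(n, 0, sig2)
        m2_at <- function(x, m1v) {
          out <- base2 + c2[x_name] * x + eps2
          if (serial) out <- out + c2[m[1]] * m1v
          out
        }
        m2_0 <- m2_at(x_obs, m1_0)
        m2_1 <- m2_at(x_obs + 1, m1_1)
      }
      baseo <- conf_part(models$out, co)
      p_at <- function(x, m1v, m2v = NULL) {
        eta <- baseo + co[x_name] * x + co[m[1]] * m1v
        if (two) eta <- eta + co[m[2]] * m2v
        plogis(eta)
      }
      if (two) {
        p00 <- p_at(x_obs, m1_0, m2_0)
        p01 <- p_at(x_obs, m1_1, m2_1)
        p10 <- p_at(x_obs + 1, m1_0, m2_0)
        p11 <- p_at(x_obs + 1, m1_1, m2_1)
      } else {
        p00 <- p_at(x_obs, m1_0)
        p01 <- p_at(x_obs, m1_1)
        p10 <- p_at(x_obs + 1, m1_0)
        p11 <- p_at(x_obs + 1, m1_1)
      }
      acme <- mean(((p01 - p00) + (p11 - p10)) / 2)
      ade <- mean(((p10 - p00) + (p11 - p01)) / 2)
      res[s, ] <- c(acme, ade, mean(p11 - p00))
    }
    est <- colMeans(res)
    se <- apply(res, 2, sd)
    ci <- apply(res, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    tibble::tibble(
      effect = colnames(res), estimate = unname(est),
      std_error = unname(se), ci_lower = ci[1, ], ci_upper = ci[2, ],
      scale = "probability"
    )
  })
}

#' Run a mediation analysis grid
#'
#' Sweeps every exposure x mediator-set x outcome combination, fitting the
#' requested configuration with bootstrap inference, and applies
#' Benjamini–Hochberg FDR control to the indirect-effect p-values across
#' the grid. Binary outcomes are fitted with a logistic outcome equation;
#' outcomes listed in `tobacco_adjusted_outcomes` (e.g. composite
#' cardiovascular disease) receive the tobacco covariate on top of the
#' shared confounders. A failing cell is logged and marked, and the grid
#' continues.
#'
#' @param data Cohort data frame.
#' @param exposures Character vector of exposure columns.
#' @param mediators A mediator set (character vector) or list of sets.
#' @param outcomes Character vector of outcome columns.
#' @param confounders Shared confounder columns.
#' @param binary_outcomes Outcomes to model as binary-logistic.
#' @param tobacco_adjusted_outcomes Outcomes additionally adjusted for
#'   `tobacco_var`.
#' @param tobacco_var Tobacco covariate column name.
#' @param configuration Model configuration for every cell.
#' @param boot Bootstrap draws per cell.
#' @param seed Base seed; each cell uses `seed + cell index`.
#' @param conf_level CI level.
#' @param fdr_q FDR level for the indirect effect (default 0.05).
#' @return Tidy tibble, one row per cell and effect, with bootstrap CIs,
#'   raw and adjusted p-values and a `status` column.
#' @export
run_mediation_grid <- function(data, exposures, mediators, outcomes,
                               confounders = character(),
                               binary_outcomes = character(),
                               tobacco_adjusted_outcomes = character(),
                               tobacco_var = "tobacco",
                               configuration = "pairwise",
                               boot = 5000, seed = 1, conf_level = 0.95,
                               fdr_q = 0.05) {
  if (length(exposures) == 0 || length(outcomes) == 0) {
    warn("Empty exposure or outcome list: returning an empty grid.")
    return(tibble::tibble(exposure = character(), outcome = character()))
  }
  if (!is.list(mediators)) mediators <- list(mediators)
  grid <- tidyr::expand_grid(
    exposure = exposures,
    mediator_set = seq_along(mediators),
    outcome = outcomes
  )
  cells <- purrr::pmap(
    list(grid$exposure, grid$mediator_set, grid$outcome, seq_len(nrow(grid))),
    function(exp_v, mset, out_v, i) {
      med <- mediators[[mset]]
      conf <- confounders
      if (out_v %in% tobacco_adjusted_outcomes) conf <- union(conf, tobacco_var)
      fam <- if (out_v %in% binary_outcomes) "binary-logistic" else "continuous"
      sp <- mediation_spec(exp_v, med, out_v, outcome_family = fam,
                           confounders = conf, configuration = configuration,
                           boot = boot, seed = seed + i, conf_level = conf_level)
      res <- tryCatch(bootstrap_effects(data, sp), error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("Grid cell %s -> %s failed: %s", exp_v, out_v,
                     conditionMessage(res)))
        return(tibble::tibble(
          exposure = exp_v, mediator_set = paste(med, collapse = "+"),
          outcome = out_v, outcome_family = fam, status = "failed",
          effect = NA_character_, estimate = NA_real_, std_error = NA_real_,
          ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_
        ))
      }
      dplyr::mutate(res$effects,
                    exposure = exp_v,
                    mediator_set = paste(med, collapse = "+"),
                    outcome = out_v, outcome_family = fam, status = "ok",
                    .before = 1)
    }
  )
  out <- dplyr::bind_rows(cells)
  # FDR across the grid's indirect-effect tests
  idx <- which(out$effect %in% "total_indirect" & out$status == "ok")
  out$p_fdr <- NA_real_
  out$fdr_rejected <- NA
  if (length(idx)) {
    adj <- bh_fdr(out$p_value[idx], q = fdr_q)
    out$p_fdr[idx] <- adj$p_adjusted
    out$fdr_rejected[idx] <- adj$rejected
  }
  out
}
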