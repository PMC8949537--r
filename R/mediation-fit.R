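#' Specify a mediation path model
#'
#' Declares one exposure–mediator(s)–outcome configuration. Pairwise
#' models use a single mediator; parallel models fit two mediators side
#' by side; serial models additionally allow the first mediator to affect
#' the second (e.g. physical activity -> adiposity). Mediator equations
#' are always linear; the outcome equation is linear for continuous
#' traits and logistic for binary disease status.
#'
#' @param exposure Exposure column name.
#' @param mediators Mediator column name(s): 1 for `pairwise`, 2 (ordered)
#'   for `parallel`/`serial`.
#' @param outcome Outcome column name.
#' @param outcome_family `"continuous"` or `"binary-logistic"`.
#' @param confounders Character vector of confounder column names.
#' @param configuration `"pairwise"`, `"parallel"` or `"serial"`.
#' @param boot Bootstrap draws for inference (default 5000).
#' @param seed Integer seed used by bootstrap and simulation estimators.
#' @param conf_level Confidence level in (0, 1) (default 0.95).
#' @return A `mediation_spec` object.
#' @export
mediation_spec <- function(exposure, mediators, outcome,
                           outcome_family = c("continuous", "binary-logistic"),
                           confounders = character(),
                           configuration = c("pairwise", "parallel", "serial"),
                           boot = 5000, seed = 1, conf_level = 0.95) {
  configuration <- match.arg(configuration)
  outcome_family <- match.arg(outcome_family)
  n_med <- length(mediators)
  if (configuration == "pairwise" && n_med != 1L) {
    abort("Pairwise mediation requires exactly 1 mediator.")
  }
  if (configuration %in% c("parallel", "serial") && n_med != 2L) {
    abort(sprintf("%s mediation requires exactly 2 mediators.", configuration))
  }
  check_number(boot, "boot", lower = 1)
  check_number(conf_level, "conf_level",
               lower = .Machine$double.eps, upper = 1 - .Machine$double.eps)
  structure(
    list(exposure = exposure, mediators = mediators, outcome = outcome,
         outcome_family = outcome_family, confounders = confounders,
         configuration = configuration, boot = as.integer(boot),
         seed = as.integer(seed), conf_level = conf_level),
    class = "mediation_spec"
  )
}

# complete-case data + per-equation design matrices for one spec
.mediation_design <- function(data, spec) {
  vars <- unique(c(spec$exposure, spec$mediators, spec$outcome, spec$confounders))
  check_columns(data, vars)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- tibble::as_tibble(data)[cc, vars, drop = FALSE]
  if (nrow(d) < length(vars) + 2L) abort("Too few complete cases to fit the model.")
  if (sd(d[[spec$exposure]]) == 0) {
    abort(sprintf("Exposure `%s` has zero variance in the estimation sample.",
                  spec$exposure))
  }
  conf <- spec$confounders
  mm <- function(rhs) {
    model.matrix(stats::reformulate(rhs), data = d)
  }
  x <- spec$exposure; m <- spec$mediators; y <- spec$outcome
  eqs <- list(m1 = list(X = mm(c(x, conf)), y = d[[m[1]]], family = "gaussian"))
  if (spec$configuration == "parallel") {
    eqs$m2 <- list(X = mm(c(x, conf)), y = d[[m[2]]], family = "gaussian")
  } else if (spec$configuration == "serial") {
    eqs$m2 <- list(X = mm(c(m[1], x, conf)), y = d[[m[2]]], family = "gaussian")
  }
  out_fam <- if (spec$outcome_family == "continuous") "gaussian" else "binomial"
  eqs$out <- list(X = mm(c(x, m, conf)), y = d[[y]], family = out_fam)
  eqs$tot <- list(X = mm(c(x, conf)), y = d[[y]], family = out_fam)
  list(data = d, eqs = eqs, n_used = nrow(d), n_dropped = sum(!cc))
}

# least-squares / logistic coefficients from a design matrix; NULL if the
# resampled design is rank deficient or the fit fails
.fit_one <- function(X, y, family) {
  if (family == "gaussian") {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) return(NULL)
    fit$coefficients
  } else {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || any(is.na(fit$coefficients))) return(NULL)
    fit$coefficients
  }
}

# named path coefficients from per-equation coefficient vectors
.path_coefs <- function(coef_list, spec) {
  x <- spec$exposure; m <- spec$mediators
  pc <- c(a1 = unname(coef_list$m1[x]),
          b1 = unname(coef_list$out[m[1]]),
          c_prime = unname(coef_list$out[x]),
          c_total = unname(coef_list$tot[x]))
  if (spec$configuration %in% c("parallel", "serial")) {
    pc["a2"] <- unname(coef_list$m2[x])
    pc["b2"] <- unname(coef_list$out[m[2]])
    pc["d"] <- if (spec$configuration == "serial") {
      unname(coef_list$m2[m[1]])
    } else 0
  }
  pc
}

# effect decomposition implied by path coefficients
.effects_from_paths <- function(pc, spec) {
  if (spec$configuration == "pairwise") {
    ind <- c(indirect_M1 = pc[["a1"]] * pc[["b1"]])
  } else {
    ind <- c(indirect_M1 = pc[["a1"]] * pc[["b1"]],
             indirect_M2 = pc[["a2"]] * pc[["b2"]],
             indirect_serial = pc[["a1"]] * pc[["d"]] * pc[["b2"]])
  }
  c(ind,
    total_indirect = sum(ind),
    direct = pc[["c_prime"]],
    total = pc[["c_prime"]] + sum(ind),
    total_eq1 = pc[["c_total"]])
}

#' Fit a mediation path model equation by equation
#'
#' Estimates every regression equation of the chosen configuration by
#' least squares (mediators, continuous outcomes) or maximum-likelihood
#' logistic regression (binary outcome equation), on the complete cases
#' of the variables in the model. Because the system is recursive with
#' observed variables only, equation-by-equation estimation coincides
#' with joint maximum likelihood in the linear case, and the total effect
#' decomposes exactly: the unadjusted exposure coefficient equals the
#' direct effect plus the sum of indirect products.
#'
#' @param data Data frame containing all model variables.
#' @param spec A [mediation_spec()].
#' @return A `mediation_fit` with path coefficients (`paths`), effect
#'   decomposition (`effects`), per-equation models, fit statistics and
#'   variance inflation factors for the outcome-equation covariates.
#' @export
#' @examples
#' tr <- cohort_truth(n = 2000, a_coefs = 0.5, b_coefs = 0.3, c_prime = 0.2)
#' fit <- fit_paths(generate_cohort(tr),
#'                  mediation_spec("X", "M1", "Y"))
#' tidy(fit)
fit_paths <- function(data, spec) {
  if (!inherits(spec, "mediation_spec")) abort("`spec` must be a `mediation_spec`.")
  des <- .mediation_design(data, spec)
  d <- des$data
  x <- spec$exposure; m <- spec$mediators; y <- spec$outcome
  conf <- spec$confounders
  fam <- if (spec$outcome_family == "continuous") stats::gaussian() else binomial()
  fit_lm <- function(lhs, rhs) lm(stats::reformulate(rhs, response = lhs), data = d)
  fit_out <- function(lhs, rhs) {
    f <- stats::reformulate(rhs, response = lhs)
    if (spec$outcome_family == "continuous") lm(f, data = d) else {
      g <- glm(f, data = d, family = binomial())
      if (!g$converged) abort("Logistic outcome equation did not converge.")
      if (any(abs(g$coefficients) > 15)) {
        warn("Very large logistic coefficients: possible separation in the outcome equation.")
      }
      g
    }
  }
  models <- list(m1 = fit_lm(m[1], c(x, conf)))
  if (spec$configuration == "parallel") {
    models$m2 <- fit_lm(m[2], c(x, conf))
  } else if (spec$configuration == "serial") {
    models$m2 <- fit_lm(m[2], c(m[1], x, conf))
  }
  models$out <- fit_out(y, c(x, m, conf))
  models$tot <- fit_out(y, c(x, conf))
  if (any(vapply(models, function(mo) anyNA(coef(mo)), logical(1)))) {
    abort("Rank-deficient design: aliased coefficients in at least one equation.")
  }
  coef_list <- purrr::map(models, coef)
  pc <- .path_coefs(coef_list, spec)
  eff <- .effects_from_paths(pc, spec)
  layout <- switch(
    spec$configuration,
    pairwise = list(a1 = c("m1", x), b1 = c("out", m[1]),
                    c_prime = c("out", x), c_total = c("tot", x)),
    parallel = list(a1 = c("m1", x), a2 = c("m2", x), b1 = c("out", m[1]),
                    b2 = c("out", m[2]), c_prime = c("out", x),
                    c_total = c("tot", x)),
    serial = list(a1 = c("m1", x), a2 = c("m2", x), d = c("m2", m[1]),
                  b1 = c("out", m[1]), b2 = c("out", m[2]),
                  c_prime = c("out", x), c_total = c("tot", x))
  )
  path_tbl <- purrr::imap_dfr(layout, function(loc, nm) {
    tibble::tibble(path = nm, equation = loc[1], term = loc[2],
                   estimate = unname(pc[nm]),
                   std_error = unname(sqrt(diag(vcov(models[[loc[1]]])))[loc[2]]))
  })
  vif <- vif_screen(models$out)
  fit_stats <- purrr::imap_dfr(models, function(mo, nm) {
    ll <- logLik(mo)
    tibble::tibble(equation = nm, log_lik = as.numeric(ll),
                   df = attr(ll, "df"), aic = stats::AIC(mo),
                   bic = stats::BIC(mo))
  })
  structure(
    list(spec = spec, models = models,
         paths = path_tbl,
         effects = tibble::tibble(effect = names(eff), estimate = unname(eff)),
         vif = vif, fit_stats = fit_stats,
         n_used = des$n_used, n_dropped = des$n_dropped),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation fit (%s, %s outcome): %s -> {%s} -> %s\n",
              x$spec$configuration, x$spec$outcome_family,
              x$spec$exposure, paste(x$spec$mediators, collapse = ", "),
              x$spec$outcome))
  cat(sprintf("n = %d complete cases (%d dropped)\n", x$n_used, x$n_dropped))
  print(x$effects)
  invisible(x)
}

#' @export
tidy.mediation_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$paths, type = "path",
                  statistic = .data$estimate / .data$std_error,
                  p_value = 2 * pnorm(-abs(.data$statistic))),
    tibble::tibble(path = x$effects$effect, estimate = x$effects$estimate,
                   type = "effect")
  )
}

#' @export
glance.mediation_fit <- function(x, ...) {
  out_row <- x$fit_stats[x$fit_stats$equation == "out", ]
  tibble::tibble(
    configuration = x$spec$configuration,
    outcome_family = x$spec$outcome_family,
    n_used = x$n_used, n_dropped = x$n_dropped,
    log_lik = out_row$log_lik, aic = out_row$aic, bic = out_row$bic,
    max_vif = max(x$vif$vif)
  )
}

#' Variance inflation factors for a design
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing
#' covariate `j` on all other covariates. Values above `threshold`
#' (default 10) are flagged for removal; perfectly collinear columns get
#' an infinite VIF.
#'
#' @param x A fitted `lm`/`glm`, a data frame or a numeric matrix of
#'   covariates (no intercept column).
#' @param threshold Flagging threshold (default 10).
#' @return Tibble with `variable`, `vif` and logical `flagged`.
#' @export
vif_screen <- function(x, threshold = 10) {
  if (inherits(x, c("lm", "glm"))) {
    X <- model.matrix(x)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(x)
  }
  if (ncol(X) < 2) {
    return(tibble::tibble(variable = colnames(X) %||% "x1",
                          vif = rep(1, ncol(X)),
                          flagged = rep(FALSE, ncol(X))))
  }
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(
    variable = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    vif = vifs,
    flagged = vifs > threshold
  )
}

#' Benjamini–Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; discoveries are
#' declared where the adjusted p-value falls below `q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `p_adjusted` and logical `rejected`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p, q = 0.05) {
  check_numeric_vec(p, "p", allow_na = TRUE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, rejected = !is.na(adj) & adj < q)
}

#' Likelihood-ratio test of full versus partial mediation
#'
#' Compares the outcome equation with the direct exposure term (partial
#' mediation) against the nested full-mediation model that removes it
#' (direct effect constrained to zero): statistic
#' `-2 (logLik_reduced - logLik_full)` on 1 df against a chi-squared
#' distribution. For recursive observed-variable path systems where the
#' direct path is the only difference, this equals the structural-model
#' chi-squared difference test.
#'
#' @param data Data frame with the model variables.
#' @param spec A [mediation_spec()].
#' @return Tibble with `statistic`, `df` and `p_value`.
#' @export
nested_model_test <- function(data, spec) {
  if (!inherits(spec, "mediation_spec")) abort("`spec` must be a `mediation_spec`.")
  des <- .mediation_design(data, spec)
  d <- des$data
  rhs_full <- c(spec$exposure, spec$mediators, spec$confounders)
  rhs_red <- c(spec$mediators, spec$confounders)
  if (spec$outcome_family == "continuous") {
    f1 <- lm(stats::reformulate(rhs_full, spec$outcome), data = d)
    f0 <- lm(stats::reformulate(rhs_red, spec$outcome), data = d)
  } else {
    f1 <- glm(stats::reformulate(rhs_full, spec$outcome), data = d, family = binomial())
    f0 <- glm(stats::reformulate(rhs_red, spec$outcome), data = d, family = binomial())
  }
  stat <- max(0, -2 * (as.numeric(logLik(f0)) - as.numeric(logLik(f1))))
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
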