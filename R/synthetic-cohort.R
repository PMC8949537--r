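#' Ground-truth parameters for a synthetic cohort
#'
#' Defines the recursive path system used to generate cohorts with known
#' mediation structure:
#' \deqn{M_1 = a_1 X + u_{M1}'C + \epsilon_1}
#' \deqn{M_2 = d M_1 + a_2 X + u_{M2}'C + \epsilon_2}
#' \deqn{Y = c' X + b_1 M_1 + b_2 M_2 + u_Y'C + \epsilon_Y}
#' with standard-normal exposure and confounders. For a binary outcome the
#' linear predictor (plus `intercept`) is passed through the inverse
#' logit; the default intercept of -2.2 gives a baseline prevalence near
#' 10%, typical of type 2 diabetes in middle-aged cohorts.
#'
#' @param n Number of participants (>= 1).
#' @param a_coefs Exposure-to-mediator effects, length 1 or 2.
#' @param b_coefs Mediator-to-outcome effects, same length as `a_coefs`.
#' @param c_prime Direct exposure-to-outcome effect.
#' @param d_coef Mediator-1-to-mediator-2 effect (serial path); only used
#'   with two mediators.
#' @param confounder_effects List with numeric entries `x`, `m` and `y`:
#'   loadings of each confounder on the exposure, every mediator and the
#'   outcome. Lengths must agree; `NULL` means no confounding.
#' @param outcome_family `"continuous"` or `"binary-logistic"`.
#' @param noise_sd Residual SD for every linear equation (> 0).
#' @param intercept Outcome-equation intercept (logit scale for binary).
#' @param seed Integer seed; identical truth + seed gives a bit-identical
#'   table.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(n, a_coefs, b_coefs, c_prime = 0, d_coef = 0,
                         confounder_effects = NULL,
                         outcome_family = c("continuous", "binary-logistic"),
                         noise_sd = 1, intercept = NULL, seed = 1) {
  check_number(n, "n", lower = 1)
  outcome_family <- match.arg(outcome_family)
  if (!length(a_coefs) %in% 1:2 || length(b_coefs) != length(a_coefs)) {
    abort("`a_coefs` and `b_coefs` must have equal length 1 or 2.")
  }
  check_number(noise_sd, "noise_sd", lower = .Machine$double.eps)
  if (!is.null(confounder_effects)) {
    lens <- lengths(confounder_effects[c("x", "m", "y")])
    if (length(unique(lens)) != 1) {
      abort("`confounder_effects` entries `x`, `m`, `y` must have equal length.")
    }
  }
  intercept <- intercept %||% if (outcome_family == "binary-logistic") -2.2 else 0
  structure(
    list(n = as.integer(n), a_coefs = a_coefs, b_coefs = b_coefs,
         c_prime = c_prime, d_coef = d_coef,
         confounder_effects = confounder_effects,
         outcome_family = outcome_family, noise_sd = noise_sd,
         intercept = intercept, seed = as.integer(seed)),
    class = "cohort_truth"
  )
}

#' Generate a synthetic cohort from known path coefficients
#'
#' Draws participants from the recursive system described in
#' [cohort_truth()]. Columns: `X` (exposure), `M1` (and `M2` with two
#' mediators), `C1...` (confounders, if any) and `Y`. In a confounder-free
#' continuous cohort the regression of `Y` on `X` alone recovers
#' `c_prime` plus the sum of the indirect products, which is what makes
#' downstream decomposition testable by parameter recovery.
#'
#' @param truth A [cohort_truth()] object.
#' @return Tibble of `truth$n` rows.
#' @export
#' @examples
#' tr <- cohort_truth(n = 500, a_coefs = 0.5, b_coefs = 0.3, c_prime = 0.2)
#' cohort <- generate_cohort(tr)
generate_cohort <- function(truth) {
  if (!inherits(truth, "cohort_truth")) abort("`truth` must be a `cohort_truth`.")
  with_seed(truth$seed, {
    n <- truth$n
    ce <- truth$confounder_effects
    p_conf <- if (is.null(ce)) 0L else length(ce$x)
    C <- if (p_conf) matrix(rnorm(n * p_conf), n, p_conf) else matrix(0, n, 0)
    conf_x <- if (p_conf) drop(C %*% ce$x) else 0
    conf_m <- if (p_conf) drop(C %*% ce$m) else 0
    conf_y <- if (p_conf) drop(C %*% ce$y) else 0
    X <- rnorm(n) + conf_x
    two <- length(truth$a_coefs) == 2L
    M1 <- truth$a_coefs[1] * X + conf_m + rnorm(n, sd = truth$noise_sd)
    eta <- truth$intercept + truth$c_prime * X + truth$b_coefs[1] * M1 + conf_y
    out <- tibble::tibble(X = X, M1 = M1)
    if (two) {
      M2 <- truth$d_coef * M1 + truth$a_coefs[2] * X + conf_m +
        rnorm(n, sd = truth$noise_sd)
      eta <- eta + truth$b_coefs[2] * M2
      out$M2 <- M2
    }
    if (p_conf) {
      colnames(C) <- paste0("C", seq_len(p_conf))
      out <- dplyr::bind_cols(out, tibble::as_tibble(C))
    }
    out$Y <- if (truth$outcome_family == "continuous") {
      eta + rnorm(n, sd = truth$noise_sd)
    } else {
      rbinom(n, 1, plogis(eta))
    }
    out
  })
}

#' True mediation effects implied by a cohort truth
#'
#' Closed-form products of the generating coefficients, used as oracles in
#' parameter-recovery tests: pairwise indirect `a*b`; with two mediators
#' the parallel products `a1*b1`, `a2*b2` and the serial chain
#' `a1*d*b2`; total = direct + all indirect (linear-predictor scale).
#'
#' @param truth A [cohort_truth()] object.
#' @return Tibble with columns `effect` and `value`.
#' @export
true_effects <- function(truth) {
  a <- truth$a_coefs; b <- truth$b_coefs
  if (length(a) == 1L) {
    ind <- c(indirect_M1 = a[1] * b[1])
  } else {
    ind <- c(indirect_M1 = a[1] * b[1],
             indirect_M2 = a[2] * b[2],
             indirect_serial = a[1] * truth$d_coef * b[2])
  }
  tibble::tibble(
    effect = c(names(ind), "total_indirect", "direct", "total"),
    value = c(unname(ind), sum(ind), truth$c_prime, truth$c_prime + sum(ind))
  )
}

#' Write a synthetic cohort with its generating truth
#'
#' Saves the cohort as a headered CSV and the generating parameters as a
#' sidecar JSON (`<path>.truth.json`) so tests can recover the oracle.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param truth The [cohort_truth()] that generated it.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, truth, path) {
  readr::write_csv(cohort, path)
  truth_json <- truth
  class(truth_json) <- NULL
  jsonlite::write_json(truth_json, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
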