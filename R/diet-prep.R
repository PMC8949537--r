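#' Log-transform dietary intakes with a small shift
#'
#' Dietary intake distributions are right-skewed and contain true zeros
#' (non-consumers), so a constant of 0.1 is added to every value before
#' taking the natural logarithm. Zero intake therefore maps to
#' `log(0.1)`, about -2.30.
#'
#' @param x Numeric vector of non-negative intakes (g/day).
#' @param shift Constant added before the log; default 0.1.
#' @return Numeric vector `log(x + shift)`.
#' @export
#' @examples
#' log_shift_transform(c(0, 0.9, 10))
log_shift_transform <- function(x, shift = 0.1) {
  check_numeric_vec(x, "x", lower = 0)
  check_number(shift, "shift", lower = .Machine$double.eps)
  log(x + shift)
}

#' Energy-adjust a nutrient by the residual method
#'
#' Regresses nutrient intake (usually after [log_shift_transform()]) on
#' total energy intake and returns the residuals re-centered at the
#' nutrient mean, so the adjusted variable keeps interpretable units while
#' being uncorrelated with total energy.
#'
#' @param nutrient Numeric vector of (transformed) nutrient intakes.
#' @param tei Numeric vector of total energy intakes (kcal/day), positive.
#' @return Numeric vector of energy-adjusted intakes; `NA` propagates.
#' @export
energy_residual_adjust <- function(nutrient, tei) {
  if (length(nutrient) != length(tei)) {
    abort("`nutrient` and `tei` must have the same length.")
  }
  check_numeric_vec(tei, "tei", lower = .Machine$double.eps)
  ok <- stats::complete.cases(nutrient, tei)
  if (sd(tei[ok]) == 0) {
    abort("`tei` is constant; the residual-method regression is undefined.")
  }
  fit <- lm(nutrient ~ tei, subset = ok)
  out <- rep(NA_real_, length(nutrient))
  out[ok] <- residuals(fit) + mean(nutrient[ok])
  out
}

#' Macronutrient energy percent (E%)
#'
#' Converts gram intake to the percentage of total energy intake using a
#' metabolizable-energy conversion factor (Atwater: 4 kcal/g for protein
#' and carbohydrate, 9 for fat, 7 for alcohol).
#'
#' @param grams Intake in g/day (non-negative).
#' @param tei_kcal Total energy intake, kcal/day (positive).
#' @param factor kcal per gram for this nutrient.
#' @return Percent of total energy, `100 * grams * factor / tei_kcal`.
#' @export
#' @examples
#' energy_percent(80, 2000, factor = 9)  # 36
energy_percent <- function(grams, tei_kcal, factor) {
  check_numeric_vec(grams, "grams", lower = 0)
  check_numeric_vec(tei_kcal, "tei_kcal", lower = .Machine$double.eps)
  check_number(factor, "factor", lower = .Machine$double.eps)
  100 * grams * factor / tei_kcal
}

#' Atwater metabolizable-energy conversion factors (kcal/g)
#'
#' @return Named numeric vector with entries `protein`, `carbohydrate`,
#'   `fat` and `alcohol`.
#' @export
atwater_factors <- function() {
  c(protein = 4, carbohydrate = 4, fat = 9, alcohol = 7)
}

#' Derive added and total sugar from sugar subcomponents
#'
#' Added sugar is all sucrose plus monosaccharides minus the sugars that
#' come from fruit and vegetables; total sugar is the sum of all mono- and
#' disaccharides. Added sugar is clamped at zero when fruit/vegetable
#' sugars exceed sucrose + monosaccharides, since negative intake is
#' physically meaningless.
#'
#' @param sucrose,monosaccharides,disaccharides,fruit_veg_sugars
#'   Non-negative numeric vectors (g/day), recycled to a common length.
#' @return A tibble with columns `added_sugar_g` and `total_sugar_g`.
#' @export
derive_sugars <- function(sucrose, monosaccharides, disaccharides, fruit_veg_sugars) {
  for (nm in c("sucrose", "monosaccharides", "disaccharides", "fruit_veg_sugars")) {
    check_numeric_vec(get(nm), nm, lower = 0)
  }
  tibble::tibble(
    added_sugar_g = pmax(0, sucrose + monosaccharides - fruit_veg_sugars),
    total_sugar_g = monosaccharides + disaccharides
  )
}

#' Friedewald estimate of LDL cholesterol
#'
#' `LDL = TC - HDL - TG/2.2` in mmol/L. The formula is invalid at high
#' triglyceride concentrations; values at or above `tg_max` yield `NA`.
#'
#' @param tc,hdl,tg Total cholesterol, HDL cholesterol and triglycerides
#'   in mmol/L.
#' @param tg_max Triglyceride validity bound in mmol/L (default 4.5).
#' @return Numeric vector of LDL-C (mmol/L); `NA` where TG >= `tg_max`.
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_max = 4.5) {
  ldl <- tc - hdl - tg / 2.2
  invalid <- !is.na(tg) & tg >= tg_max
  if (any(invalid)) {
    inform(sprintf("%d record(s) with TG >= %.1f mmol/L set to NA (Friedewald invalid).",
                   sum(invalid), tg_max))
  }
  ldl[invalid] <- NA_real_
  ldl
}

#' Correct lipid levels for lipid-lowering medication use
#'
#' Adds published constants to treated participants only: +0.208 mmol/L
#' for TG, +1.347 for TC, -0.060 for HDL-C and +1.290 for LDL-C.
#' Untreated rows are returned unchanged, so clearing the flag and
#' re-running is a no-op.
#'
#' @param data Data frame with the lipid columns and a logical/0-1
#'   medication flag column.
#' @param tc,hdl,ldl,tg,on_medication Column names (strings).
#' @return The input as a tibble with corrected lipid columns.
#' @export
lipid_medication_correct <- function(data, tc = "tc_mmol", hdl = "hdl_mmol",
                                     ldl = "ldl_mmol", tg = "tg_mmol",
                                     on_medication = "lipid_med") {
  check_columns(data, c(tc, hdl, ldl, tg, on_medication))
  flag <- as.logical(data[[on_medication]])
  flag[is.na(flag)] <- FALSE
  shifts <- c(0.208, 1.347, -0.060, 1.290)
  cols <- c(tg, tc, hdl, ldl)
  out <- tibble::as_tibble(data)
  for (i in seq_along(cols)) {
    out[[cols[i]]] <- out[[cols[i]]] + ifelse(flag, shifts[i], 0)
  }
  out
}

#' Principal components of nutrient intake patterns
#'
#' Columns are centered and scaled to unit variance, then the correlation
#' matrix is eigendecomposed; participant scores are the standardized data
#' projected on the loadings. The top components summarize co-occurring
#' intakes as dietary patterns.
#'
#' @param data Data frame or matrix, participants x nutrients, no missing
#'   values.
#' @param n_components Number of components to retain (default 3).
#' @return An object of class `nutrient_pca` with elements `loadings`
#'   (variables x components, orthonormal columns), `variance_explained`
#'   (fractions, all components), `scores` (tibble of retained component
#'   scores) and `n_components`.
#' @export
nutrient_pattern_pca <- function(data, n_components = 3) {
  m <- as.matrix(data)
  if (ncol(m) < 2) abort("At least 2 nutrient columns are required.")
  if (anyNA(m)) abort("Missing values must be removed before PCA.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance column(s): %s.",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  n_components <- min(n_components, ncol(m))
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- tibble::as_tibble(pc$x[, keep, drop = FALSE])
  structure(
    list(
      loadings = pc$rotation,
      variance_explained = ve,
      scores = scores,
      n_components = n_components
    ),
    class = "nutrient_pca"
  )
}

#' @export
print.nutrient_pca <- function(x, ...) {
  cat("Nutrient-pattern PCA:", nrow(x$loadings), "variables,",
      x$n_components, "retained component(s)\n")
  cat("Variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(x$n_components)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.nutrient_pca <- function(x, ...) {
  keep <- seq_len(x$n_components)
  tibble::tibble(
    component = paste0("PC", keep),
    variance_explained = x$variance_explained[keep],
    cumulative = cumsum(x$variance_explained)[keep]
  )
}

#' Exclude records by range and flag rules
#'
#' Applies per-variable admissible ranges and exclusion flags, the way
#' implausible anthropometry and supplement users are removed before
#' analysis. Rules are a data frame with columns `variable`, and either
#' `min`/`max` (range rule, NA for open-ended) or `flag_value` (rows whose
#' variable equals this value are dropped). Rows with `NA` in a rule
#' variable are kept (missingness is handled downstream as complete-case).
#'
#' @param data Cohort data frame.
#' @param rules Data frame of rules; see Details.
#' @return The filtered tibble with an attribute `exclusions`, a tibble of
#'   per-rule removal counts.
#' @export
exclude_records <- function(data, rules) {
  rules <- tibble::as_tibble(rules)
  check_columns(rules, "variable", where = "rules")
  check_columns(data, unique(rules$variable))
  if (!"min" %in% names(rules)) rules$min <- NA_real_
  if (!"max" %in% names(rules)) rules$max <- NA_real_
  if (!"flag_value" %in% names(rules)) rules$flag_value <- NA
  keep <- rep(TRUE, nrow(data))
  counts <- integer(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    v <- data[[rules$variable[i]]]
    bad <- rep(FALSE, length(v))
    if (!is.na(rules$min[i])) bad <- bad | (!is.na(v) & v < rules$min[i])
    if (!is.na(rules$max[i])) bad <- bad | (!is.na(v) & v > rules$max[i])
    if (!is.na(rules$flag_value[i])) {
      bad <- bad | (!is.na(v) & v == rules$flag_value[i])
    }
    counts[i] <- sum(bad & keep)
    keep <- keep & !bad
  }
  out <- tibble::as_tibble(data)[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble::tibble(
    variable = rules$variable,
    removed = counts
  )
  inform(sprintf("Excluded %d of %d record(s) across %d rule(s).",
                 nrow(data) - nrow(out), nrow(data), nrow(rules)))
  out
}

#' Default exclusion-rule configuration
#'
#' Reads the packaged default outlier/flag configuration (YAML) into the
#' rule table accepted by [exclude_records()]. Ranges are configuration,
#' not constants: cohort data managers set them per study.
#'
#' @param path Optional path to a YAML config; defaults to the packaged
#'   file.
#' @return A tibble of rules.
#' @export
read_exclusion_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exclusion-rules.yaml",
                                package = "nutrimedmr", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw$rules, function(r) {
    tibble::tibble(
      variable = r$variable,
      min = r$min %||% NA_real_,
      max = r$max %||% NA_real_,
      flag_value = r$flag_value %||% NA
    )
  })
}
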