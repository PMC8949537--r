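# rounded effect text: 2 decimals for effects, scientific for small p
.fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, digits = digits, format = "f"))
}

.fmt_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "-",
    p < 1e-3 ~ formatC(p, digits = 2, format = "e"),
    TRUE ~ formatC(p, digits = 2, format = "f")
  )
}

#' Render MR results as an effect table
#'
#' One row per exposure–outcome pair with the estimator columns in
#' standard order (instrument count, median F, then estimate / 95% CI /
#' p for IVW, MR-Egger with its intercept, MR-PRESSO and MR-RAPS).
#' Methods that were not estimable (e.g. Egger with a single variant)
#' are rendered as `"-"`. Every number is a rounded copy of a field in
#' the result object; nothing is recomputed at formatting time.
#'
#' @param results A named list of `mr_result` objects (or a single one);
#'   names become the `analysis` column.
#' @param path Optional TSV output path.
#' @return The rendered tibble (written to `path` when given).
#' @export
render_effect_table <- function(results, path = NULL) {
  if (inherits(results, "mr_result")) results <- list(analysis = results)
  rows <- purrr::imap_dfr(results, function(res, nm) {
    g <- function(m, col) {
      r <- res$methods[res$methods$method == m, ]
      if (nrow(r) == 0) NA_real_ else r[[col]][1]
    }
    scale_col <- if (isTRUE(res$binary_outcome)) "or" else "estimate"
    ci_l <- if (isTRUE(res$binary_outcome)) "or_ci_lower" else "ci_lower"
    ci_u <- if (isTRUE(res$binary_outcome)) "or_ci_upper" else "ci_upper"
    est_block <- function(m) {
      e <- g(m, scale_col)
      if (is.na(e)) c("-", "-", "-") else {
        c(.fmt_num(e),
          sprintf("(%s, %s)", .fmt_num(g(m, ci_l)), .fmt_num(g(m, ci_u))),
          .fmt_p(g(m, "p_value")))
      }
    }
    ivw <- est_block("ivw"); egger <- est_block("egger")
    raps <- est_block("raps"); wald <- est_block("wald_ratio")
    tibble::tibble(
      analysis = nm,
      n_snps = res$k,
      f_median = .fmt_num(res$instrument_strength$median_f, 1),
      ivw_estimate = ivw[1], ivw_ci = ivw[2], ivw_p = ivw[3],
      egger_estimate = egger[1], egger_ci = egger[2], egger_p = egger[3],
      egger_intercept = .fmt_num(g("egger_intercept", "estimate")),
      egger_intercept_p = .fmt_p(g("egger_intercept", "p_value")),
      presso_global_p = if (is.null(res$presso)) "-" else .fmt_p(res$presso$global_p),
      raps_estimate = raps[1], raps_ci = raps[2], raps_p = raps[3],
      wald_estimate = wald[1], wald_ci = wald[2], wald_p = wald[3],
      verdict = res$verdict
    )
  })
  if (!is.null(path)) readr::write_tsv(rows, path)
  rows
}

#' Forest-plot data for an MR result
#'
#' Per-variant Wald ratios with 95% intervals plus one summary row per
#' estimable method; suitable for a downstream forest plot (see
#' [autoplot.mr_result()]).
#'
#' @param result An `mr_result`.
#' @param path Optional TSV output path.
#' @return Tibble with `label`, `type` (`variant`/`summary`),
#'   `estimate`, `ci_lower`, `ci_upper`.
#' @export
render_forest_data <- function(result, path = NULL) {
  h <- result$harmonized
  z <- qnorm(0.975)
  variants <- tibble::tibble(
    label = h$SNP, type = "variant",
    estimate = h$ratio,
    ci_lower = h$ratio - z * h$ratio_se,
    ci_upper = h$ratio + z * h$ratio_se
  )
  sums <- dplyr::filter(result$methods, .data$estimable,
                        .data$method != "egger_intercept")
  summaries <- tibble::tibble(
    label = sums$method, type = "summary",
    estimate = sums$estimate,
    ci_lower = sums$ci_lower, ci_upper = sums$ci_upper
  )
  out <- dplyr::bind_rows(variants, summaries)
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Write a run manifest
#'
#' Records what a pipeline run did — command, configuration hash, seeds,
#' input digests, row/variant counts before and after each filter,
#' package version and timestamp — as JSON, so identical inputs and
#' seeds can be verified to reproduce identical outputs.
#'
#' @param path Output JSON path.
#' @param command Short command/stage label.
#' @param seeds Named or unnamed seed vector.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param filter_counts Data frame with columns `stage`, `n_before`,
#'   `n_removed` (all removals must be non-negative).
#' @param status `"completed"` or `"failed"`.
#' @param failed_stage Stage name when `status = "failed"`.
#' @param config Optional configuration list (hashed into the manifest).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seeds = integer(), inputs = character(),
                           filter_counts = NULL, status = "completed",
                           failed_stage = NULL, config = NULL) {
  if (!is.null(filter_counts)) {
    filter_counts <- tibble::as_tibble(filter_counts)
    check_columns(filter_counts, c("stage", "n_before", "n_removed"),
                  where = "filter_counts")
    if (any(filter_counts$n_removed < 0)) {
      abort("Filter removed-counts must be non-negative.")
    }
  }
  digest_file <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    # content digest: size + sum of raw bytes (stable, dependency-free)
    raw <- readBin(f, "raw", n = file.size(f))
    sprintf("size%d-sum%.0f", length(raw), sum(as.integer(raw)))
  }
  manifest <- list(
    command = command,
    config_hash = if (is.null(config)) NA_character_ else {
      sprintf("%.0f", sum(utf8ToInt(paste(deparse(config), collapse = ""))))
    },
    seeds = as.list(seeds),
    inputs = purrr::map(setNames(as.list(inputs), inputs), digest_file),
    filters = if (is.null(filter_counts)) list() else filter_counts,
    software_version = as.character(packageVersion("nutrimedmr")),
    status = status,
    failed_stage = failed_stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(manifest)
}
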