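#' Select genetic instruments from exposure summary statistics
#'
#' Keeps variants whose exposure association passes `p_threshold`
#' (default 5e-6, the relaxed threshold used when genome-wide-significant
#' variants are scarce), then applies greedy LD clumping: the
#' lowest-p-value variant is retained and every other variant within
#' `window_kb` of it on the same chromosome with squared correlation at
#' or above `r2_max` is removed; the process repeats on the remainder.
#' Clumping requires an LD matrix; without one the p-value filter alone
#' is applied and a message is emitted.
#'
#' @param exposure GWAS summary tibble (see [validate_gwas_summary()]).
#' @param p_threshold Inclusion threshold in (0, 1].
#' @param ld Optional square matrix of squared correlations (r^2) with
#'   unit diagonal, dimnames = variant ids.
#' @param r2_max Clumping r^2 cutoff (default 0.2).
#' @param window_kb Clumping window, kb each side (default 1000).
#' @return Filtered summary tibble.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-6, ld = NULL,
                               r2_max = 0.2, window_kb = 1000) {
  exposure <- validate_gwas_summary(exposure)
  check_number(p_threshold, "p_threshold", lower = .Machine$double.xmin, upper = 1)
  kept <- exposure[!is.na(exposure$P) & exposure$P < p_threshold, , drop = FALSE]
  if (nrow(kept) == 0) {
    warn("No variants pass the p-value threshold.")
    return(kept)
  }
  if (is.null(ld)) {
    if (nrow(kept) > 1) {
      inform("No LD matrix supplied: clumping skipped, p-value filter only.")
    }
    return(kept)
  }
  ld <- as.matrix(ld)
  if (nrow(ld) != ncol(ld) || is.null(rownames(ld)) ||
      !all(kept$SNP %in% rownames(ld))) {
    abort("`ld` must be a square matrix whose dimnames cover the selected variants.")
  }
  if (max(abs(ld - t(ld))) > 1e-8 || any(abs(diag(ld) - 1) > 1e-8)) {
    abort("`ld` must be symmetric with unit diagonal.")
  }
  remaining <- kept[order(kept$P), , drop = FALSE]
  chosen <- character()
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    chosen <- c(chosen, top$SNP)
    same_window <- remaining$CHR == top$CHR &
      abs(remaining$POS - top$POS) <= window_kb * 1000
    r2 <- ld[top$SNP, remaining$SNP]
    drop_idx <- same_window & r2 >= r2_max
    drop_idx[1] <- TRUE
    remaining <- remaining[!drop_idx, , drop = FALSE]
  }
  kept[kept$SNP %in% chosen, , drop = FALSE]
}

#' Combine two instrument sets, removing overlapping variants
#'
#' Builds an adjusted instrument (e.g. carbohydrate adjusted for sugar)
#' by taking the union of two selected sets and removing any variant that
#' appears in both, since shared variants signal pleiotropy between the
#' component exposures. Provenance is recorded per variant.
#'
#' @param set_a,set_b Selected summary tibbles.
#' @param labels Length-2 names recorded in the `source` column.
#' @return The union tibble minus overlapping variants, with a `source`
#'   column; attribute `overlap` lists the removed ids.
#' @export
build_adjusted_instrument <- function(set_a, set_b, labels = c("set_a", "set_b")) {
  set_a <- validate_gwas_summary(set_a)
  set_b <- validate_gwas_summary(set_b)
  overlap <- intersect(set_a$SNP, set_b$SNP)
  out <- dplyr::bind_rows(
    dplyr::mutate(set_a[!set_a$SNP %in% overlap, ], source = labels[1]),
    dplyr::mutate(set_b[!set_b$SNP %in% overlap, ], source = labels[2])
  )
  if (nrow(out) == 0) {
    abort("All variants overlap between the two sets: empty instrument.")
  }
  if (length(overlap)) {
    inform(sprintf("Removed %d overlapping variant(s): %s",
                   length(overlap), paste(overlap, collapse = ", ")))
  }
  attr(out, "overlap") <- overlap
  out
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two studies on the exposure's effect allele: variants
#' missing from the outcome study are dropped (`removed_missing`);
#' palindromic A/T and C/G variants are dropped regardless of frequency
#' (`removed_palindromic`) because their strand cannot be resolved from
#' alleles alone; outcome records whose alleles are swapped (directly or
#' on the opposite strand) have their effect sign and allele frequency
#' flipped exactly once (`flipped`); allele pairs that match neither
#' directly nor by strand complement are dropped (`removed_mismatch`).
#'
#' @param exposure,outcome GWAS summary tibbles keyed by `SNP`.
#' @return A `harmonized_instruments` tibble of kept variants with
#'   columns `SNP`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `action`, and per-variant Wald ratios
#'   `ratio`/`ratio_se`. The full per-variant action log (including
#'   removals) is in `attr(, "log")`.
#' @export
harmonize <- function(exposure, outcome) {
  exposure <- validate_gwas_summary(exposure)
  outcome <- validate_gwas_summary(outcome)
  log <- tibble::tibble(SNP = exposure$SNP, action = NA_character_)
  o_idx <- match(exposure$SNP, outcome$SNP)
  keep_rows <- list()
  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, ]
    if (is.na(o_idx[i])) { log$action[i] <- "removed_missing"; next }
    if (.is_palindromic(e$EA, e$OA)) { log$action[i] <- "removed_palindromic"; next }
    o <- outcome[o_idx[i], ]
    direct <- o$EA == e$EA && o$OA == e$OA
    swapped <- o$EA == e$OA && o$OA == e$EA
    comp_direct <- o$EA == .complement[e$EA] && o$OA == .complement[e$OA]
    comp_swapped <- o$EA == .complement[e$OA] && o$OA == .complement[e$EA]
    if (!direct && !swapped && !comp_direct && !comp_swapped) {
      log$action[i] <- "removed_mismatch"; next
    }
    flip <- swapped || comp_swapped
    log$action[i] <- if (flip) "flipped" else "kept"
    keep_rows[[length(keep_rows) + 1L]] <- tibble::tibble(
      SNP = e$SNP, CHR = e$CHR, POS = e$POS,
      beta_exposure = e$BETA, se_exposure = e$SE,
      beta_outcome = if (flip) -o$BETA else o$BETA,
      se_outcome = o$SE,
      eaf_exposure = e$EAF,
      eaf_outcome = if (flip) 1 - o$EAF else o$EAF,
      action = log$action[i]
    )
  }
  out <- if (length(keep_rows)) dplyr::bind_rows(keep_rows) else tibble::tibble(
    SNP = character(), CHR = numeric(), POS = numeric(),
    beta_exposure = numeric(), se_exposure = numeric(),
    beta_outcome = numeric(), se_outcome = numeric(),
    eaf_exposure = numeric(), eaf_outcome = numeric(), action = character()
  )
  if (nrow(out)) {
    out$ratio <- out$beta_outcome / out$beta_exposure
    out$ratio_se <- out$se_outcome / abs(out$beta_exposure)
  } else {
    out$ratio <- numeric()
    out$ratio_se <- numeric()
  }
  n_removed <- sum(!log$action %in% c("kept", "flipped"))
  if (n_removed) {
    inform(sprintf("Harmonization removed %d of %d variant(s) (%s).",
                   n_removed, nrow(exposure),
                   paste(names(table(log$action[!log$action %in% c("kept", "flipped")])),
                         collapse = ", ")))
  }
  structure(out, log = log, class = c("harmonized_instruments", class(out)))
}
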