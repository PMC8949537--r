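# internal argument checks shared across modules

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf, allow_na = TRUE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  if (!allow_na && anyNA(x)) abort(sprintf("`%s` must not contain missing values.", name))
  if (any(x < lower, na.rm = TRUE)) {
    abort(sprintf("`%s` must be >= %s.", name, lower))
  }
  invisible(x)
}

check_columns <- function(data, cols, where = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("Column(s) %s not found in %s.",
                  paste0("`", missing, "`", collapse = ", "), where))
  }
  invisible(data)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
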