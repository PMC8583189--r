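# Internal argument checks shared across modules.

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_(sprintf("`%s` must be numeric with no missing values", name))
  }
  if (positive && any(x <= 0)) {
    stop_(sprintf("`%s` must be strictly positive", name))
  }
  if (nonneg && any(x < 0)) {
    stop_(sprintf("`%s` must be non-negative", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))
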