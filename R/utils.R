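# internal helpers

abort_param <- function(msg) rlang::abort(msg, class = "polyadapt_param_error")
abort_input <- function(msg) rlang::abort(msg, class = "polyadapt_input_error")
abort_data  <- function(msg) rlang::abort(msg, class = "polyadapt_data_error")

check_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) abort_param(sprintf("`%s` must be a fraction in %s", name,
                               if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort_param(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

# midpoints between consecutive positions; used for block boundaries
midpoints <- function(pos) (pos[-length(pos)] + pos[-1L]) / 2

# safe tibble column access (tibbles warn on `$` for missing columns)
col_or_null <- function(df, name) if (name %in% names(df)) df[[name]] else NULL
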