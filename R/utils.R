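## Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on class.
stop_metapan <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "metapanr_error"), ...)
}

assert_columns <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_metapan(
      sprintf("`%s` is missing required column(s): %s",
              arg, paste(missing, collapse = ", ")),
      class = "metapanr_input_error"
    )
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    stop_metapan(
      sprintf("`%s` must be a single finite number in %s%s, %s%s (got %s)",
              name, if (lower_open) "(" else "[", format(lower),
              format(upper), if (upper_open) ")" else "]",
              paste(format(x), collapse = ", ")),
      class = "metapanr_config_error"
    )
  }
  invisible(x)
}

# Deterministic substream seed: root seed plus a fixed per-stage offset,
# kept well below 2^31.
substream <- function(seed, stage) {
  offsets <- c(catalog = 1L, coverage = 2L, annotations = 3L,
               permutation = 4L, design = 5L)
  if (!stage %in% names(offsets)) {
    stop_metapan(sprintf("unknown seed substream '%s'", stage),
                 class = "metapanr_config_error")
  }
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# Site factor honouring the canonical oral ordering for known labels and
# first-appearance order for anything else.
site_factor <- function(x) {
  known <- intersect(oral_sites, unique(x))
  extra <- setdiff(unique(x), oral_sites)
  factor(x, levels = c(known, extra))
}
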