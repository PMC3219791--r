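# Error helpers: every user-facing failure carries a class so callers (and
# tests) can distinguish malformed files from bad experimental designs from
# bad configuration.

abort_format <- function(msg, ...) {
  abort(msg, class = "droughtseq_format_error", ...)
}

abort_design <- function(msg, ...) {
  abort(msg, class = "droughtseq_design_error", ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "droughtseq_config_error", ...)
}

is_scaffold_id <- function(x, pattern = SCAFFOLD_PATTERN) {
  grepl(pattern, x)
}

# Percentages in QC reports are printed to one decimal, matching the
# convention of published lane-summary tables.
round1 <- function(x) round(x, 1)

assert_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_format(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic child seeds derived from one global seed, so that every
# sub-generator is independently reproducible. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %% 2147483587)
}
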