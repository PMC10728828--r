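# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit child seed for a named substream so that, e.g., the
# cohort generator and a downstream bootstrap never consume the same RNG
# stream. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  if (is.character(stream)) stream <- sum(utf8ToInt(stream))
  (((as.numeric(seed) %% 1000003) * 2011) + (as.numeric(stream) %% 99991) * 7919) %%
    2147483646 + 1
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
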