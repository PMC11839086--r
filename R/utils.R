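# internal helpers shared across modules

# Deterministic per-stage seed derived from the global seed, so adding a
# stage never perturbs the randomness of earlier stages.  Kept < 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- rlang::`%||%`

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# uppercase + strip whitespace: the exact-match normalisation used whenever
# gene symbols from different tables are compared
norm_symbol <- function(x) toupper(gsub("\\s+", "", x))

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
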