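# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

FRACTIONS <- c("cytosol", "chromatin")
RUN_LABELS <- c("exp1", "exp2")
ORIENTATIONS <- c("control-heavy", "control-light")
QUADRANTS <- c("double_positive", "chromatin_pos_cytosol_neg",
               "double_negative", "cytosol_pos_chromatin_neg", "center")

`%||%` <- function(a, b) if (is.null(a)) b else a
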