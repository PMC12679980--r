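#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed for a named stage, keyed by (seed, stage name).
# Keeps every pipeline stage independently reproducible from one master seed.
# The hash is a small polynomial over the stage name's UTF-8 bytes, folded
# into [0, 2^31 - 2] so it is a valid 32-bit R integer seed.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  bytes <- as.integer(charToRaw(stage))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 1000003 * 2017 + h) %% 2147483647)
}

# Evaluate a thunk under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_upf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "upfsurvey_error")))
}
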