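# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' package functions never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-subject seed from a master seed
#'
#' Deterministic integer hash so each subject has an independent, reproducible
#' random stream (Lehmer-style congruential mix; all arithmetic stays below
#' 2^53 so it is exact in doubles).
#'
#' @param master_seed integer master seed.
#' @param index 1-based subject index.
#' @return integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_subject_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (abs(as.numeric(master_seed)) %% m)
  h <- (h * 48271 + 16807 * as.numeric(index) + 12345) %% m
  h <- (h * 69621 + 1) %% m
  as.integer(h + 1)
}

# Smallest power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_interval <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 2L && all(is.finite(x)) && x[1] < x[2]))
    stopf("%s must be a finite interval c(lo, hi) with lo < hi", name)
  invisible(x)
}

# dB helper
db <- function(ratio) 20 * log10(ratio)
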