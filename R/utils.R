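#' Derive a stage-specific sub-seed from a global seed
#'
#' A single run seed fans out deterministically to each randomized stage
#' (cohort generation, splitting, weight initialization, batch sampling), so
#' changing one stage's randomness never silently changes another's. The
#' derivation hashes the stage name into the seed and keeps the result inside
#' the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"cohort"`, `"train"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # multiplicative hash mod a prime below 2^31; all-double arithmetic is
  # exact here because intermediates stay far below 2^53
  p <- 2147483629
  as.integer(((abs(seed) %% p) * 48271 + h * 16807) %% p)
}

# Run an expression under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-up, immune to the banker's rounding of base round()
round_half_up <- function(x) floor(x + 0.5)

stop_lnm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "lnmfusion_error"))
}
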