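## Internal helpers shared across modules.

#' Run code with a local, restorable RNG seed
#'
#' All stochastic operations funnel their randomness through this helper so a
#' user-supplied seed makes them bit-reproducible without disturbing the
#' caller's RNG stream. `seed = NULL` leaves the global stream untouched.
#' @noRd
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Deterministically expand one run seed into per-stage seeds
#'
#' Stages of a pipeline run each get their own seed so any stage can be rerun
#' in isolation and still reproduce.
#'
#' @param seed integer master seed.
#' @param n number of stage seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @examples
#' spawnSeeds(1, 3)
#' @export
spawnSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
.assertProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1], got ",
         deparse(x), call. = FALSE)
  invisible(x)
}

#' @noRd
.assertNonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("'", name, "' must be a single non-negative number, got ",
         deparse(x), call. = FALSE)
  invisible(x)
}
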