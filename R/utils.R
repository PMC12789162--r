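# Small shared numeric helpers.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; discretization of simulated scores
#' and the continuous-SIM rescaling recipe both require ties to go away from
#' zero (so 6.5 -> 7, -6.5 -> -7). Used everywhere a score is discretized.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Log-odds of a proportion
#'
#' Natural-log odds, as used in the APM adjustment formula.
#'
#' @param p proportion strictly inside (0, 1).
#' @return \code{log(p / (1 - p))}.
#' @export
logodds <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("logodds() requires proportions strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state. Keeps all derived seeds below 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
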