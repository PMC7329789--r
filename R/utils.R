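#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return probabilities in (0, 1).
#' @keywords internal
invlogit <- function(x) stats::plogis(x)

#' Logit
#'
#' @param p numeric vector of probabilities.
#' @return log-odds.
#' @keywords internal
logit <- function(p) stats::qlogis(p)

#' Round half away from zero
#'
#' Display rounding used for percent-reported tables: ties go away from
#' zero (40.5 -> 41, -40.5 -> -41), unlike base [round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(40.09, 29.73, 88.52, 0.5, -0.5))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic sub-seed below 2^31 from a base seed and index keys.
# Mixes with distinct large primes so (seed, g, r) collisions are not a
# practical concern at the grid sizes used here.
mix_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed %% 2147483647L)
  primes <- c(2654435761, 40503, 2246822519, 3266489917, 668265263)
  for (i in seq_along(keys)) {
    p <- primes[((i - 1L) %% length(primes)) + 1L]
    s <- (s * 31 + as.double(keys[i]) * p) %% 2147483647
  }
  as.integer(s)
}

# Validate that a named numeric vector is a proper proportion vector.
check_proportions <- function(p, what, tol = 1e-9) {
  errs <- character(0)
  if (length(p) == 0L) {
    return(sprintf("%s: empty proportion vector", what))
  }
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    errs <- c(errs, sprintf("%s: proportions must be named", what))
  }
  if (any(p < 0)) {
    errs <- c(errs, sprintf("%s: negative proportion", what))
  }
  if (abs(sum(p) - 1) > tol) {
    errs <- c(errs, sprintf("%s: proportions sum to %.9g, not 1", what, sum(p)))
  }
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
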