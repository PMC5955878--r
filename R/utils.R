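## Internal helpers shared across modules.

#' Derive a reproducible per-stage seed from the session seed
#'
#' All stochastic stages draw from substreams keyed by stage name, so a single
#' session seed controls every source of randomness while stages stay
#' order-independent.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Mean of x over index range [lo, hi] via a 0-prefixed cumulative sum.
## lo/hi may be vectors; invalid ranges give NA.
bin_mean_cs <- function(cs, lo, hi) {
  n <- length(cs) - 1L
  bad <- lo > hi | lo < 1L | hi > n
  lo2 <- pmax(pmin(lo, n), 1L)
  hi2 <- pmax(pmin(hi, n), 1L)
  out <- (cs[hi2 + 1L] - cs[lo2]) / (hi2 - lo2 + 1)
  out[bad] <- NA_real_
  out
}

## Circularly shift a vector by k (k >= 0 moves content rightwards).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[1:(n - k)])
}

## Local maxima indices of a numeric vector (strict on the left, >= right,
## so plateaus report their first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
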