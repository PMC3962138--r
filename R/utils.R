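# Small numeric helpers shared across the pipeline.

#' Trapezoidal integral
#'
#' Integrates `y` over `x` by the trapezoidal rule (zero baseline).
#'
#' @param x numeric, strictly increasing abscissae.
#' @param y numeric, same length as `x`.
#' @return scalar integral in units of `x * y`.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Centered moving average with odd window k; edges keep the raw values so the
# smoothed trace has the same length and no NA padding.
moving_average <- function(y, k = 5L) {
  k <- as.integer(k)
  if (k <= 1L) return(y)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(y)
  if (n < k) return(y)
  s <- stats::filter(y, rep(1 / k, k), sides = 2)
  s <- as.numeric(s)
  half <- (k - 1L) %/% 2L
  idx <- c(seq_len(half), seq(n - half + 1L, n))
  s[idx] <- y[idx]
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
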