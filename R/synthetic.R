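#' Reference time series of known scaling exponent
#'
#' Generators used to validate the DFA stage independently of the walker
#' simulator: `"white"` gives i.i.d. Gaussian noise (`alpha = 0.5`),
#' `"brown"` its cumulative sum (`alpha` about 1.5), and `"fgn"` fractional
#' Gaussian noise with Hurst exponent `hurst` (`alpha` recovers `hurst`).
#' fGn is synthesised by circulant embedding of its exact autocovariance,
#' which is exact in distribution and testable against the closed-form
#' lag-1 autocorrelation `2^(2H-1) - 1`.
#'
#' The realized series is affinely mapped to have sample mean `mean` and
#' sample standard deviation `sd` (scaling does not affect `alpha`).
#'
#' Randomness is drawn from R's RNG; call `set.seed()` for reproducibility,
#' or pass `seed`.
#'
#' @param kind `"white"`, `"brown"` or `"fgn"`.
#' @param n series length (`n >= 16`).
#' @param hurst target Hurst exponent in (0, 1); fGn only.
#' @param mean,sd sample mean and standard deviation of the output.
#' @param seed optional integer; if supplied the series is drawn from a
#'   local RNG state (the global state is restored).
#' @return Numeric series of length `n`.
#' @examples
#' set.seed(42)
#' x <- synthetic_series("white", 500)
#' dfa(x)$alpha # about 0.5
#' @export
synthetic_series <- function(kind = c("white", "brown", "fgn"), n,
                             hurst = 0.75, mean = 0, sd = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 16L, sd > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  z <- switch(kind,
    white = stats::rnorm(n),
    brown = cumsum(stats::rnorm(n)),
    fgn = {
      if (hurst <= 0 || hurst >= 1)
        stop("hurst must lie strictly between 0 and 1")
      fgn_circulant(n, hurst)
    })
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# Exact fGn autocovariance at lags 0..m for unit variance.
fgn_autocov <- function(m, H) {
  k <- 0:m
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Circulant-embedding (Dietrich-Newsam) synthesis of fractional Gaussian
# noise.  The embedding of the fGn covariance is nonnegative definite for
# H in (0,1); tiny negative eigenvalues from rounding are clipped.
fgn_circulant <- function(n, H) {
  m <- n
  repeat {
    first_row <- c(fgn_autocov(m, H), rev(fgn_autocov(m, H)[2:m]))
    lam <- Re(stats::fft(first_row))
    if (min(lam) > -1e-8 * max(lam)) break
    m <- 2L * m
  }
  lam[lam < 0] <- 0
  M <- length(lam) # = 2m
  z <- complex(real = stats::rnorm(M), imaginary = stats::rnorm(M))
  w <- stats::fft(sqrt(lam / (2 * M)) * z)
  Re(w)[seq_len(n)]
}
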