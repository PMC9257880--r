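#' Accumulated profile of a stride-interval series
#'
#' Forms `y(i) = sum_{k<=i} (x(k) - mean(x))`, the mean-centred accumulated
#' sum on which DFA operates.  By construction `y(N) = 0` up to rounding.
#'
#' @param x numeric series (stride intervals, s).
#' @return A list with `y` (the profile) and `xbar` (the series mean).
#' @export
dfa_accumulate <- function(x) {
  stopifnot(length(x) >= 1L)
  xbar <- mean(x)
  list(y = cumsum(x - xbar), xbar = xbar)
}

#' Logarithmically spaced box sizes for DFA
#'
#' `count` integers spaced equally on a log scale between 4 and `N/4`,
#' rounded to integers with duplicates resolved upward.  For `N = 500`,
#' `count = 20` this grid runs 4, 5, 6, ..., 87, 104, 125.
#'
#' @param N series length (`N >= 16`).
#' @param count requested number of box sizes.
#' @return Integer vector of box sizes in `[4, N/4]`; may be shorter than
#'   `count` if the range cannot hold `count` distinct integers.
#' @export
dfa_box_grid <- function(N, count = 20L) {
  if (N < 16L) stop("DFA needs N >= 16 (no box sizes in [4, N/4])")
  nmax <- floor(N / 4)
  raw <- 4 * (nmax / 4) ^ (seq(0L, count - 1L) / (count - 1L))
  n <- as.integer(round(raw))
  for (i in seq_along(n)[-1L])
    if (n[i] <= n[i - 1L]) n[i] <- n[i - 1L] + 1L
  n[n <= nmax]
}

#' Fluctuation function for one box size
#'
#' Splits the profile into `floor(N/n)` non-overlapping segments of length
#' `n` from the start (any remainder is discarded), removes a least-squares
#' line from each segment, and returns the root of the mean squared residual
#' pooled over all retained segments.
#'
#' @param y accumulated profile (numeric, or the list from
#'   [dfa_accumulate()]).
#' @param n box size (`4 <= n <= length(y)/4`).
#' @return `F(n)`, in the units of the series.
#' @export
dfa_fluctuation <- function(y, n) {
  if (is.list(y)) y <- y$y
  N <- length(y)
  if (n > N / 4) stop("box size n = ", n, " exceeds N/4 = ", N / 4)
  if (n < 2L) stop("box size must be at least 2")
  k <- N %/% n
  seg <- matrix(y[seq_len(k * n)], nrow = n)
  s <- seq_len(n) - (n + 1) / 2           # centred regressor
  ss <- sum(s * s)
  beta <- colSums(seg * s) / ss
  alpha <- colMeans(seg)
  resid <- seg - rep(alpha, each = n) - outer(s, beta)
  sqrt(mean(resid^2))
}

#' Detrended fluctuation analysis of a stride-interval series
#'
#' Computes the DFA-1 fluctuation function `F(n)` over a log-spaced box
#' grid and fits `log F(n) ~ log n` by ordinary least squares; the slope is
#' the scaling exponent `alpha`.  `alpha = 0.5` indicates an uncorrelated
#' (white) series; `alpha < 0.5` statistical anti-persistence;
#' `0.5 < alpha <= 1` statistical persistence; `alpha > 1` brown noise
#' (integrated white noise).
#'
#' @param x numeric series of stride intervals (length >= 16), or a
#'   `walk_trial` object (whose analysis window is then extracted with
#'   [analysis_window()] defaults).
#' @param n_boxes number of box sizes (see [dfa_box_grid()]).
#' @param discard,keep forwarded to [analysis_window()] when `x` is a
#'   `walk_trial`.
#' @return An object of class `"dfa"`: `n`, `F`, `alpha`, `intercept`
#'   (log-log fit), `N`, `xbar`, `classification`.
#' @examples
#' set.seed(1)
#' d <- dfa(rnorm(500))
#' d$alpha # about 0.5
#' @export
dfa <- function(x, n_boxes = 20L, discard = 150L, keep = 500L) {
  if (inherits(x, "walk_trial"))
    x <- analysis_window(x, discard = discard, keep = keep)
  x <- as.numeric(x)
  N <- length(x)
  if (N < 16L) stop("DFA needs at least 16 observations")
  prof <- dfa_accumulate(x)
  n <- dfa_box_grid(N, n_boxes)
  Fv <- vapply(n, function(nn) dfa_fluctuation(prof$y, nn), numeric(1))
  if (any(!is.finite(Fv)) || any(Fv <= 0))
    stop("degenerate series: F(n) vanished (series is exactly ",
         "linear after accumulation); log F is undefined")
  if (length(n) < 3L) stop("fewer than 3 valid box sizes")
  fit <- stats::lm.fit(cbind(1, log(n)), log(Fv))
  alpha <- unname(fit$coefficients[2L])
  structure(list(n = n, F = Fv, alpha = alpha,
                 intercept = unname(fit$coefficients[1L]),
                 N = N, xbar = prof$xbar,
                 classification = persistence_class(alpha)),
            class = "dfa")
}

#' Fit the scaling exponent from an (n, F) grid
#'
#' Slope of the unweighted least-squares line through
#' `(log n, log F)`; the logarithm base does not affect the slope.
#'
#' @param n box sizes.
#' @param F fluctuation values (`F > 0`).
#' @return The scaling exponent `alpha`.
#' @export
dfa_fit_alpha <- function(n, F) {
  ok <- is.finite(F) & F > 0
  if (sum(ok) < 3L) stop("need at least 3 valid (n, F) pairs")
  fit <- stats::lm.fit(cbind(1, log(n[ok])), log(F[ok]))
  unname(fit$coefficients[2L])
}

#' Persistence classification of a scaling exponent
#'
#' @param alpha scaling exponent(s).
#' @return A factor with levels `"anti-persistent"` (`alpha < 0.5`),
#'   `"uncorrelated"` (`alpha = 0.5`), `"persistent"`
#'   (`0.5 < alpha <= 1`), `"brown"` (`alpha > 1`).
#' @export
persistence_class <- function(alpha) {
  lv <- c("anti-persistent", "uncorrelated", "persistent", "brown")
  cls <- ifelse(alpha < 0.5, lv[1L],
         ifelse(alpha == 0.5, lv[2L],
         ifelse(alpha <= 1.0, lv[3L], lv[4L])))
  factor(cls, levels = lv)
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf("DFA: N = %d, %d box sizes in [%d, %d]\n",
              x$N, length(x$n), min(x$n), max(x$n)))
  cat(sprintf("alpha = %.4f (%s)\n", x$alpha,
              as.character(x$classification)))
  invisible(x)
}

#' @export
coef.dfa <- function(object, ...) {
  c(intercept = object$intercept, alpha = object$alpha)
}

#' @export
plot.dfa <- function(x, ...) {
  plot(log10(x$n), log10(x$F), xlab = "log10 n", ylab = "log10 F(n)",
       main = sprintf("DFA: alpha = %.3f", x$alpha), ...)
  abline(a = x$intercept / log(10) , b = x$alpha, lty = 2)
  invisible(x)
}

#' Random-shuffle surrogate of a series
#'
#' Returns a uniformly random permutation of `x`.  Shuffling destroys all
#' temporal structure while preserving the value distribution, so DFA on a
#' shuffled surrogate of any series yields `alpha` near 0.5.
#'
#' @param x numeric series.
#' @param seed optional integer; if supplied, the permutation is drawn from
#'   a local RNG state seeded with it (the global RNG state is restored).
#' @return A permutation of `x`.
#' @export
shuffle_surrogate <- function(x, seed = NULL) {
  stopifnot(length(x) >= 2L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  x[sample.int(length(x))]
}
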