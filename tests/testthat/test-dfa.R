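test_that("accumulated profile telescopes to zero", {
  p <- dfa_accumulate(c(1, 2, 3))
  expect_equal(p$xbar, 2)
  expect_equal(p$y, c(-1, -1, 0))
  expect_equal(dfa_accumulate(rep(3.7, 40))$y, rep(0, 40))
  set.seed(2)
  x <- rnorm(500)
  expect_lt(abs(dfa_accumulate(x)$y[500]), 1e-12 * 500 * stats::sd(x))
})

test_that("box grid is log-spaced with the documented anchors", {
  n <- dfa_box_grid(500, 20)
  expect_length(n, 20L)
  expect_false(any(duplicated(n)))
  expect_equal(min(n), 4L)
  expect_equal(max(n), 125L)
  expect_true(all(c(4L, 5L, 6L, 87L, 104L, 125L) %in% n))
  expect_true(all(n >= 4 & n <= 125))
  # endpoint collapse
  expect_true(all(dfa_box_grid(16, 20) == 4L))
  expect_error(dfa_box_grid(15), "N >= 16")
  # bounds hold for other lengths
  for (N in c(100, 237, 1000))
    expect_true(all(dfa_box_grid(N) <= floor(N / 4)))
})

test_that("fluctuation function matches the brute-force oracle", {
  set.seed(5)
  for (i in 1:3) {
    y <- dfa_accumulate(rnorm(500))$y
    for (n in c(4, 7, 25, 125)) {
      expect_equal(dfa_fluctuation(y, n), oracle_fluctuation(y, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("exactly linear profiles are flagged as degenerate", {
  expect_error(dfa(rep(1.31, 100)), "degenerate")
})

test_that("alpha fit recovers exact power laws", {
  n <- dfa_box_grid(500, 20)
  expect_equal(dfa_fit_alpha(n, 2.3 * n^0.5), 0.5, tolerance = 1e-12)
  expect_equal(dfa_fit_alpha(n, 0.1 * n^1.27), 1.27, tolerance = 1e-12)
  expect_error(dfa_fit_alpha(1:2, c(1, 2)), "3 valid")
})

test_that("alpha classifies white and brown noise per the taxonomy", {
  set.seed(31)
  a_white <- replicate(10, dfa(rnorm(500))$alpha)
  expect_equal(mean(a_white), 0.5, tolerance = 0.08)
  a_brown <- replicate(5, dfa(cumsum(rnorm(500)))$alpha)
  expect_true(all(a_brown > 1.0))
  expect_equal(mean(a_brown), 1.5, tolerance = 0.25)
})

test_that("persistence classification uses the exact boundaries", {
  cls <- persistence_class(c(0.3, 0.5, 0.7, 1.0, 1.2))
  expect_equal(as.character(cls),
               c("anti-persistent", "uncorrelated", "persistent",
                 "persistent", "brown"))
})

test_that("DFA is invariant to offsets and equivariant to scale", {
  set.seed(8)
  x <- rnorm(300, mean = 1.3, sd = 0.05)
  d1 <- dfa(x)
  d2 <- dfa(x + 10)
  d3 <- dfa(x * 7)
  expect_equal(d1$F, d2$F, tolerance = 1e-9)
  expect_equal(d3$F, 7 * d1$F, tolerance = 1e-9)
  expect_equal(d3$alpha, d1$alpha, tolerance = 1e-9)
})

test_that("shuffle surrogates whiten persistent series", {
  x <- synthetic_series("fgn", 500, hurst = 0.9, seed = 14)
  expect_gt(dfa(x)$alpha, 0.6) # persistent before shuffling
  sh <- shuffle_surrogate(x, seed = 5)
  expect_equal(sort(sh), sort(x))
  expect_identical(shuffle_surrogate(x, seed = 5), sh)
  a_sh <- mean(vapply(1:8, function(s)
    dfa(shuffle_surrogate(x, seed = s))$alpha, numeric(1)))
  expect_equal(a_sh, 0.5, tolerance = 0.08)
})

test_that("F(n) grows with n for positively correlated series", {
  hits <- 0; total <- 0; Fsum <- 0
  for (s in 1:20) {
    d <- dfa(synthetic_series("fgn", 500, hurst = 0.9, seed = 100 + s))
    inc <- diff(d$F) > 0
    hits <- hits + sum(inc); total <- total + length(inc)
    Fsum <- Fsum + d$F
  }
  # per-realization monotonicity is high but noisy between adjacent
  # log-spaced boxes; the ensemble-mean curve must be strictly increasing
  expect_gt(hits / total, 0.90)
  expect_true(all(diff(Fsum) > 0))
})
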