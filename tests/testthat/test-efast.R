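test_that("search curves hit their defining values", {
  # uniform arcsine curve
  expect_equal(search_curve_uniform(pi / 2, 1, 0), 1)
  expect_equal(search_curve_uniform(0, 1, 0), 0.5)
  expect_equal(search_curve_uniform(0, 3, pi / 2), 1)

  # exponential curve at the extremes and the nominal
  expect_equal(search_curve_exponential(pi / 2, 1, 0, 0.1), 1)
  expect_equal(search_curve_exponential(-pi / 2, 1, 0, 0.1), 0.01)
  expect_equal(search_curve_exponential(0, 1, 0, 0.1), 0.1)
  expect_error(search_curve_exponential(0, 1, 0, 1.5), "strictly in")
})

test_that("the uniform curve fills [0,1] uniformly", {
  s <- seq(-pi, pi, length.out = 1e5 + 1)[-1]
  x <- search_curve_uniform(s, 11, 0.37)
  ks <- max(abs(sort(x) - (seq_along(x) - 0.5) / length(x)))
  expect_lt(ks, 0.01)
  expect_true(all(x >= 0 & x <= 1))
})

test_that("design arithmetic follows the Nyquist bound", {
  des <- efast_design(cbind(rep(0, 13), rep(1, 13)), rep("uniform", 13),
                      NS = 2049, NR = 5, M = 4)
  expect_equal(des$omega_max, 256)
  expect_equal(des$n_per_block, 2049 * 5)
  expect_true(all(des$omega_comp >= 1))
  expect_true(max(des$omega_comp) * des$M < des$omega_max)
  expect_error(efast_design(cbind(c(0, 0), c(1, 1)), rep("uniform", 2),
                            NS = 2048), "odd")
  expect_error(efast_design(cbind(rep(0, 2), rep(1, 2)), rep("uniform", 2),
                            NS = 5, M = 4), "aliasing|harmonics")

  X <- efast_samples(des, 1, 1)
  expect_identical(dim(X), c(2049L, 13L))
  expect_true(all(X >= 0 & X <= 1))
})

test_that("indices match analytic values for a linear additive model", {
  des <- efast_design(cbind(rep(0, 3), rep(1, 3)), rep("uniform", 3),
                      NS = 1025, NR = 3, M = 4, seed = 2)
  res <- efast_run(des, function(X) X[, 1] + 2 * X[, 2] + 0 * X[, 3],
                   param_labels = c("a", "b", "c"))
  expect_equal(res$S_i, c(0.2, 0.8, 0), tolerance = 0.05)
  expect_equal(res$S_Ti[1:2], c(0.2, 0.8), tolerance = 0.05)
  expect_lt(res$S_Ti[3], 0.05)
  expect_equal(res$S_i[2] / res$S_i[1], 4, tolerance = 0.05)
  expect_true(all(res$S_i <= res$S_Ti + 0.02))
  expect_lte(sum(res$S_i), 1.05)
})

test_that("indices match analytic values for the Ishigami function", {
  des <- efast_design(cbind(rep(-pi, 3), rep(pi, 3)), rep("uniform", 3),
                      NS = 1025, NR = 3, M = 4, seed = 5)
  ish <- function(X) sin(X[, 1]) + 7 * sin(X[, 2])^2 +
    0.1 * X[, 3]^4 * sin(X[, 1])
  res <- efast_run(des, ish, param_labels = c("x1", "x2", "x3"))
  # closed-form Sobol indices for a = 7, b = 0.1
  b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- 49 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  expect_equal(res$S_i, c(V1 / V, V2 / V, 0), tolerance = 0.05)
  expect_equal(res$S_Ti[1], (V1 + V13) / V, tolerance = 0.05)
  expect_gt(res$S_Ti[3], res$S_i[3] + 0.1)  # pure-interaction parameter
  expect_true(all(res$S_i <= res$S_Ti + 0.02))
})

test_that("index error shrinks when the sample size doubles", {
  dev_at <- function(NS) {
    des <- efast_design(cbind(rep(0, 3), rep(1, 3)), rep("uniform", 3),
                        NS = NS, NR = 4, M = 4, seed = 3)
    res <- efast_run(des, function(X) X[, 1] + 2 * X[, 2] + 0.5 * X[, 3],
                     param_labels = c("a", "b", "c"))
    V <- (1 + 4 + 0.25) / 12
    truth <- c(1, 4, 0.25) / 12 / V
    mean(abs(res$S_i - truth))
  }
  d1 <- dev_at(513)
  d2 <- dev_at(1025)
  expect_lt(d2, d1 * 1.5)  # no worse, typically about half
})

test_that("resampling spread shrinks roughly as 1/sqrt(NR)", {
  sem_at <- function(NR) {
    des <- efast_design(cbind(rep(0, 3), rep(1, 3)), rep("uniform", 3),
                        NS = 257, NR = NR, M = 4, seed = 4)
    res <- efast_run(des, function(X) X[, 1] + 2 * X[, 2] + 0.5 * X[, 3]^2,
                     param_labels = c("a", "b", "c"))
    mean(res$sem_Si)
  }
  ratio <- sem_at(5) / sem_at(20)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.0)
})

test_that("a constant model yields zero indices with a warning", {
  des <- efast_design(cbind(rep(0, 2), rep(1, 2)), rep("uniform", 2),
                      NS = 257, NR = 2, M = 4, seed = 1)
  expect_warning(res <- efast_run(des, function(X) rep(5, nrow(X)),
                                  param_labels = c("a", "b")),
                 "constant")
  expect_true(all(res$S_i == 0))
  expect_true(all(res$S_Ti == 0))
})

test_that("failed evaluations are imputed up to the tolerated fraction", {
  des <- efast_design(cbind(rep(0, 2), rep(1, 2)), rep("uniform", 2),
                      NS = 257, NR = 2, M = 4, seed = 6)
  holey <- function(X) {
    y <- X[, 1] + 2 * X[, 2]
    y[seq_len(5)] <- NA  # < 5% of 257
    y
  }
  expect_warning(res <- efast_run(des, holey, param_labels = c("a", "b")),
                 "imputing")
  expect_equal(res$S_i, c(0.2, 0.8), tolerance = 0.07)

  broken <- function(X) rep(NA_real_, nrow(X))
  expect_error(suppressWarnings(efast_run(des, broken,
                                          param_labels = c("a", "b"))),
               "failed evaluations")
})

test_that("the exponential curve concentrates samples near the nominal", {
  s <- seq(-pi, pi, length.out = 2e4 + 1)[-1]
  x <- search_curve_exponential(s, 7, 1.1, 0.2)
  expect_true(all(x >= 0.2^2 - 1e-12 & x <= 1 + 1e-12))
  # median of the curve equals the nominal (sin is symmetric around 0)
  expect_equal(median(x), 0.2, tolerance = 0.01)
})
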