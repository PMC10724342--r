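test_that("rhs reproduces hand-evaluated rates", {
  p <- default_params()

  # empty microenvironment: only constant T-cell activation remains
  expect_equal(unname(gbm_rhs(c(0, 0, 0), p)), c(0, p[["a_T"]], 0))

  # at carrying capacity the logistic term vanishes
  d <- gbm_rhs(c(p[["C_max"]], 0, 0), p)
  expect_equal(unname(d[1]), 0)
  expect_equal(unname(d[2]), p[["a_T"]])
  expect_equal(unname(d[3]),
               p[["s_M"]] * p[["C_max"]] +
                 p[["alpha"]] * p[["C_max"]] / (p[["q"]] + p[["C_max"]]))

  # all-ones parameters (C_max = 2 for a nontrivial logistic term) at (1,1,1):
  # dC = 1*(1 - 1/2) - 1 = -0.5; dT = (1+1)/(1+1*(1+1)) - 1 - 1 = -4/3;
  # dM = 1 + 1/2 - 1 = 0.5
  ones <- parameter_set(lambda_C = 1, C_max = 2, eta = 1, a_T = 1, s_T = 1,
                        rho = 1, eps_C = 1, r = 1, d_T = 1, s_M = 1,
                        alpha = 1, q = 1, d_M = 1)
  expect_equal(unname(gbm_rhs(c(1, 1, 1), ones)), c(-0.5, -4 / 3, 0.5))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(parameter_set(rep(-1, 13)), "positive")
  bad <- unclass(default_params()); bad[["eta"]] <- NA
  expect_error(parameter_set(bad), "non-finite")
  expect_error(gbm_rhs(c(1, NA, 1), default_params()), "finite")
})

test_that("the tumor-free equilibrium is a fixed point of the solver", {
  p <- default_params()
  T0 <- tumor_free_equilibrium(p)$T0_star
  tr <- gbm_simulate(p, init = c(0, T0, 0), t_end = 50)
  expect_identical(tr$solver$status, "ok")
  expect_equal(tr$states[, "T"], rep(T0, length(tr$times)), tolerance = 1e-6)
  expect_true(all(tr$states[, c("C", "M")] == 0))
})

test_that("positive solutions remain positive and tumor-bounded", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_params()
    init <- c(C = 10^runif(1, 2, 6), T = 10^runif(1, 0, 5),
              M = 10^runif(1, 0, 4))
    tr <- gbm_simulate(p, init = init, times = seq(0, 40, by = 1))
    expect_identical(tr$solver$status, "ok")
    expect_true(all(tr$states >= 0))
    # strict positivity: T and M always (constant activation inflow and
    # bounded death rates); C whenever its exponential decay bound keeps it
    # above the solver's absolute tolerance over the window
    early <- tr$times > 0 & tr$times <= 5
    expect_true(all(tr$states[early, c("T", "M")] > 0))
    if (p[["eta"]] * max(tr$states[, "T"]) * 5 < log(init[1] / 1e-5)) {
      expect_true(all(tr$states[early, "C"] > 0))
    }
    # tumor never exceeds max(C0, C_max)
    expect_lte(max(tr$states[, "C"]),
               max(init[1], p[["C_max"]]) * (1 + 1e-6))
  }
})

test_that("MDSCs respect the asymptotic recruitment/death bound", {
  set.seed(202)
  for (i in 1:25) {
    p <- random_params()
    init <- c(35000, 10, 10)
    b <- population_bounds(p, init)
    t_end <- 50 / p[["d_M"]]
    tr <- gbm_simulate(p, init = init,
                       times = seq(0, t_end, length.out = 201))
    expect_identical(tr$solver$status, "ok")
    m_lim <- (p[["s_M"]] * b$C_hat + p[["alpha"]]) / p[["d_M"]]
    expect_lte(tr$states[nrow(tr$states), "M"], m_lim * (1 + 1e-3))
  }
})

test_that("adaptive solver matches a fine fixed-step RK4 oracle", {
  # default parameter set from the experimental initial condition
  days <- c(5, 10, 20, 40)
  ora <- rk4_solve(default_params(), c(35000, 0, 0), 40, 1e-3, days)
  tr <- gbm_simulate(default_params(), times = c(0, days))
  expect_equal(tr$states[-1, ], ora, tolerance = 1e-4, ignore_attr = TRUE)

  # 20 random (moderately jittered) parameter sets
  set.seed(303)
  for (i in 1:20) {
    p <- jittered_params()
    ora <- rk4_solve(p, c(35000, 0, 0), 20, 1e-3, c(10, 20))
    tr <- gbm_simulate(p, times = c(0, 10, 20))
    expect_equal(tr$states[-1, ], ora, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("population bounds match their defining formulas", {
  p <- default_params()

  # implanting fewer cells than carrying capacity: C_hat = C_max
  b <- population_bounds(p, c(35000, 0, 0))
  expect_identical(b$C_hat, p[["C_max"]])
  # implanting more: C_hat = C(0)
  b2 <- population_bounds(p, c(1e8, 0, 0))
  expect_identical(b2$C_hat, 1e8)

  # rho = a_T = s_T = 1, C_hat = 1 gives T_m = sqrt(2) - 1
  toy <- parameter_set(lambda_C = 1, C_max = 1, eta = 1, a_T = 1, s_T = 1,
                       rho = 1, eps_C = 1, r = 1, d_T = 1, s_M = 1,
                       alpha = 1, q = 1, d_M = 1)
  bt <- population_bounds(toy, c(1, 0, 0))
  expect_equal(bt$T_m, sqrt(2) - 1, tolerance = 1e-12)

  # T_m maximizes g for arbitrary parameters
  set.seed(404)
  for (i in 1:20) {
    p <- random_params()
    b <- population_bounds(p, c(35000, 0, 0))
    delta <- 1e-6 * b$T_m
    expect_gte(b$g(b$T_m), b$g(b$T_m + delta))
    expect_gte(b$g(b$T_m), b$g(b$T_m - delta))
  }
})

test_that("trajectories export to CSV with the documented header", {
  tr <- gbm_simulate(default_params(), times = c(0, 1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_identical(readLines(f, n = 1), "time_days,C,T,M")
  back <- read.csv(f)
  expect_equal(back$C, unname(tr$states[, "C"]))
})
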