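test_that("tumor-free T-cell level solves the cubic", {
  # a_T = d_T = rho = 1: root of T^3 + T - 1 (bisection oracle value)
  p <- parameter_set(lambda_C = 1, C_max = 2, eta = 1, a_T = 1, s_T = 1,
                     rho = 1, eps_C = 1, r = 1, d_T = 1, s_M = 1,
                     alpha = 1, q = 1, d_M = 1)
  eq <- tumor_free_equilibrium(p)
  expect_equal(eq$T0_star, 0.6823278, tolerance = 1e-7)
  expect_lt(eq$residual, 1e-8)

  # vanishing checkpoint: d_T * T = a_T
  v <- unclass(p); v[["a_T"]] <- 3; v[["d_T"]] <- 1.5; v[["rho"]] <- 1e-12
  expect_equal(tumor_free_equilibrium(parameter_set(v))$T0_star, 2,
               tolerance = 1e-6)

  # doubling a_T raises the equilibrium
  v2 <- unclass(p); v2[["a_T"]] <- 2
  expect_gt(tumor_free_equilibrium(parameter_set(v2))$T0_star, eq$T0_star)
})

test_that("closed form agrees with bisection to 10 significant digits", {
  set.seed(11)
  for (i in 1:1000) {
    aT <- 10^runif(1, 0, 7); dT <- 10^runif(1, -2, 0.5)
    rho <- 10^runif(1, -13, 0.5)
    v <- unclass(default_params())
    v[["a_T"]] <- aT; v[["d_T"]] <- dT; v[["rho"]] <- rho
    T0 <- tumor_free_equilibrium(parameter_set(v))$T0_star
    f <- function(T) dT * rho * T^3 + dT * T - aT
    lo <- 0; hi <- aT / dT + 1
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    expect_equal(T0, (lo + hi) / 2, tolerance = 1e-10)
  }
})

test_that("equilibrium level is monotone in a_T, d_T and rho", {
  base <- unclass(default_params())
  t0 <- function(v) tumor_free_equilibrium(parameter_set(v))$T0_star
  grid <- function(name, values) {
    vapply(values, function(x) {
      v <- base; v[[name]] <- x; t0(v)
    }, numeric(1))
  }
  expect_true(all(diff(grid("a_T", 10^seq(2, 6, length.out = 5))) > 0))
  expect_true(all(diff(grid("d_T", 10^seq(-2, 0, length.out = 5))) < 0))
  expect_true(all(diff(grid("rho", 10^seq(-12, 0, length.out = 5))) < 0))
})

test_that("stability classification follows the sign of lambda_C - eta*T0", {
  p <- default_params()
  T0 <- tumor_free_equilibrium(p)$T0_star

  # eta tuned so eta*T0 = 2*lambda_C (approximately; T0 is eta-independent)
  v <- unclass(p); v[["eta"]] <- 2 * v[["lambda_C"]] / T0
  eq_s <- tumor_free_equilibrium(parameter_set(v))
  expect_identical(eq_s$classification, "stable")
  expect_lt(eq_s$eigenvalues[1], 0)

  v2 <- unclass(p); v2[["eta"]] <- 0.5 * v2[["lambda_C"]] / T0
  eq_u <- tumor_free_equilibrium(parameter_set(v2))
  expect_identical(eq_u$classification, "saddle")
  expect_equal(unname(eq_u$eigenvalues[1]),
               v2[["lambda_C"]] - v2[["eta"]] * T0, tolerance = 1e-12)

  # third eigenvalue is always -d_M; second always negative
  set.seed(21)
  for (i in 1:25) {
    pp <- random_params()
    ev <- tumor_free_equilibrium(pp)$eigenvalues
    expect_equal(unname(ev[3]), -pp[["d_M"]])
    expect_lt(ev[2], 0)
  }
})

test_that("linearized prediction matches perturbation simulations", {
  set.seed(31)
  n_checked <- 0
  while (n_checked < 50) {
    p <- random_params()
    eq <- tumor_free_equilibrium(p)
    lam1 <- eq$eigenvalues[1]
    if (abs(lam1) < 1e-3) next  # skip near-marginal cases: growth too slow
    horizon <- min(2 / abs(lam1), 1000)
    # size the tumor perturbation to the linear regime: the slaved T-cell
    # response ~ J21 * C / |lam2| must not shift eta*T by order lam1
    J <- gbm_jacobian(c(0, eq$T0_star, 0), p)
    basin <- abs(lam1) * abs(J[2, 2]) / (p[["eta"]] * abs(J[2, 1]) + 1e-300)
    eps <- min(1e-3 * eq$T0_star, 0.1 * basin)
    if (eps < 1e-200) next
    tr <- gbm_simulate(p, init = c(eps, eq$T0_star, 0),
                       times = seq(0, horizon, length.out = 51),
                       rtol = 1e-10, atol = eps * 1e-6)
    if (tr$solver$status != "ok") next
    grew <- unname(tr$states[nrow(tr$states), "C"] > eps)
    expect_identical(grew, unname(lam1 > 0))
    n_checked <- n_checked + 1
  }
})

test_that("analytic Jacobian matches central differences", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_params()
    st <- c(10^runif(1, 2, 6), 10^runif(1, 1, 5), 10^runif(1, 1, 4))
    J <- gbm_jacobian(st, p)
    Jn <- matrix(NA_real_, 3, 3)
    for (j in 1:3) {
      h <- 1e-6 * st[j]
      e <- c(0, 0, 0); e[j] <- h
      Jn[, j] <- (gbm_rhs(st + e, p) - gbm_rhs(st - e, p)) / (2 * h)
    }
    expect_equal(J, Jn, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

# Parameter set with a weak checkpoint and weak tumor-driven stimulation,
# so the T-cell lower bound beta is macroscopic and the global-stability
# condition can actually be met by a realistic kill rate.
controlled_params <- function(eta = 10) {
  parameter_set(lambda_C = 0.1, C_max = 1e6, eta = eta, a_T = 1e3,
                s_T = 1e-4, rho = 1e-10, eps_C = 1, r = 1e-7, d_T = 0.1,
                s_M = 0.01, alpha = 1e3, q = 1e4, d_M = 0.2)
}

test_that("global-stability condition behaves as a sufficient screen", {
  gs_hold <- global_stability_condition(controlled_params())
  expect_true(gs_hold$condition_holds)
  expect_gt(gs_hold$beta, 0)
  expect_lte(gs_hold$beta,
             gs_hold$gamma / unclass(controlled_params())[["d_T"]])

  # beta does not depend on eta, so the condition is monotone in eta:
  # scaling eta up far enough always turns it on, scaling lambda_C up
  # always turns it off
  p <- default_params()
  gs0 <- global_stability_condition(p)
  expect_false(gs0$condition_holds)
  v <- unclass(p); v[["eta"]] <- 2 * v[["lambda_C"]] / gs0$beta
  gs_big <- global_stability_condition(parameter_set(v))
  expect_equal(gs_big$beta, gs0$beta)
  expect_true(gs_big$condition_holds)
  v2 <- unclass(p); v2[["lambda_C"]] <- v2[["lambda_C"]] * 1e9
  expect_false(global_stability_condition(parameter_set(v2))$condition_holds)

  # global condition implies the local (eigenvalue) condition
  expect_true(tumor_free_equilibrium(parameter_set(v))$lambda1_sign_condition)
  expect_true(tumor_free_equilibrium(controlled_params())$lambda1_sign_condition)
})

test_that("the global condition predicts tumor extinction from any start", {
  p <- controlled_params()
  expect_true(global_stability_condition(p)$condition_holds)
  set.seed(51)
  for (i in 1:10) {
    init <- c(10^runif(1, 2, 7), 10^runif(1, 0, 5), 10^runif(1, 0, 4))
    tr <- gbm_simulate(p, init = init, times = seq(0, 300, by = 10))
    expect_identical(tr$solver$status, "ok")
    expect_lt(tr$states[nrow(tr$states), "C"], 1)
  }
})

test_that("tumorous equilibria are genuine, classified fixed points", {
  p <- default_params()
  te <- tumorous_equilibria(p)
  expect_false(te$existence_screen)  # modes violate C_max*eps_C*eta/lambda_C < 1
  expect_gt(nrow(te$points), 0)
  for (i in seq_len(nrow(te$points))) {
    st <- as.numeric(te$points[i, c("C", "T", "M")])
    expect_lt(sqrt(sum(gbm_rhs(st, p)^2)), 1e-6 * sqrt(sum(st^2)))
  }

  # a stable point attracts a 1% displaced trajectory back within 1%
  stable <- te$points[te$points$classification == "stable", ]
  expect_gt(nrow(stable), 0)
  st <- as.numeric(stable[1, c("C", "T", "M")])
  tr <- gbm_simulate(p, init = 1.01 * st, times = seq(0, 500, by = 10))
  expect_identical(tr$solver$status, "ok")
  expect_equal(as.numeric(tr$states[nrow(tr$states), ]), st, tolerance = 0.01)
})

test_that("a strongly controlled tumor leaves no tumorous equilibrium", {
  v <- unclass(default_params()); v[["eta"]] <- v[["eta"]] * 1e9
  p <- parameter_set(v)
  expect_identical(classify_tumor_free(p), "stable")
  expect_identical(nrow(tumorous_equilibria(p)$points), 0L)
})
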