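#' Tumor-free equilibrium of the GBM-immune model
#'
#' With no tumor (`C = 0`) the MDSC equation forces `M = 0` and the T-cell
#' steady state `T0_star` is the unique positive root of the cubic
#' `f(T) = d_T * rho * T^3 + d_T * T - a_T` (unique by Descartes' rule of
#' signs).  The root is evaluated in a cancellation-free Cardano form and
#' polished with one Newton step; a bracketed `uniroot` solve acts as an
#' internal consistency check.
#'
#' The Jacobian at `(0, T0_star, 0)` is lower triangular in the relevant
#' sense and has eigenvalues
#' `lambda1 = lambda_C - eta * T0_star`,
#' `lambda2 = -2 a_T rho T0_star / (1 + rho T0_star^2)^2 - d_T < 0`,
#' `lambda3 = -d_M < 0`,
#' so stability is decided by the sign of `lambda1` alone.
#'
#' @param params A [parameter_set()].
#' @return List of class `"tumor_free_eq"` with `T0_star`, `residual`
#'   (absolute cubic residual), `eigenvalues` (length 3),
#'   `lambda1_sign_condition` (`lambda_C < eta * T0_star`), and
#'   `classification` (`"stable"`, `"saddle"`, or `"marginal"`).
#' @examples
#' tumor_free_equilibrium(default_params())
#' @export
tumor_free_equilibrium <- function(params) {
  p <- parameter_set(params)
  aT <- p[["a_T"]]; dT <- p[["d_T"]]; rho <- p[["rho"]]

  T0 <- cubic_positive_root(aT, dT, rho)

  f  <- function(T) dT * rho * T^3 + dT * T - aT
  # bracketed verification; [0, a_T/d_T + 1] always brackets the root
  hi <- aT / dT + 1
  T0_num <- stats::uniroot(f, c(0, hi), tol = 1e-12 * hi)$root
  if (abs(T0 - T0_num) > 1e-6 * max(T0, T0_num)) {
    stop(sprintf(
      "closed-form and bracketed roots disagree: %.12g vs %.12g", T0, T0_num))
  }

  D <- 1 + rho * T0^2
  ev <- c(lambda1 = p[["lambda_C"]] - p[["eta"]] * T0,
          lambda2 = -2 * aT * rho * T0 / D^2 - dT,
          lambda3 = -p[["d_M"]])
  cls <- classify_lambda1(p[["lambda_C"]], p[["eta"]] * T0)
  structure(
    list(T0_star = T0, residual = abs(f(T0)), eigenvalues = ev,
         lambda1_sign_condition = p[["lambda_C"]] < p[["eta"]] * T0,
         classification = cls),
    class = "tumor_free_eq"
  )
}

# Unique positive root of d_T*rho*T^3 + d_T*T - a_T = 0, via a Cardano form
# arranged to avoid the catastrophic cancellation that the textbook radical
# suffers when a_T/(2*d_T*rho) is large, then one Newton polish.
cubic_positive_root <- function(aT, dT, rho) {
  u <- aT / (2 * dT * rho)          # half the constant term of t^3 + t/rho = aT/(dT rho)
  m <- (1 / (3 * rho))^3
  A <- u + sqrt(u^2 + m)
  T0 <- A^(1 / 3) - (m / A)^(1 / 3) # exact: product of Cardano radicands is -m
  # one Newton step on f(T) = dT*rho*T^3 + dT*T - aT
  fv <- dT * rho * T0^3 + dT * T0 - aT
  fp <- 3 * dT * rho * T0^2 + dT
  T0 - fv / fp
}

classify_lambda1 <- function(lambda_C, eta_T0) {
  if (abs(lambda_C - eta_T0) < 1e-12 * lambda_C) return("marginal")
  if (lambda_C < eta_T0) "stable" else "saddle"
}

#' @export
print.tumor_free_eq <- function(x, ...) {
  cat(sprintf("Tumor-free equilibrium (0, %.6g, 0): %s\n", x$T0_star,
              x$classification))
  cat(sprintf("eigenvalues: %.4g, %.4g, %.4g\n",
              x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  invisible(x)
}

#' Classify the tumor-free equilibrium
#'
#' Locally asymptotically stable when the tumor growth rate is below the
#' initial immune kill pressure (`lambda_C < eta * T0_star`), a saddle when
#' above; near-equality (within 1e-12 relative) is reported as `"marginal"`.
#'
#' @param params A [parameter_set()].
#' @return `"stable"`, `"saddle"`, or `"marginal"`.
#' @export
classify_tumor_free <- function(params) {
  tumor_free_equilibrium(params)$classification
}

#' Sufficient condition for global stability of the tumor-free equilibrium
#'
#' Using the a priori population bounds, the T-cell population is bounded
#' below asymptotically by `beta = gamma / (r * M_hat + d_T)` with
#' `gamma = a_T / (1 + rho * T_hat * (T_hat + eps_C * C_hat))`.  When
#' `lambda_C < eta * beta`, T-cell pressure exceeds tumor growth from any
#' positive initial state and the tumor is driven extinct regardless of
#' initial size.
#'
#' @param params A [parameter_set()].
#' @param init Initial state (enters through the bounds).
#' @return List of class `"global_stability"` with `gamma`, `beta`,
#'   `condition_holds`, and `bounds_used`.
#' @export
global_stability_condition <- function(params, init = default_init()) {
  p <- parameter_set(params)
  b <- population_bounds(p, init)
  gamma <- p[["a_T"]] /
    (1 + p[["rho"]] * b$T_hat * (b$T_hat + p[["eps_C"]] * b$C_hat))
  beta <- gamma / (p[["r"]] * b$M_hat + p[["d_T"]])
  structure(
    list(gamma = gamma, beta = beta,
         condition_holds = p[["lambda_C"]] < p[["eta"]] * beta,
         bounds_used = b),
    class = "global_stability"
  )
}

#' @export
print.global_stability <- function(x, ...) {
  cat(sprintf("Global-stability screen: beta = %.4g, condition %s\n",
              x$beta, if (x$condition_holds) "HOLDS (tumor-free globally stable)"
              else "does not hold"))
  invisible(x)
}

#' Analytic Jacobian of the model
#'
#' Hand-differentiated Jacobian of [gbm_rhs()] at an arbitrary state, used
#' for eigenvalue classification of fixed points.  Cross-checked against a
#' central-difference Jacobian in the test suite.
#'
#' @param state Numeric `(C, T, M)`.
#' @param params A [parameter_set()].
#' @return 3x3 numeric matrix.
#' @export
gbm_jacobian <- function(state, params) {
  p <- parameter_set(params)
  C <- state[1]; Tc <- state[2]; M <- state[3]
  lam <- p[["lambda_C"]]; Cm <- p[["C_max"]]; eta <- p[["eta"]]
  aT <- p[["a_T"]]; sT <- p[["s_T"]]; rho <- p[["rho"]]; eC <- p[["eps_C"]]
  r <- p[["r"]]; dT <- p[["d_T"]]; sM <- p[["s_M"]]; al <- p[["alpha"]]
  q <- p[["q"]]; dM <- p[["d_M"]]
  N <- aT + sT * Tc * C
  D <- 1 + rho * Tc * (Tc + eC * C)
  matrix(c(
    lam * (1 - 2 * C / Cm) - eta * Tc, -eta * C, 0,
    sT * Tc / D - N * rho * eC * Tc / D^2,
    sT * C / D - N * (2 * rho * Tc + rho * eC * C) / D^2 - r * M - dT,
    -r * Tc,
    sM + al * q / (q + C)^2, 0, -dM
  ), nrow = 3, byrow = TRUE)
}

#' Numerically locate tumorous equilibria
#'
#' A fixed point with `C* > 0` must satisfy the nullclines
#' `T* = lambda_C * (1 - C*/C_max) / eta` (from the tumor equation) and
#' `M* = (s_M * C* + alpha * C* / (q + C*)) / d_M` (from the MDSC
#' equation); substituting both into the T-cell equation leaves one scalar
#' equation in `C*`, which is scanned for sign changes on a log-spaced grid
#' over `(0, C_max]` and solved by bracketed root finding.  Each point is
#' classified by the eigenvalues of the analytic Jacobian.  The reported
#' `existence_screen` is the sufficient-condition flag
#' `C_max * eps_C * eta / lambda_C < 1` (used only as a report, never to
#' skip the numeric search).
#'
#' @param params A [parameter_set()].
#' @param n_grid Number of log-spaced scan points (default 2000).
#' @param c_min Lower end of the scan grid in cells (default 1e-3).
#' @return List of class `"tumorous_eq"` with `points` (data frame with
#'   `C`, `T`, `M`, `residual`, `classification`, and eigenvalue columns)
#'   and `existence_screen`.
#' @export
tumorous_equilibria <- function(params, n_grid = 2000, c_min = 1e-3) {
  p <- parameter_set(params)
  lam <- p[["lambda_C"]]; Cm <- p[["C_max"]]; eta <- p[["eta"]]

  T_of_C <- function(C) lam * (1 - C / Cm) / eta
  M_of_C <- function(C) (p[["s_M"]] * C + p[["alpha"]] * C / (p[["q"]] + C)) /
    p[["d_M"]]
  h <- function(C) {
    Tc <- T_of_C(C); M <- M_of_C(C)
    (p[["a_T"]] + p[["s_T"]] * Tc * C) /
      (1 + p[["rho"]] * Tc * (Tc + p[["eps_C"]] * C)) -
      p[["r"]] * Tc * M - p[["d_T"]] * Tc
  }

  grid <- exp(seq(log(c_min), log(Cm), length.out = n_grid))
  hv <- vapply(grid, h, numeric(1))
  sgn <- sign(hv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)

  roots <- vapply(idx, function(i) {
    stats::uniroot(h, c(grid[i], grid[i + 1]), tol = 1e-12 * Cm)$root
  }, numeric(1))
  # exact zeros on the grid (rare but possible)
  roots <- sort(unique(c(roots, grid[hv == 0])))

  pts <- lapply(roots, function(Cs) {
    st <- c(Cs, T_of_C(Cs), M_of_C(Cs))
    if (st[2] < 0) return(NULL)    # beyond carrying capacity: not biological
    res <- gbm_rhs(st, p)
    ev <- eigen(gbm_jacobian(st, p), only.values = TRUE)$values
    re <- Re(ev)
    cls <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
    data.frame(C = st[1], T = st[2], M = st[3],
               residual = sqrt(sum(res^2)),
               eig1 = re[1], eig2 = re[2], eig3 = re[3],
               classification = cls, stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) {
    pts <- data.frame(C = numeric(0), T = numeric(0), M = numeric(0),
                      residual = numeric(0), eig1 = numeric(0),
                      eig2 = numeric(0), eig3 = numeric(0),
                      classification = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(points = pts,
         existence_screen = Cm * p[["eps_C"]] * eta / lam < 1,
         params = p),
    class = "tumorous_eq"
  )
}

#' @export
print.tumorous_eq <- function(x, ...) {
  cat(sprintf("Tumorous equilibria: %d point(s); existence screen %s\n",
              nrow(x$points),
              if (x$existence_screen) "satisfied" else "not satisfied"))
  if (nrow(x$points)) print(x$points, digits = 4)
  invisible(x)
}
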