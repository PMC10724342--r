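#' Right-hand side of the GBM-immune ODE system
#'
#' Evaluates the instantaneous rates of change of the three populations:
#' tumor cells `C` grow logistically toward `C_max` and are killed by T
#' cells; activated T cells `T` are activated at a constant rate and
#' stimulated by tumor contact, with both terms damped by the PD-L1-PD-1
#' checkpoint factor `1 / (1 + rho * T * (T + eps_C * C))`, and are lost to
#' MDSC suppression and natural death; MDSCs `M` are recruited by
#' tumor-secreted chemokines (CCL2/CCL7), expand saturably with tumor load,
#' and die at rate `d_M`.
#'
#' @param state Numeric vector `(C, T, M)`, components >= 0 (cells).
#' @param params A [parameter_set()] (or coercible named vector).
#' @return Named numeric vector `(dC, dT, dM)` in cells/day.
#' @examples
#' gbm_rhs(c(C = 0, T = 0, M = 0), default_params())  # (0, a_T, 0)
#' @export
gbm_rhs <- function(state, params) {
  p <- as.numeric(parameter_set(params))
  names(p) <- param_names()
  s <- unname(as.numeric(state))
  if (length(s) != 3L || any(!is.finite(s))) {
    stop("state must be 3 finite values (C, T, M)")
  }
  C <- s[1]; Tc <- s[2]; M <- s[3]
  checkpoint <- 1 + p[["rho"]] * Tc * (Tc + p[["eps_C"]] * C)
  c(
    dC = p[["lambda_C"]] * C * (1 - C / p[["C_max"]]) - p[["eta"]] * Tc * C,
    dT = (p[["a_T"]] + p[["s_T"]] * Tc * C) / checkpoint -
      p[["r"]] * Tc * M - p[["d_T"]] * Tc,
    dM = p[["s_M"]] * C + p[["alpha"]] * C / (p[["q"]] + C) - p[["d_M"]] * M
  )
}

#' Default initial condition: 35,000 implanted glioma cells
#'
#' Mirrors the experimental protocol of orthotopic implantation of 35,000
#' glioma cells into a naive brain: no activated T cells and no MDSCs at
#' day 0.
#'
#' @return Named numeric vector `(C, T, M)`.
#' @export
default_init <- function() c(C = 35000, T = 0, M = 0)

#' Simulate the GBM-immune model
#'
#' Solves the three-population system with an adaptive-step solver
#' (`deSolve::lsoda`, which switches automatically between stiff and
#' non-stiff integrators) using the compiled right-hand side.  Small
#' negative excursions within the absolute tolerance are clamped to zero;
#' larger ones, or solver non-convergence, mark the trajectory as failed
#' (callers such as the ABC distance treat failed solves as infinite error).
#'
#' @param params A [parameter_set()].
#' @param init Initial state `(C, T, M)`, components >= 0.
#'   Default [default_init()].
#' @param t_end Final time in days (ignored when `times` is given).
#' @param times Optional explicit output grid (days, strictly increasing,
#'   starting at 0).  Default: hourly from 0 to `t_end`.
#' @param rtol,atol Solver tolerances (relative; absolute in cells).
#' @return Object of class `"gbm_trajectory"`: list with `times`, `states`
#'   (matrix with columns C, T, M), `params`, and `solver` (status report).
#' @examples
#' tr <- gbm_simulate(default_params(), t_end = 34)
#' tail(tr$states)
#' @export
gbm_simulate <- function(params, init = default_init(), t_end = 40,
                         times = NULL, rtol = 1e-8, atol = 1e-6) {
  p <- parameter_set(params)
  init <- as.numeric(init)
  if (length(init) != 3L || any(!is.finite(init)) || any(init < 0)) {
    stop("init must be 3 finite non-negative values (C, T, M)")
  }
  if (is.null(times)) {
    if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
    times <- seq(0, t_end, by = 1 / 24)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  raw <- solve_raw(as.numeric(p), init, times, rtol, atol)
  finish_trajectory(raw, times, p, rtol, atol)
}

# Bare deSolve call against the compiled rhs; returns the ode() matrix or NULL.
solve_raw <- function(pvec, init, times, rtol, atol) {
  out <- try(suppressWarnings(
    deSolve::ode(y = init, times = times, func = "gbm_derivs",
                 parms = pvec, dllname = "gbmimmune",
                 initfunc = "gbm_initmod", rtol = rtol, atol = atol,
                 maxsteps = 20000)
  ), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  out
}

finish_trajectory <- function(out, times, params, rtol, atol) {
  status <- "ok"
  message <- ""
  if (is.null(out) || nrow(out) < length(times) || anyNA(out)) {
    status <- "failed"
    message <- "solver did not reach the end of the requested grid"
    states <- matrix(NA_real_, length(times), 3,
                     dimnames = list(NULL, c("C", "T", "M")))
  } else {
    states <- unname(out[, 2:4, drop = FALSE])
    colnames(states) <- c("C", "T", "M")
    low <- min(states)
    # local truncation error is controlled per step, not globally, so the
    # clamp window is a small multiple of the absolute tolerance
    if (low < -100 * atol) {
      status <- "failed"
      message <- sprintf("negative excursion beyond tolerance (min = %.3g)", low)
    } else if (low < 0) {
      states[states < 0] <- 0
    }
  }
  structure(
    list(times = times, states = states, params = params,
         solver = list(status = status, message = message,
                       rtol = rtol, atol = atol)),
    class = "gbm_trajectory"
  )
}

#' @export
print.gbm_trajectory <- function(x, ...) {
  cat(sprintf("GBM-immune trajectory: %d time points over [%g, %g] days (%s)\n",
              length(x$times), min(x$times), max(x$times), x$solver$status))
  if (x$solver$status == "ok") {
    fin <- x$states[nrow(x$states), ]
    cat(sprintf("final state: C = %.4g, T = %.4g, M = %.4g cells\n",
                fin[1], fin[2], fin[3]))
  }
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `gbm_trajectory`.
#' @param path Output file; header `time_days,C,T,M`.
#' @export
write_trajectory <- function(trajectory, path) {
  d <- data.frame(time_days = trajectory$times,
                  C = trajectory$states[, "C"],
                  T = trajectory$states[, "T"],
                  M = trajectory$states[, "M"])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analytic a priori bounds on the three populations
#'
#' Computes the componentwise upper bounds guaranteed for trajectories with
#' non-negative initial data:
#' `C_hat = max(C0, C_max)` (logistic comparison), `T_hat = max(T0,
#' g(T_m) / d_T)` where `g(T) = (a_T + s_T * T * C_hat) / (1 + rho * T^2)`
#' attains its maximum at `T_m`, and `M_hat = max(M0, (s_M * C_hat +
#' alpha) / d_M)`.  These bounds feed the global-stability condition of
#' [global_stability_condition()].
#'
#' @param params A [parameter_set()].
#' @param init Initial state `(C, T, M)`.
#' @return List of class `"bound_set"` with `C_hat`, `T_hat`, `M_hat`, `T_m`
#'   and the bounding function `g`.
#' @export
population_bounds <- function(params, init = default_init()) {
  p <- parameter_set(params)
  init <- as.numeric(init)
  if (length(init) != 3L || any(init < 0)) stop("init must be (C,T,M) >= 0")
  C_hat <- max(init[1], p[["C_max"]])
  aT <- p[["a_T"]]; sT <- p[["s_T"]]; rho <- p[["rho"]]
  sC <- sT * C_hat
  T_m <- sqrt(rho * (rho * aT^2 + sC^2)) / (rho * sC) - aT / sC
  g <- function(T) (aT + sC * T) / (1 + rho * T^2)
  T_hat <- max(init[2], g(T_m) / p[["d_T"]])
  M_hat <- max(init[3], (p[["s_M"]] * C_hat + p[["alpha"]]) / p[["d_M"]])
  structure(list(C_hat = C_hat, T_hat = T_hat, M_hat = M_hat,
                 T_m = T_m, g = g),
            class = "bound_set")
}

#' @export
print.bound_set <- function(x, ...) {
  cat(sprintf("Population bounds: C_hat = %.4g, T_hat = %.4g, M_hat = %.4g (T_m = %.4g)\n",
              x$C_hat, x$T_hat, x$M_hat, x$T_m))
  invisible(x)
}
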