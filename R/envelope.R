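#' Posterior-predictive envelope of the cell-count trajectories
#'
#' Samples `n_draws` parameter sets from a posterior source, simulates each
#' from 35,000 implanted glioma cells, and records the across-draw mean and
#' standard deviation of each population at every output time (hourly by
#' default).  Each observed data point is then classified by its distance
#' to the envelope mean in units of the envelope SD at its day, and the
#' number of points falling within `sigma/4`, `sigma/2`, `3*sigma/4` and
#' `sigma` of the mean is reported.
#'
#' @param source Where parameter draws come from: an `abc_result`
#'   (posterior subset resampled with replacement), a numeric matrix of
#'   draws (rows resampled), a data frame of per-parameter families
#'   (e.g. [reference_posterior()]), or a list of `fitted_distribution`
#'   objects from [fit_posterior_families()].
#' @param data An `observed_data` data frame (for the coverage counts).
#' @param n_draws Number of simulations (default 10000).
#' @param t_end End of the hourly grid in days; default covers the last
#'   observation day.
#' @param grid_step Output step in days (default 1 hour).
#' @param seed Integer seed.
#' @param max_fail_frac Abort if more than this fraction of draws fails to
#'   solve (default 0.05).
#' @return List of class `"envelope_report"`: `times`, `mean` and `sd`
#'   (times x 3 matrices), `coverage` (data frame with counts per band),
#'   `points` (per data point: day, population, count, z), `n_draws`,
#'   `n_failed`.
#' @export
posterior_predictive_envelope <- function(source, data, n_draws = 10000,
                                          t_end = NULL, grid_step = 1 / 24,
                                          seed = 1, max_fail_frac = 0.05) {
  validate_observed(data)
  if (is.null(t_end)) t_end <- max(data$day)
  if (t_end < max(data$day)) stop("t_end must cover the last observation day")
  set.seed(seed)
  draws <- envelope_draws(source, n_draws)
  times <- seq(0, t_end, by = grid_step)

  nt <- length(times)
  sum1 <- matrix(0, nt, 3)
  sum2 <- matrix(0, nt, 3)
  n_ok <- 0L
  for (i in seq_len(nrow(draws))) {
    out <- solve_raw(draws[i, ], default_init(), times, 1e-8, 1e-6)
    if (is.null(out) || nrow(out) < nt || anyNA(out)) next
    s <- out[, 2:4, drop = FALSE]
    sum1 <- sum1 + s
    sum2 <- sum2 + s * s
    n_ok <- n_ok + 1L
  }
  n_failed <- nrow(draws) - n_ok
  if (n_failed > max_fail_frac * nrow(draws)) {
    stop(sprintf("%d of %d envelope simulations failed (limit %.0f%%)",
                 n_failed, nrow(draws), 100 * max_fail_frac))
  }
  mu <- sum1 / n_ok
  va <- pmax(sum2 / n_ok - mu^2, 0) * n_ok / max(n_ok - 1, 1)
  va[va < 1e-12 * mu^2] <- 0   # round-off from the one-pass moment formula
  sd <- sqrt(va)
  colnames(mu) <- colnames(sd) <- c("C", "T", "M")

  pts <- data[, c("day", "population", "count")]
  ti <- vapply(pts$day, function(d) which.min(abs(times - d)), integer(1))
  pj <- match(pts$population, c("C", "T", "M"))
  mu_at <- mu[cbind(ti, pj)]
  sd_at <- sd[cbind(ti, pj)]
  # a zero-width envelope covers only points on the trajectory itself
  # (up to solver tolerance)
  z <- ifelse(sd_at > 0, abs(pts$count - mu_at) / sd_at,
              ifelse(abs(pts$count - mu_at) <= 1e-6 * pmax(mu_at, 1), 0, Inf))
  pts$z <- z
  bands <- c(0.25, 0.5, 0.75, 1)
  coverage <- data.frame(
    band = c("sigma/4", "sigma/2", "3sigma/4", "sigma"),
    width = bands,
    count = vapply(bands, function(b) sum(z <= b), integer(1)),
    total = nrow(pts)
  )
  structure(
    list(times = times, mean = mu, sd = sd, coverage = coverage,
         points = pts, n_draws = nrow(draws), n_failed = n_failed),
    class = "envelope_report"
  )
}

envelope_draws <- function(source, n_draws) {
  if (inherits(source, "abc_result")) {
    if (nrow(source$posterior) == 0) stop("empty posterior in abc_result")
    source <- source$posterior
  }
  if (is.matrix(source)) {
    return(source[sample.int(nrow(source), n_draws, replace = TRUE), ,
                  drop = FALSE])
  }
  sample_from_families(n_draws, spec = source)
}

#' @export
print.envelope_report <- function(x, ...) {
  cat(sprintf("Posterior-predictive envelope: %d draws (%d failed), %d time points\n",
              x$n_draws, x$n_failed, length(x$times)))
  print(x$coverage, row.names = FALSE)
  invisible(x)
}

#' Relative errors of a single parameter set against observed data
#'
#' Simulates the model for one parameter set and evaluates the
#' per-population relative errors against the chosen per-day data statistic
#' (mean, min, or max), as used to score the best-fit parameter sets of the
#' three ABC trials.
#'
#' @param params A [parameter_set()].
#' @param data An `observed_data` data frame.
#' @param stat Per-day statistic: `"mean"` (default), `"min"`, `"max"`.
#' @param init Initial state (default 35,000 implanted glioma cells).
#' @return Named vector `(E_C, E_T, E_M, E_total)`; all `Inf` if the solve
#'   fails.
#' @export
best_fit_error <- function(params, data, stat = "mean",
                           init = default_init()) {
  p <- parameter_set(params)
  tgt <- observed_target(data, stat)
  tr <- gbm_simulate(p, init = init, times = c(0, tgt$days))
  if (tr$solver$status != "ok") {
    return(c(E_C = Inf, E_T = Inf, E_M = Inf, E_total = Inf))
  }
  x <- tr$states[match(tgt$days, tr$times), , drop = FALSE]
  e <- vapply(1:3, function(k) relative_error(tgt$target[, k], x[, k]),
              numeric(1))
  c(E_C = e[1], E_T = e[2], E_M = e[3], E_total = sum(e))
}

#' Minimal-error parameter set of an ABC run under an alternate statistic
#'
#' Re-scores the stored simulations of an ABC run against the per-day mean,
#' minimum, or maximum data statistic and returns the draw with the
#' smallest total relative error (the "best fit" of that trial).
#'
#' @param abc An `abc_result` created with `keep_sims = TRUE`.
#' @param data The `observed_data` the run was fitted to.
#' @param stat `"mean"`, `"min"`, or `"max"`.
#' @return List with `params` (the best draw), `errors`
#'   (`E_C`, `E_T`, `E_M`, `E_total`), and `index`.
#' @export
abc_best_fit <- function(abc, data, stat = "mean") {
  if (is.null(abc$sims)) {
    stop("abc_best_fit needs an abc_result built with keep_sims = TRUE")
  }
  tgt <- observed_target(data, stat)
  E <- abc_errors(abc$sims, tgt$target)
  i <- which.min(E[, "E_total"])
  list(params = parameter_set(abc$draws[i, ]),
       errors = E[i, ], index = i)
}
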