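# Independent numerical oracles and random-case generators for the suite.
# Everything here deliberately avoids the package's solver path: the rhs is
# re-written inline and integrated with a hand-rolled fixed-step RK4.

# Bare-arithmetic rhs (no validation, no deSolve) for the oracle integrator.
oracle_rhs <- function(y, p) {
  C <- y[1]; Tc <- y[2]; M <- y[3]
  D <- 1 + p[6] * Tc * (Tc + p[7] * C)
  c(p[1] * C * (1 - C / p[2]) - p[3] * Tc * C,
    (p[4] + p[5] * Tc * C) / D - p[8] * Tc * M - p[9] * Tc,
    p[10] * C + p[11] * C / (p[12] + C) - p[13] * M)
}

# Classical fixed-step RK4 on [0, t_end], reporting states at `report` times
# (which must be multiples of dt).
rk4_solve <- function(p, y0, t_end, dt, report) {
  p <- as.numeric(p)
  y <- as.numeric(y0)
  n_steps <- round(t_end / dt)
  report_steps <- round(report / dt)
  out <- matrix(NA_real_, length(report), 3)
  hit <- match(0L, report_steps)
  if (!is.na(hit)) out[hit, ] <- y
  for (k in seq_len(n_steps)) {
    k1 <- oracle_rhs(y, p)
    k2 <- oracle_rhs(y + dt / 2 * k1, p)
    k3 <- oracle_rhs(y + dt / 2 * k2, p)
    k4 <- oracle_rhs(y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- match(k, report_steps)
    if (!is.na(hit)) out[hit, ] <- y
  }
  out
}

# Random valid parameter set drawn log-uniformly within the default prior
# box (positive lower bounds enforced for s_M via a floor).
random_params <- function() {
  pr <- default_priors()
  lo <- pmax(pr$lower, pr$upper * 1e-6)
  v <- exp(stats::runif(13, log(lo), log(pr$upper)))
  names(v) <- pr$parameter
  parameter_set(v)
}

# Mildly jittered copy of the default parameter set (factor 0.5-2 per
# component); stays in a regime where a fixed-step integrator is stable.
jittered_params <- function() {
  v <- unclass(default_params()) * exp(stats::runif(13, log(0.5), log(2)))
  parameter_set(v)
}

# Shared small synthetic dataset (mode truth, CV 0.2), built once per run.
fixture_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_observed(noise_cv = 0.2, seed = 42)
    cache
  }
})
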