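#' Mean relative error between data and simulation
#'
#' The ABC distance for one population: `mean(|d_i - x_i| / d_i)` over the
#' observation days, where `d_i` is the per-day data statistic (mean by
#' default; min or max in the alternate trials) and `x_i` the simulated
#' count.
#'
#' @param data_means Positive per-day data values.
#' @param sim_values Simulated values on the same days.
#' @return Dimensionless non-negative error.
#' @examples
#' relative_error(c(100, 200), c(110, 180))  # 0.1
#' @export
relative_error <- function(data_means, sim_values) {
  if (length(data_means) != length(sim_values) || length(data_means) < 1L) {
    stop("data and simulation vectors must have equal positive length")
  }
  if (any(!is.finite(data_means)) || any(data_means <= 0)) {
    stop("data values must be positive and finite")
  }
  if (any(!is.finite(sim_values))) return(Inf)
  mean(abs(data_means - sim_values) / data_means)
}

# Per-day data statistic matrix (days x populations C,T,M) for a chosen stat.
observed_target <- function(data, stat = c("mean", "min", "max")) {
  stat <- match.arg(stat)
  st <- observed_stats(data)
  days <- sort(unique(st$day))
  m <- sapply(c("C", "T", "M"), function(pop) {
    sub <- st[st$population == pop, ]
    sub[[stat]][match(days, sub$day)]
  })
  if (anyNA(m)) stop("every population needs a value at every observation day")
  list(days = days, target = m)
}

#' Draw uniform prior samples
#'
#' @param priors Data frame with columns `parameter`, `lower`, `upper`
#'   (default [default_priors()]).
#' @param n Number of draws.
#' @return `n` x 13 matrix, columns in [param_names()] order.
#' @export
sample_priors <- function(priors = default_priors(), n) {
  priors <- priors[match(param_names(), priors$parameter), ]
  if (anyNA(priors$parameter)) stop("priors must cover all 13 parameters")
  if (any(priors$lower >= priors$upper)) stop("prior lower bounds must be < upper")
  m <- sapply(seq_len(13), function(j) {
    stats::runif(n, priors$lower[j], priors$upper[j])
  })
  if (n == 1L) m <- matrix(m, nrow = 1)
  colnames(m) <- param_names()
  m
}

# Simulate a matrix of parameter draws at the observation days.
# Returns an n x days x 3 array; failed solves yield NA slices.
simulate_draws_at_days <- function(draws, days, init = default_init(),
                                   rtol = 1e-8, atol = 1e-6) {
  n <- nrow(draws)
  times <- c(0, days)
  sims <- array(NA_real_, dim = c(n, length(days), 3),
                dimnames = list(NULL, NULL, c("C", "T", "M")))
  for (i in seq_len(n)) {
    out <- solve_raw(draws[i, ], init, times, rtol, atol)
    if (!is.null(out) && nrow(out) == length(times) && !anyNA(out)) {
      sims[i, , ] <- out[-1, 2:4]
    }
  }
  sims
}

#' ABC rejection sampling against longitudinal cell-count data
#'
#' Draws `n_samples` parameter sets i.i.d. uniform from the prior bounds,
#' simulates each from 35,000 implanted glioma cells, and computes the
#' per-population relative errors `E_C`, `E_T`, `E_M` against the per-day
#' data statistic.  A draw is accepted iff `E_C <= R_C`, `E_T <= R_T` and
#' `E_M <= R_M` simultaneously (boundary equality accepts); failed solves
#' score infinite error and are never accepted.  The reported posterior is
#' the smallest 25% of accepted draws by total error `E_total = E_C + E_T +
#' E_M` (ceiling size, ties broken by draw index), with per-parameter
#' summary statistics.
#'
#' @param data An `observed_data` data frame covering the observation days.
#' @param priors Prior bounds data frame (default [default_priors()]).
#' @param n_samples Number of prior draws.
#' @param thresholds Named vector `c(R_C=, R_T=, R_M=)`;
#'   defaults `(0.75, 0.72, 0.78)`.
#' @param stat Per-day data statistic used as `d_i`: `"mean"` (default),
#'   `"min"`, or `"max"`.
#' @param posterior_fraction Fraction of accepted draws (smallest by
#'   `E_total`) kept as the posterior subset; default 0.25.
#' @param seed Integer seed; all draws are generated up front from this
#'   single seed, so results are reproducible.
#' @param keep_sims Keep the simulated day values (n x days x 3 array)?
#'   Default FALSE.
#' @return List of class `"abc_result"`: `draws`, `errors` (matrix with
#'   columns E_C, E_T, E_M, E_total), `accepted` (logical), `posterior`
#'   (matrix of posterior-subset draws), `posterior_index`, `summaries`
#'   (per-parameter mean/median/mode/sd), `thresholds`, `acceptance_rate`,
#'   `n_failed`, and optionally `sims`.
#' @export
abc_rejection <- function(data, priors = default_priors(), n_samples,
                          thresholds = c(R_C = 0.75, R_T = 0.72, R_M = 0.78),
                          stat = "mean", posterior_fraction = 0.25,
                          seed = 1, keep_sims = FALSE) {
  stopifnot(n_samples >= 1)
  tgt <- observed_target(data, stat)
  set.seed(seed)
  draws <- sample_priors(priors, n_samples)
  sims <- simulate_draws_at_days(draws, tgt$days)
  errors <- abc_errors(sims, tgt$target)
  res <- abc_collect(draws, errors, thresholds, posterior_fraction)
  res$stat <- stat
  res$days <- tgt$days
  if (keep_sims) res$sims <- sims
  res
}

# Relative errors per draw from a sims array and a days x 3 target matrix.
abc_errors <- function(sims, target) {
  n <- dim(sims)[1]
  E <- matrix(Inf, n, 4, dimnames = list(NULL, c("E_C", "E_T", "E_M", "E_total")))
  for (k in 1:3) {
    dk <- target[, k]
    ek <- sweep(abs(sweep(sims[, , k, drop = FALSE][, , 1, drop = TRUE]
                          , 2, dk)), 2, dk, "/")
    if (is.null(dim(ek))) ek <- matrix(ek, nrow = n)
    E[, k] <- rowMeans(ek)
  }
  E[!is.finite(E)] <- Inf
  E[, 4] <- E[, 1] + E[, 2] + E[, 3]
  E
}

abc_collect <- function(draws, errors, thresholds, posterior_fraction) {
  acc <- errors[, "E_C"] <= thresholds[["R_C"]] &
    errors[, "E_T"] <= thresholds[["R_T"]] &
    errors[, "E_M"] <= thresholds[["R_M"]]
  acc[is.na(acc)] <- FALSE
  idx_acc <- which(acc)
  status <- "ok"
  if (length(idx_acc) == 0L) {
    warning("ABC rejection accepted zero draws")
    status <- "empty"
    post_idx <- integer(0)
  } else {
    k <- ceiling(posterior_fraction * length(idx_acc))
    ord <- idx_acc[order(errors[idx_acc, "E_total"])]  # stable: ties by index
    post_idx <- ord[seq_len(k)]
  }
  posterior <- draws[post_idx, , drop = FALSE]
  summaries <- if (length(post_idx) >= 10) {
    do.call(rbind, lapply(param_names(), function(nm) {
      s <- posterior_summaries(posterior[, nm])
      data.frame(parameter = nm, mean = s[["mean"]], median = s[["median"]],
                 mode = s[["mode"]], sd = s[["sd"]], stringsAsFactors = FALSE)
    }))
  } else NULL
  structure(
    list(n_sampled = nrow(draws), draws = draws, errors = errors,
         accepted = acc, thresholds = thresholds,
         acceptance_rate = mean(acc), n_failed = sum(!is.finite(errors[, 4])),
         posterior = posterior, posterior_index = post_idx,
         posterior_fraction = posterior_fraction,
         summaries = summaries, status = status),
    class = "abc_result"
  )
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC rejection: %d draws, %d accepted (%.2f%%), %d failed solves\n",
              x$n_sampled, sum(x$accepted), 100 * x$acceptance_rate, x$n_failed))
  cat(sprintf("posterior subset: smallest %.0f%% of accepted = %d draws\n",
              100 * x$posterior_fraction, nrow(x$posterior)))
  if (!is.null(x$summaries)) print(x$summaries, digits = 3)
  invisible(x)
}

#' Summary statistics of a posterior sample
#'
#' Mean, median, sample SD, and a mode estimate from a Gaussian kernel
#' density (Silverman's bandwidth).  For strictly positive samples spanning
#' two or more decades the density is estimated on the log10 scale (the
#' right-skewed marginals typical of rate parameters), otherwise on the
#' linear scale.
#'
#' @param x Numeric sample, at least 10 values.
#' @return Named vector `(mean, median, mode, sd)`.
#' @export
posterior_summaries <- function(x) {
  if (length(x) < 10) stop("need at least 10 samples for posterior summaries")
  if (stats::sd(x) == 0) {
    return(c(mean = x[1], median = x[1], mode = x[1], sd = 0))
  }
  wide <- min(x) > 0 && max(x) / min(x) >= 100
  if (wide) {
    d <- stats::density(log10(x), bw = "nrd0", n = 1024)
    mode <- 10^d$x[which.max(d$y)]
  } else {
    d <- stats::density(x, bw = "nrd0", n = 1024)
    mode <- d$x[which.max(d$y)]
  }
  c(mean = mean(x), median = stats::median(x), mode = mode, sd = stats::sd(x))
}
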