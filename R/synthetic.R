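#' Generate a synthetic murine-style cell-count dataset
#'
#' Emulates the structure of the longitudinal murine glioma experiment:
#' 35,000 glioma cells implanted at day 0, and at each observation day
#' (defaults 7, 13, 20, 24, 27, 34 days post-implantation) a small cohort of
#' mice (1-4) euthanized and their tumor-cell, CD3+ T-cell and MDSC counts
#' recorded.  Each mouse's count is the ground-truth ODE trajectory value
#' multiplied by lognormal noise with a chosen coefficient of variation
#' (cell counts are positive and right-skewed; the true within-day noise
#' structure of such data is unknown, so the CV is an explicit knob).
#'
#' @param true_params Ground-truth [parameter_set()] (default:
#'   [default_params()]).
#' @param init Initial state, default 35,000 implanted glioma cells.
#' @param days Integer observation days.
#' @param mice_per_day Mice euthanized per day (each in 1..4, recycled to
#'   `length(days)`).  Default 2 per day, giving the 36 data points
#'   (6 days x 2 mice x 3 populations) of the reference experiment.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (>= 0; 0 reproduces the trajectory exactly).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param cohort_check Enforce the experimental 1-4 mice per day (default
#'   TRUE; disable for large in-silico cohorts, e.g. noise calibration).
#' @return Data frame of class `"observed_data"` with columns
#'   `day`, `mouse_id`, `population` (one of `"C"`, `"T"`, `"M"`), `count`.
#' @examples
#' d <- generate_observed(noise_cv = 0.2, seed = 1)
#' head(d)
#' @export
generate_observed <- function(true_params = default_params(),
                              init = default_init(),
                              days = c(7, 13, 20, 24, 27, 34),
                              mice_per_day = 2,
                              noise_cv = 0.2, seed = 1, cohort_check = TRUE) {
  p <- parameter_set(true_params)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  mice_per_day <- rep_len(mice_per_day, length(days))
  if (any(mice_per_day < 1)) stop("mice_per_day must be >= 1")
  if (cohort_check && any(mice_per_day > 4)) {
    stop("mice_per_day must be within 1..4 (set cohort_check = FALSE to override)")
  }
  tr <- gbm_simulate(p, init = init, times = c(0, days))
  if (tr$solver$status != "ok") {
    stop("ground-truth trajectory failed to solve for the given parameters")
  }
  truth <- tr$states[match(days, tr$times), , drop = FALSE]

  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  mouse <- 0L
  for (i in seq_along(days)) {
    for (m in seq_len(mice_per_day[i])) {
      mouse <- mouse + 1L
      noise <- if (noise_cv == 0) rep(1, 3) else
        stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        day = as.integer(days[i]),
        mouse_id = sprintf("m%02d", mouse),
        population = c("C", "T", "M"),
        count = as.numeric(truth[i, ]) * noise,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("observed_data", "data.frame")
  out
}

#' Per-day per-population summary statistics of an observed dataset
#'
#' @param data An `observed_data` data frame (or anything with columns
#'   `day`, `population`, `count`).
#' @return Data frame with columns `day`, `population`, `mean`, `min`,
#'   `max`, `n`, sorted by population then day.  Always recomputed from the
#'   records.
#' @export
observed_stats <- function(data) {
  validate_observed(data)
  agg <- stats::aggregate(count ~ day + population, data = data,
                          FUN = function(x) c(mean = mean(x), min = min(x),
                                              max = max(x), n = length(x)))
  out <- data.frame(day = agg$day, population = agg$population,
                    mean = agg$count[, "mean"], min = agg$count[, "min"],
                    max = agg$count[, "max"], n = as.integer(agg$count[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$population, out$day), , drop = FALSE]
}

validate_observed <- function(data) {
  need <- c("day", "population", "count")
  if (!all(need %in% names(data))) {
    stop("observed data needs columns: ", paste(need, collapse = ", "))
  }
  bad_pop <- which(!data$population %in% c("C", "T", "M"))
  if (length(bad_pop)) {
    stop("unknown population code at row(s): ",
         paste(utils::head(bad_pop, 5), collapse = ", "))
  }
  bad_count <- which(!is.finite(data$count) | data$count < 0)
  if (length(bad_count)) {
    stop("negative or non-finite count at row(s): ",
         paste(utils::head(bad_count, 5), collapse = ", "))
  }
  invisible(data)
}

#' Read / write observed cell-count data
#'
#' CSV dialect: header `day,mouse_id,population,count`, population codes
#' `C` (tumor cells), `T` (CD3+ T cells), `M` (MDSCs).  `read_observed`
#' validates populations and counts and reports offending row numbers;
#' write-then-read is the identity on records.
#'
#' A small synthetic example dataset generated by [generate_observed()]
#' (seed 42, noise CV 0.2) ships with the package, see the example.
#'
#' @param path File path.
#' @return `read_observed`: an `observed_data` data frame.
#' @examples
#' d <- read_observed(system.file("extdata", "synthetic_counts.csv",
#'                                package = "gbmimmune"))
#' observed_stats(d)
#' @export
read_observed <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(day = "integer", mouse_id = "character",
                                      population = "character",
                                      count = "numeric"))
  need <- c("day", "mouse_id", "population", "count")
  if (!identical(names(d), need)) {
    stop("malformed header in ", path, "; expected ",
         paste(need, collapse = ","))
  }
  validate_observed(d)
  class(d) <- c("observed_data", "data.frame")
  d
}

#' @rdname read_observed
#' @param data An `observed_data` data frame.
#' @export
write_observed <- function(data, path) {
  validate_observed(data)
  utils::write.csv(data[, c("day", "mouse_id", "population", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
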