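#' eFAST search curves
#'
#' Periodic space-filling curves mapping the scalar phase variable
#' `s` in `(-pi, pi)` to the unit interval, so that each parameter
#' oscillates at its own integer frequency.  `search_curve_uniform` is the
#' arcsine curve whose samples are uniform on `[0, 1]`;
#' `search_curve_exponential` is the mode-anchored exponential curve
#' `x = n_i * exp(v_i * sin(omega * s + phi))` with `v_i = log(1 / n_i)`,
#' which oscillates within `[n_i^2, 1]` around the nominal value `n_i` and
#' concentrates samples near it (suited to right-skewed posteriors).
#'
#' @param s Phase variable (radians).
#' @param omega Integer angular frequency.
#' @param phi Phase shift (radians).
#' @param n_i Nominal value in (0, 1), exponential curve only.
#' @return Values in `[0, 1]`.
#' @examples
#' search_curve_uniform(pi / 2, 1, 0)           # 1
#' search_curve_exponential(-pi / 2, 1, 0, 0.1) # 0.01
#' @export
search_curve_uniform <- function(s, omega, phi) {
  0.5 + asin(sin(omega * s + phi)) / pi
}

#' @rdname search_curve_uniform
#' @export
search_curve_exponential <- function(s, omega, phi, n_i) {
  if (any(n_i <= 0 | n_i >= 1)) stop("nominal n_i must lie strictly in (0, 1)")
  v <- log(1 / n_i)
  n_i * exp(v * sin(omega * s + phi))
}

#' Build an eFAST sampling design
#'
#' For each parameter-of-interest block, the parameter under study is
#' assigned the maximum frequency `omega_max = (NS - 1) / (2 * M)` and the
#' complementary parameters receive integer frequencies spread over
#' `[1, omega_max / (2 * M)]`, so that the first `M` harmonics of the
#' parameter of interest do not alias with any complementary harmonic.
#' Phase shifts are drawn uniformly on `[0, 2 * pi)` per parameter and
#' resampling; the phase grid is `s_k = -pi + pi * (2k + 1) / NS`.
#'
#' @param ranges 13 x 2 matrix (or data frame with `lower`, `upper`) of
#'   target parameter ranges, rows in [param_names()] order.
#' @param curve_kinds Character vector (length 13) of `"uniform"` /
#'   `"exponential"`.
#' @param nominals Nominal parameter values (natural units) for the
#'   exponential curves; normalized internally to `(0, 1)` within the range
#'   (clamped away from the endpoints with a warning if outside).
#' @param NS Samples per curve (odd; default 2049).
#' @param NR Number of resamplings (default 5).
#' @param M Number of harmonics (default 4).
#' @param seed Integer seed for the phases.
#' @return List of class `"efast_design"`; `n_per_block = NS * NR` model
#'   evaluations are needed per parameter-of-interest block.
#' @export
efast_design <- function(ranges, curve_kinds, nominals = NULL,
                         NS = 2049, NR = 5, M = 4, seed = 1) {
  if (is.data.frame(ranges)) ranges <- cbind(ranges$lower, ranges$upper)
  k <- nrow(ranges)
  stopifnot(k >= 2, ncol(ranges) == 2, length(curve_kinds) == k)
  if (NS %% 2 == 0) stop("NS must be odd")
  omega_max <- (NS - 1) %/% (2 * M)
  if (omega_max < 1 || NS < 2 * M * omega_max + 1) {
    stop("NS too small for ", M, " harmonics (aliasing)")
  }
  omega_comp_max <- max(1L, omega_max %/% (2 * M))
  omega_comp <- unique(round(seq(1, omega_comp_max, length.out = k - 1)))
  omega_comp <- rep_len(omega_comp, k - 1)

  n01 <- rep(NA_real_, k)
  if (any(curve_kinds == "exponential")) {
    if (is.null(nominals)) stop("exponential curves need nominal values")
    n01 <- (as.numeric(nominals) - ranges[, 1]) / (ranges[, 2] - ranges[, 1])
    out_of_range <- curve_kinds == "exponential" & (n01 <= 0 | n01 >= 1)
    if (any(out_of_range)) {
      warning("nominal value outside its range for: ",
              paste(which(out_of_range), collapse = ", "), "; clamping")
      n01[out_of_range] <- pmin(pmax(n01[out_of_range], 1e-6), 1 - 1e-6)
    }
  }
  set.seed(seed)
  phases <- array(stats::runif(k * k * NR, 0, 2 * pi), dim = c(k, k, NR))
  s <- -pi + pi * (2 * seq_len(NS) - 1) / NS

  structure(
    list(ranges = ranges, curve_kinds = curve_kinds, n01 = n01,
         NS = NS, NR = NR, M = M,
         omega_max = omega_max, omega_comp = omega_comp,
         phases = phases, s = s, n_per_block = NS * NR),
    class = "efast_design"
  )
}

#' Parameter samples for one eFAST block and resampling
#'
#' @param design An [efast_design()].
#' @param block Index of the parameter of interest (gets `omega_max`).
#' @param resampling Resampling index in `1..NR`.
#' @return `NS` x k matrix of parameter values in natural units.
#' @export
efast_samples <- function(design, block, resampling) {
  k <- nrow(design$ranges)
  omega <- integer(k)
  omega[block] <- design$omega_max
  omega[-block] <- design$omega_comp
  X <- matrix(NA_real_, design$NS, k)
  for (j in seq_len(k)) {
    phi <- design$phases[block, j, resampling]
    x01 <- if (design$curve_kinds[j] == "exponential") {
      search_curve_exponential(design$s, omega[j], phi, design$n01[j])
    } else {
      search_curve_uniform(design$s, omega[j], phi)
    }
    X[, j] <- design$ranges[j, 1] + x01 * (design$ranges[j, 2] - design$ranges[j, 1])
  }
  X
}

# First- and total-order index from one output series on the s grid.
# Lambda_j = |fft(y)[j + 1]|^2 is the power at integer frequency j because
# the s grid is uniform with spacing 2*pi/NS.
efast_spectrum_indices <- function(y, omega_max, M) {
  NS <- length(y)
  lam <- Mod(stats::fft(y))[2:((NS - 1) / 2 + 1)]^2
  V <- sum(lam)
  if (V < 1e-12 * mean(y)^2 || !is.finite(V) || V == 0) {
    return(c(Si = 0, STi = 0, degenerate = 1))
  }
  Vi <- sum(lam[seq_len(M) * omega_max])
  Vc <- sum(lam[seq_len(omega_max %/% 2)])
  c(Si = Vi / V, STi = 1 - Vc / V, degenerate = 0)
}

#' Compute eFAST sensitivity indices from model outputs
#'
#' Runs the model over every block and resampling of a design and estimates
#' the first-order index `S_i` (variance at the parameter-of-interest
#' frequency and its first `M` harmonics over total variance) and the
#' total-order index `S_Ti` (one minus the complementary variance at
#' frequencies up to `omega_max / 2` over total variance).  Reported values
#' are means over the `NR` resamplings with their standard error.
#'
#' Failed model evaluations (non-finite outputs) are imputed with the
#' per-curve median when they make up at most `max_fail_frac` of a curve;
#' more than that aborts, since the Fourier analysis needs a complete
#' ordered sample.
#'
#' @param design An [efast_design()].
#' @param model Function taking an `NS` x k parameter matrix and returning
#'   a numeric matrix with one column per model output (columns named).
#' @param param_labels Optional parameter names (default [param_names()]
#'   when k = 13, else `p1..pk`).
#' @param max_fail_frac Maximum tolerated fraction of failed evaluations per
#'   curve (default 0.05).
#' @return Data frame of class `"efast_indices"`: `parameter`, `output`,
#'   `S_i`, `S_Ti`, `sem_Si`, `sem_STi`, `degenerate`.
#' @export
efast_run <- function(design, model, param_labels = NULL,
                      max_fail_frac = 0.05) {
  k <- nrow(design$ranges)
  if (is.null(param_labels)) {
    param_labels <- if (k == 13) param_names() else paste0("p", seq_len(k))
  }
  res <- list()
  for (b in seq_len(k)) {
    acc <- NULL  # per-resampling indices: array [NR, n_out, 3]
    for (r in seq_len(design$NR)) {
      X <- efast_samples(design, b, r)
      Y <- model(X)
      if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(NULL, "y"))
      for (cc in seq_len(ncol(Y))) {
        y <- Y[, cc]
        bad <- !is.finite(y)
        if (any(bad)) {
          if (mean(bad) > max_fail_frac) {
            stop(sprintf("eFAST block %d: %.1f%% failed evaluations (limit %.0f%%)",
                         b, 100 * mean(bad), 100 * max_fail_frac))
          }
          warning(sprintf("imputing %d failed evaluation(s) in eFAST block %d",
                          sum(bad), b))
          y[bad] <- stats::median(y[!bad])
        }
        Y[, cc] <- y
      }
      ind <- vapply(seq_len(ncol(Y)), function(cc) {
        efast_spectrum_indices(Y[, cc], design$omega_max, design$M)
      }, numeric(3))
      if (is.null(acc)) {
        acc <- array(NA_real_, dim = c(design$NR, ncol(Y), 3),
                     dimnames = list(NULL, colnames(Y), c("Si", "STi", "degenerate")))
      }
      acc[r, , ] <- t(ind)
    }
    for (out_name in dimnames(acc)[[2]]) {
      si <- acc[, out_name, "Si"]; sti <- acc[, out_name, "STi"]
      res[[length(res) + 1L]] <- data.frame(
        parameter = param_labels[b], output = out_name,
        S_i = mean(si), S_Ti = mean(sti),
        sem_Si = stats::sd(si) / sqrt(design$NR),
        sem_STi = stats::sd(sti) / sqrt(design$NR),
        degenerate = any(acc[, out_name, "degenerate"] > 0),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  if (any(out$degenerate)) {
    warning("constant model output in some block(s): indices reported as 0")
  }
  class(out) <- c("efast_indices", "data.frame")
  out
}

#' eFAST sensitivity analysis of the GBM-immune model
#'
#' Samples the 13 model parameters along eFAST search curves and computes
#' first- and total-order indices of each parameter on the tumor, T-cell
#' and MDSC counts at one or more simulation end times.  With
#' `curves = "mixed"` (default) the six parameters with right-skewed
#' reference posteriors (`lambda_C`, `C_max`, `eta`, `rho`, `eps_C`, `r`)
#' use the mode-anchored exponential curve with the posterior mode as
#' nominal value, and the remaining seven use the uniform curve;
#' `curves = "uniform"` samples all 13 uniformly.
#'
#' @param end_times Simulation end times in days (default
#'   `c(5, 10, 20, 40, 60, 80, 100)`).
#' @param ranges Parameter ranges (default [default_priors()]).
#' @param nominals Nominal values for the exponential curves (default
#'   [default_params()], the reference posterior modes).
#' @param curves `"mixed"` or `"uniform"`.
#' @param NS,NR,M,seed Design settings, see [efast_design()].
#' @param init Initial state (default 35,000 implanted glioma cells).
#' @return An `efast_indices` data frame with an `end_time` column;
#'   outputs are labelled `C`, `T`, `M`.
#' @export
run_efast_on_model <- function(end_times = c(5, 10, 20, 40, 60, 80, 100),
                               ranges = default_priors(),
                               nominals = default_params(),
                               curves = c("mixed", "uniform"),
                               NS = 2049, NR = 5, M = 4, seed = 1,
                               init = default_init()) {
  curves <- match.arg(curves)
  skewed <- c("lambda_C", "C_max", "eta", "rho", "eps_C", "r")
  kinds <- rep("uniform", 13)
  if (curves == "mixed") kinds[param_names() %in% skewed] <- "exponential"
  design <- efast_design(ranges, kinds, nominals = as.numeric(nominals),
                         NS = NS, NR = NR, M = M, seed = seed)
  end_times <- sort(end_times)
  times <- c(0, end_times)
  model <- function(X) {
    n <- nrow(X)
    Y <- matrix(NA_real_, n, 3 * length(end_times))
    colnames(Y) <- paste0(rep(c("C", "T", "M"), times = length(end_times)),
                          "@", rep(end_times, each = 3))
    for (i in seq_len(n)) {
      out <- solve_raw(X[i, ], init, times, 1e-8, 1e-6)
      if (!is.null(out) && nrow(out) == length(times) && !anyNA(out)) {
        Y[i, ] <- as.numeric(t(out[-1, 2:4]))
      }
    }
    Y
  }
  res <- efast_run(design, model)
  parts <- strsplit(res$output, "@", fixed = TRUE)
  res$end_time <- as.numeric(vapply(parts, `[`, character(1), 2))
  res$output <- vapply(parts, `[`, character(1), 1)
  res[, c("end_time", "output", "parameter", "S_i", "S_Ti",
          "sem_Si", "sem_STi", "degenerate")]
}
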