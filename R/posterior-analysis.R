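# Downstream analyses of trajectories and fitted ensembles: per-mechanism
# repair tallies, posterior predictive bands, half-maximum times, pathway
# occupancy and activity timelines, and KS comparisons of posteriors.

#' Per-mechanism repair tally of a trajectory
#'
#' The cumulative number of breaks that entered each channel (recruitment
#' firings -- the event-count realisation of the pathway-entry integral
#' of the recruitment propensity), the number each channel completed
#' (ligations), and both as proportions of the initial break count. Two
#' integral evaluations of the entry flux are returned for cross-checking:
#' the exact along-path integral and a trapezoid quadrature on the output
#' grid.
#'
#' @param traj a \code{\link{simulate_repair}} trajectory.
#' @return list with \code{entered}, \code{completed}, \code{proportions},
#'   \code{residual_free} (breaks never recruited), \code{entry_integral}
#'   (exact), \code{entry_quadrature} (grid trapezoid).
#' @export
tally_mechanisms <- function(traj) {
  stopifnot(inherits(traj, "repair_trajectory"))
  last <- length(traj$time)
  entered <- traj$cum_recruit[last, ]
  completed <- traj$cum_ligate[last, ]
  # instantaneous recruitment propensity at each snapshot, trapezoid in t
  quad <- vapply(seq_along(CHANNELS), function(i) {
    C <- traj$C[i]
    if (C <= 0) return(0)
    a <- traj$params$K[i] * traj$x * (C - traj$y[, i]) / C
    sum(diff(traj$time) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
  }, numeric(1))
  names(entered) <- names(completed) <- CHANNELS
  list(entered = entered, completed = completed,
       proportions = entered / max(traj$x0, 1),
       residual_free = traj$x[last],
       entry_integral = stats::setNames(traj$entry_integral[last, ], CHANNELS),
       entry_quadrature = stats::setNames(quad, CHANNELS))
}

# one posterior-predictive trajectory: resample a particle by weight,
# redraw rates from its hyperparameters, simulate
predictive_draw <- function(ensemble, spec, grid, zero_channels = NULL) {
  j <- sample.int(nrow(ensemble$particles), 1, prob = ensemble$particles$weight)
  mu <- as.numeric(ensemble$particles[j, paste0("mu", 1:4)])
  hyper <- list(mu = mu, sigma2 = ensemble$particles$sigma2[j])
  pw <- spec$pathways
  for (ch in zero_channels) pw[[ch]] <- pathway("absent")
  rates <- sample_rates(hyper, pw)
  simulate_repair(rates, dose_to_dsb(spec$dose_gy), grid)
}

#' Posterior predictive repair-curve bands
#'
#' Resamples particles by weight, redraws the dataset's rates from each
#' particle's hyperparameters, re-simulates, and returns pointwise quantiles
#' of the dose-equivalent curve: the median, the 0.5 credible region
#' (0.25, 0.75) and the 0.95 credible region (0.025, 0.975).
#'
#' @param ensemble a \code{\link{abc_smc_fit}} posterior.
#' @param spec the \code{\link{dataset_spec}} to re-simulate.
#' @param grid output times (default: the dataset's own timepoints).
#' @param n_draws posterior draws (>= 10).
#' @param zero_channels channels whose rates are set to zero before
#'   re-simulation (in-silico knockout), default none.
#' @param seed optional integer seed.
#' @return data.frame: time, q025, q25, q50, q75, q975.
#' @export
predictive_bands <- function(ensemble, spec, grid = NULL, n_draws = 200,
                             zero_channels = NULL, seed = NULL) {
  stopifnot(inherits(ensemble, "dsb_posterior"), nrow(ensemble$particles) > 0)
  if (n_draws < 10) stop("n_draws must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- spec$timepoints
  curves <- vapply(seq_len(n_draws), function(i)
    measured_curve(predictive_draw(ensemble, spec, grid, zero_channels)),
    numeric(length(grid)))
  qs <- apply(curves, 1, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
              names = FALSE)
  data.frame(time = grid, q025 = qs[1, ], q25 = qs[2, ], q50 = qs[3, ],
             q75 = qs[4, ], q975 = qs[5, ])
}

#' In-silico channel knockout re-simulation
#'
#' Identical to \code{\link{predictive_bands}} but with the listed channels'
#' rates set to zero, predicting e.g. the repair the alternative end joining
#' channel alone could achieve.
#'
#' @inheritParams predictive_bands
#' @param channels channels to zero out.
#' @export
channel_knockout_resim <- function(ensemble, spec, channels, grid = NULL,
                                   n_draws = 200, seed = NULL) {
  predictive_bands(ensemble, spec, grid = grid, n_draws = n_draws,
                   zero_channels = channels, seed = seed)
}

#' Time for a channel to reach half its final ligation count
#'
#' The smallest output-grid time at which the channel's cumulative ligations
#' reach half their final value -- the half-maximum time of repair carried
#' out by that mechanism. The ensemble method re-simulates posterior draws
#' and reports the median with the 0.5 credible region.
#'
#' @param x a \code{repair_trajectory} or \code{dsb_posterior}.
#' @param channel one of "fast", "slow", "aej"; must be a full channel.
#' @param ... passed to methods.
#' @return trajectory method: hours (NA if the channel never ligates);
#'   ensemble method: named vector (median, q25, q75).
#' @export
time_to_half_max <- function(x, channel, ...) UseMethod("time_to_half_max")

#' @rdname time_to_half_max
#' @export
time_to_half_max.repair_trajectory <- function(x, channel, ...) {
  channel <- match.arg(channel, CHANNELS)
  if (x$params$mode[channel] != "full")
    stop("channel '", channel, "' is ", x$params$mode[channel],
         ": half-maximum repair time is undefined")
  cl <- x$cum_ligate[, match(channel, CHANNELS)]
  final <- cl[length(cl)]
  if (final == 0) return(NA_real_)
  x$time[which(cl >= final / 2)[1]]
}

#' @rdname time_to_half_max
#' @param spec dataset to re-simulate (ensemble method).
#' @param grid output grid; default a dense hourly grid to 48 h.
#' @param n_draws posterior draws (ensemble method).
#' @param seed optional integer seed.
#' @export
time_to_half_max.dsb_posterior <- function(x, channel, spec,
                                           grid = seq(0, 48, by = 0.25),
                                           n_draws = 100, seed = NULL, ...) {
  channel <- match.arg(channel, CHANNELS)
  if (spec$pathways[[channel]]$mode != "full")
    stop("channel '", channel, "' is ", spec$pathways[[channel]]$mode,
         " in ", spec$id)
  if (!is.null(seed)) set.seed(seed)
  times <- vapply(seq_len(n_draws), function(i)
    time_to_half_max(predictive_draw(x, spec, grid), channel),
    numeric(1))
  q <- quantile(times, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Per-channel share of in-process DSBs over time
#'
#' At each output time, the fraction of all bound (being-processed) breaks
#' that sit in each channel: \code{y_i(t) / sum_j y_j(t)}, defined as 0 when
#' no breaks are bound. Free breaks are not yet assigned to any mechanism
#' and are excluded.
#'
#' @param traj a \code{repair_trajectory}.
#' @return data.frame: time, share_fast, share_slow, share_aej.
#' @export
occupancy_series <- function(traj) {
  stopifnot(inherits(traj, "repair_trajectory"))
  tot <- rowSums(traj$y)
  sh <- sweep(traj$y, 1, ifelse(tot > 0, tot, 1), "/")
  sh[tot == 0, ] <- 0
  data.frame(time = traj$time, share_fast = sh[, 1], share_slow = sh[, 2],
             share_aej = sh[, 3])
}

#' Activity timeline of repair mechanisms across posterior draws
#'
#' For each posterior draw and output time, a channel is flagged active when
#' it holds more than \code{threshold} (default 30\%) of all breaks
#' currently being processed. Returns the boolean activity array together
#' with each draw's rate constants and per-channel total activity duration,
#' for rate-vs-activation summaries.
#'
#' @param ensemble a \code{dsb_posterior}.
#' @param spec dataset to re-simulate.
#' @param threshold occupancy fraction in (0, 1), default 0.30.
#' @param grid output times.
#' @param n_draws posterior draws.
#' @param seed optional integer seed.
#' @return list: \code{active} (array draw x time x channel), \code{time},
#'   \code{rates} (data.frame of each draw's K per channel), \code{duration}
#'   (data.frame, hours each channel spent active per draw).
#' @export
activity_timeline <- function(ensemble, spec, threshold = 0.30,
                              grid = seq(0, 24, by = 0.25), n_draws = 100,
                              seed = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(grid)
  active <- array(FALSE, c(n_draws, nt, 3),
                  dimnames = list(NULL, NULL, CHANNELS))
  rates <- matrix(NA_real_, n_draws, 3, dimnames = list(NULL, CHANNELS))
  dt <- c(diff(grid), 0)
  duration <- matrix(0, n_draws, 3, dimnames = list(NULL, CHANNELS))
  for (i in seq_len(n_draws)) {
    tr <- predictive_draw(ensemble, spec, grid)
    occ <- occupancy_series(tr)
    for (k in seq_along(CHANNELS)) {
      act <- occ[[paste0("share_", CHANNELS[k])]] > threshold
      active[i, , k] <- act
      duration[i, k] <- sum(dt[act])
      rates[i, k] <- tr$params$K[k]
    }
  }
  list(active = active, time = grid, rates = as.data.frame(rates),
       duration = as.data.frame(duration))
}

#' Two-sample Kolmogorov-Smirnov comparison of posterior samples
#'
#' Two-sided KS test between two (possibly weighted) posterior samples.
#' Weighted samples are first resampled to unweighted draws; the statistic
#' is the supremum distance between the empirical CDFs with the asymptotic
#' p-value.
#'
#' @param a,b numeric samples (at least 8 points each).
#' @param w_a,w_b optional weights; triggers resampling to unweighted.
#' @param n_resample resample size when weights are supplied.
#' @param seed optional integer seed for the resampling step.
#' @return list with \code{D} and \code{p_value}.
#' @export
ks_two_sample <- function(a, b, w_a = NULL, w_b = NULL, n_resample = 1000,
                          seed = NULL) {
  if (length(a) < 8 || length(b) < 8)
    stop("need at least 8 points per sample")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(w_a)) a <- sample(a, n_resample, replace = TRUE, prob = w_a)
  if (!is.null(w_b)) b <- sample(b, n_resample, replace = TRUE, prob = w_b)
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}
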