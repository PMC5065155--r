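# Synthetic repair-curve generator. The published PFGE curves behind D1-D8
# were traced from figures and are not deposited, so the pipeline is exercised
# on simulated data with the same structure: stochastic three-process repair
# at the published doses, observed on a sparse time grid with additive
# measurement noise on the dose-equivalent axis.

#' Reference ground-truth rates for the eight datasets
#'
#' The fitted posterior median rate constants (1/hr) for each dataset and
#' channel, used as the default ground truth of the synthetic generator.
#' Binding-only channels carry a recruitment rate only.
#'
#' @return named list over D1..D8 of \code{\link{rate_params}}.
#' @export
default_true_rates <- function() {
  list(
    D1 = rate_params(K = c(fast = 3.06, slow = 0.04, aej = 0.34),
                     Kprime = c(fast = 2.87, slow = 0.04, aej = 0.40)),
    D2 = rate_params(K = c(fast = 0.05, slow = 0.037, aej = 0.40),
                     Kprime = c(slow = 0.041, aej = 0.62),
                     mode = c(fast = "binding_only", slow = "full", aej = "full")),
    D3 = rate_params(K = c(fast = 0.04, slow = 0.038, aej = 0.50),
                     Kprime = c(slow = 0.041, aej = 0.91),
                     mode = c(fast = "binding_only", slow = "full", aej = "full")),
    D4 = rate_params(K = c(fast = 2.24, slow = 0.056, aej = 0.45),
                     Kprime = c(fast = 4.35, aej = 0.29),
                     mode = c(fast = "full", slow = "binding_only", aej = "full")),
    D5 = rate_params(K = c(slow = 0.066, aej = 0.22),
                     Kprime = c(slow = 0.025, aej = 0.16)),
    D6 = rate_params(K = c(slow = 0.057, aej = 0.29),
                     Kprime = c(slow = 0.034, aej = 0.19)),
    D7 = rate_params(K = c(slow = 0.042), Kprime = c(slow = 0.022)),
    D8 = rate_params(K = c(fast = 2.34, slow = 0.048),
                     Kprime = c(fast = 3.20, slow = 0.041)))
}

#' Default observation grid for synthetic repair curves
#'
#' A sparse grid spanning the fast (sub-hour), intermediate (hours) and slow
#' (tens of hours) repair regimes. The grid reaches 24 h, about 1.4
#' half-times of the slowest reference rate (0.04/hr, half-time 17.3 h) --
#' late-time information on the slow channel is therefore partial, as it is
#' in the traced assays.
#'
#' @param id dataset label (unused by the default; present so per-dataset
#'   grids can be plugged in).
#' @return numeric vector of hours.
#' @export
default_timepoints <- function(id = NULL) {
  c(0, 0.25, 0.5, 1, 2, 4, 8, 12, 24)
}

#' Configuration of the synthetic-data generator
#'
#' @param ids dataset labels to generate (default all of D1..D8).
#' @param pathways pathway configuration (default
#'   \code{\link{default_pathway_config}}).
#' @param rates ground-truth rates per dataset (default
#'   \code{\link{default_true_rates}}).
#' @param doses named dose vector in Gy (default the published doses).
#' @param timepoints function id -> grid, default
#'   \code{\link{default_timepoints}}.
#' @param noise_frac additive Gaussian noise s.d. as a fraction of the dose
#'   (default 0.05, i.e. 5\% of dose on the Gy axis), truncated at 0.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(ids = DATASET_IDS,
                             pathways = default_pathway_config(),
                             rates = default_true_rates(),
                             doses = NULL, timepoints = default_timepoints,
                             noise_frac = 0.05) {
  if (is.null(doses)) {
    tab <- default_dataset_table()
    doses <- stats::setNames(tab$dose_gy, tab$id)
  }
  stopifnot(noise_frac >= 0, all(doses[ids] > 0))
  structure(list(ids = ids, pathways = pathways, rates = rates,
                 doses = doses, timepoints = timepoints,
                 noise_frac = noise_frac), class = "generator_config")
}

#' Generate a synthetic repair-curve suite
#'
#' For each configured dataset: one exact stochastic simulation at the
#' ground-truth rates (publication doses give hundreds to thousands of
#' breaks, so a single realisation already averages over breaks like the
#' population-level PFGE assay), observed through \code{measured_curve} at
#' the dataset's timepoints, plus additive Gaussian noise truncated at 0.
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed optional integer seed; the whole suite is reproducible.
#' @return named list of \code{\link{dataset_spec}} objects; the ground
#'   truth (rates, noise-free curves, seed) is attached as
#'   \code{attr(, "truth")}.
#' @examples
#' suite <- generate_suite(generator_config(ids = c("D1", "D7")), seed = 1)
#' suite$D1
#' @export
generate_suite <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  tab <- default_dataset_table()
  datasets <- list()
  truth <- list(seed = seed, rates = config$rates[config$ids], clean = list())
  for (id in config$ids) {
    tp <- config$timepoints(id)
    dose <- config$doses[[id]]
    tr <- simulate_repair(config$rates[[id]], dose_to_dsb(dose), tp)
    clean <- measured_curve(tr)
    noisy <- clean + rnorm(length(clean), 0, config$noise_frac * dose)
    noisy <- pmin(pmax(noisy, 0), dose * 1.2)
    phase <- tab$phase[match(id, tab$id)]
    if (is.na(phase)) phase <- "asynchronous"
    datasets[[id]] <- dataset_spec(id, dose, tp, noisy,
                                   config$pathways[[id]], phase)
    truth$clean[[id]] <- clean
  }
  attr(datasets, "truth") <- truth
  datasets
}
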