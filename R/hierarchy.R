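# Hierarchical structure: which repair channels are active in which knockout
# dataset, which population-level hyperparameter each rate draws from, and the
# lognormal sampling of per-dataset rates.

DATASET_IDS <- paste0("D", 1:8)

# dose (Gy), cell-cycle phase and knockout description for the eight
# literature repair-curve assays the hierarchy is built around
DATASET_TABLE <- data.frame(
  id = DATASET_IDS,
  dose_gy = c(20, 20, 20, 80, 80, 54, 52, 32),
  phase = c("asynchronous", "G1", "G2", "asynchronous", "asynchronous",
            "asynchronous", "asynchronous", "asynchronous"),
  mutant = c("wild type", "DNA-PKcs-/-", "DNA-PKcs-/-", "Rad52-/-",
             "Ku70-/-/Rad54-/-", "Ku70-/-", "Ku70-/- + PARP-1 inhibitor",
             "wild type + PARP-1 inhibitor"),
  stringsAsFactors = FALSE)

#' Dose, phase and mutant annotation of the eight knockout datasets
#'
#' @return data.frame with columns id, dose_gy, phase, mutant.
#' @export
default_dataset_table <- function() DATASET_TABLE

pathway <- function(mode, mu = NA_integer_) {
  list(mode = mode, mu = as.integer(mu))
}

#' Default channel/hyperparameter configuration for datasets D1-D8
#'
#' Encodes the knockout structure of the eight repair assays: which of the
#' fast (NHEJ), slow (SSA) and alternative end joining channels is fully
#' active, binding-only (the recruitment protein binds but a downstream
#' repair factor is ablated, so complexes form and persist without ligation)
#' or absent, and which population-level hyperparameter index (1-4) the
#' channel's rates draw from. Binding-only channels always draw from the
#' dedicated hyperparameter mu4. Both K and K' of a full channel draw
#' (independently) from the same mu.
#'
#' @return named list over D1..D8; each element is a named list over
#'   channels \code{fast}, \code{slow}, \code{aej} with fields \code{mode}
#'   and \code{mu}.
#' @examples
#' cfg <- default_pathway_config()
#' cfg$D7  # slow channel only
#' @export
default_pathway_config <- function() {
  list(
    D1 = list(fast = pathway("full", 1), slow = pathway("full", 2),
              aej = pathway("full", 3)),
    D2 = list(fast = pathway("binding_only", 4), slow = pathway("full", 2),
              aej = pathway("full", 3)),
    D3 = list(fast = pathway("binding_only", 4), slow = pathway("full", 2),
              aej = pathway("full", 3)),
    D4 = list(fast = pathway("full", 1), slow = pathway("binding_only", 4),
              aej = pathway("full", 3)),
    D5 = list(fast = pathway("absent"), slow = pathway("full", 2),
              aej = pathway("full", 3)),
    D6 = list(fast = pathway("absent"), slow = pathway("full", 2),
              aej = pathway("full", 3)),
    D7 = list(fast = pathway("absent"), slow = pathway("full", 2),
              aej = pathway("absent")),
    D8 = list(fast = pathway("full", 1), slow = pathway("full", 2),
              aej = pathway("absent")))
}

#' Count free rate parameters implied by a pathway map
#'
#' Full channels contribute two (K, K'), binding-only channels one (K),
#' absent channels none.
#'
#' @param pathways one element of \code{\link{default_pathway_config}}.
#' @return integer parameter count.
#' @export
n_rate_params <- function(pathways) {
  sum(vapply(pathways, function(p)
    switch(p$mode, full = 2L, binding_only = 1L, absent = 0L), integer(1)))
}

#' A repair-curve dataset with its knockout configuration
#'
#' @param id dataset label, e.g. "D1".
#' @param dose_gy radiation dose in Gray (> 0).
#' @param timepoints strictly increasing observation times in hours.
#' @param observed dose-equivalent measurements (Gy), same length as
#'   \code{timepoints}.
#' @param pathways per-channel mode/hyperparameter map (see
#'   \code{\link{default_pathway_config}}).
#' @param phase cell-cycle phase label.
#' @return object of class \code{dsb_dataset}.
#' @export
dataset_spec <- function(id, dose_gy, timepoints, observed, pathways,
                         phase = "asynchronous") {
  stopifnot(dose_gy > 0, length(timepoints) == length(observed))
  if (timepoints[1] < 0 || is.unsorted(timepoints, strictly = TRUE))
    stop(id, ": timepoints must be strictly increasing, first >= 0")
  if (any(observed < 0) || any(observed > dose_gy * 1.2))
    stop(id, ": observed values must lie in [0, 1.2 * dose]")
  modes <- vapply(pathways, `[[`, "", "mode")
  if (all(modes == "absent")) stop(id, ": at least one channel must be active")
  structure(list(id = id, dose_gy = dose_gy, phase = phase,
                 timepoints = as.numeric(timepoints),
                 observed = as.numeric(observed), pathways = pathways),
            class = "dsb_dataset")
}

#' @export
print.dsb_dataset <- function(x, ...) {
  modes <- vapply(x$pathways, `[[`, "", "mode")
  cat(sprintf("%s: %g Gy (%s), %d timepoints; channels: %s\n", x$id,
              x$dose_gy, x$phase, length(x$timepoints),
              paste(names(modes), modes, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Uniform hyperprior on the population-level log-rate means
#'
#' Each hyperparameter mu_i (the mean of log K for the rates it governs) has
#' an independent uniform prior on [alpha_i, beta_i] in log-rate space. The
#' shared lognormal variance sigma^2 is fixed by default; pass a length-2
#' range to infer it under a uniform prior.
#'
#' @param alpha,beta length-4 lower/upper bounds of the uniform priors on
#'   mu_1..mu_4 (log 1/hr). Defaults bracket rates of 0.001-20 per hour.
#' @param sigma2 fixed variance of log K (default 0.25), or a length-2
#'   vector \code{c(lo, hi)} to place a uniform prior on it.
#' @return object of class \code{hyper_prior}.
#' @export
hyper_prior <- function(alpha = rep(log(1e-3), 4), beta = rep(log(20), 4),
                        sigma2 = 0.25) {
  alpha <- rep_len(alpha, 4); beta <- rep_len(beta, 4)
  if (any(alpha > beta)) stop("need alpha <= beta componentwise")
  infer <- length(sigma2) == 2
  if (!infer && sigma2 <= 0) stop("sigma2 must be > 0")
  structure(list(alpha = alpha, beta = beta, sigma2 = sigma2,
                 infer_sigma2 = infer), class = "hyper_prior")
}

#' Draw hyperparameters from their prior
#'
#' @param prior a \code{\link{hyper_prior}}.
#' @param seed optional integer seed.
#' @return list with \code{mu} (length 4) and \code{sigma2}.
#' @export
sample_hyperparams <- function(prior, seed = NULL) {
  stopifnot(inherits(prior, "hyper_prior"))
  if (!is.null(seed)) set.seed(seed)
  mu <- runif(4, prior$alpha, prior$beta)
  s2 <- if (prior$infer_sigma2) runif(1, prior$sigma2[1], prior$sigma2[2])
        else prior$sigma2
  list(mu = mu, sigma2 = s2)
}

#' Draw per-dataset rate parameters from the hierarchy
#'
#' For every rate slot required by the dataset's pathway map, log K is drawn
#' from N(mu_assigned, sigma2): full channels get independent K and K' draws
#' from the same mu; binding-only channels get a recruitment rate only (from
#' mu4); absent channels get nothing.
#'
#' @param hyper list with \code{mu} (length 4) and \code{sigma2}, as from
#'   \code{\link{sample_hyperparams}}.
#' @param pathways per-channel map for one dataset.
#' @param seed optional integer seed.
#' @return a \code{\link{rate_params}} object.
#' @export
sample_rates <- function(hyper, pathways, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(hyper$sigma2)
  K <- Kp <- numeric(0); mode <- character(0)
  for (ch in names(pathways)) {
    p <- pathways[[ch]]
    if (p$mode == "absent") next
    K[ch] <- exp(rnorm(1, hyper$mu[p$mu], sd))
    mode[ch] <- p$mode
    if (p$mode == "full") Kp[ch] <- exp(rnorm(1, hyper$mu[p$mu], sd))
  }
  rate_params(K = K, Kprime = Kp, mode = mode)
}

# hyperparameter indices actually used by a set of datasets (sorted)
used_mu_indices <- function(datasets) {
  idx <- unlist(lapply(datasets, function(d)
    vapply(d$pathways, function(p)
      if (p$mode == "absent") NA_integer_ else p$mu, integer(1))))
  sort(unique(idx[!is.na(idx)]))
}
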