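# Comparison of nested one-, two- and three-process repair models with
# approximate information criteria built on a kernel surrogate likelihood
# of the ABC distance.

MODEL_CHANNELS <- list(M1 = "fast", M2 = c("fast", "slow"),
                       M3 = c("fast", "slow", "aej"))

#' Restrict a dataset suite to a model variant's channel set
#'
#' M1 keeps only the fast channel, M2 fast+slow, M3 all three; channel modes
#' within the kept set are unchanged. Channels outside the set become absent.
#' A dataset whose channels are all excluded simulates no repair (flat curve)
#' and so is fitted -- badly -- rather than dropped, which is what penalises
#' under-specified variants.
#'
#' @param datasets named list of \code{\link{dataset_spec}} objects.
#' @param variant "M1", "M2" or "M3".
#' @return restricted dataset list.
#' @export
restrict_to_variant <- function(datasets, variant) {
  keep <- MODEL_CHANNELS[[match.arg(variant, names(MODEL_CHANNELS))]]
  lapply(datasets, function(d) {
    for (ch in setdiff(CHANNELS, keep)) d$pathways[[ch]] <- pathway("absent")
    d
  })
}

#' Kernel surrogate log-likelihood of an ABC distance
#'
#' Gaussian kernel in the distance: \code{-0.5 * (rho/h)^2 - log(h)}, with
#' bandwidth \code{h} on the scale of a converged fit's final epsilon (model
#' comparison shares one bandwidth across variants). A declared stand-in
#' for an intractable likelihood: only its ordering (smaller distance, larger
#' score) and its nesting behaviour across model variants are contractual,
#' not its absolute value.
#'
#' @param rho non-negative distance(s).
#' @param bandwidth kernel bandwidth h > 0.
#' @return surrogate log-likelihood, same length as \code{rho}.
#' @export
surrogate_loglik <- function(rho, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  -0.5 * (rho / bandwidth)^2 - log(bandwidth)
}

# deviance of a point hyperparameter estimate: average the distance over a
# few fresh rate draws + simulations, then apply the surrogate kernel
point_deviance <- function(mu, sigma2, datasets, bandwidth, n_eval = 10) {
  d <- mean(vapply(seq_len(n_eval), function(i)
    score_hyper(list(mu = mu, sigma2 = sigma2), datasets)$distance,
    numeric(1)))
  -2 * surrogate_loglik(d, bandwidth)
}

#' Compare one-, two- and three-process model variants
#'
#' Fits each nested variant to the same datasets with an identical ABC SMC
#' schedule and scores it with approximate information criteria on the
#' surrogate likelihood: AIC-like = -2 max loglik + 2k, BIC-like with
#' k log(n_obs), and DIC-like = mean deviance + p_D where
#' p_D = mean deviance - deviance at the posterior mean hyperparameters.
#' k counts the hyperparameters the variant actually uses. Lower is better
#' throughout. One kernel bandwidth -- the smallest final epsilon achieved
#' by any variant -- is shared by all variants: likelihoods evaluated under
#' different kernels are not comparable, and a per-variant bandwidth would
#' reward poorly fitting models with a forgivingly wide kernel.
#'
#' @param datasets named list of \code{\link{dataset_spec}} objects.
#' @param variants subset of c("M1","M2","M3").
#' @param prior,n_particles,n_generations,epsilon_quantile passed to
#'   \code{\link{abc_smc_fit}}.
#' @param n_eval fresh simulations used for the point-deviance term.
#' @param seed optional integer seed covering all fits.
#' @return data.frame with one row per variant: k, final_epsilon, the
#'   shared bandwidth, max_loglik, aic, bic, dic, mean_deviance, p_d; plus
#'   the fitted ensembles as \code{attr(, "fits")}.
#' @examples
#' \donttest{
#' suite <- generate_suite(generator_config(ids = "D1"), seed = 1)
#' compare_models(suite, n_particles = 60, n_generations = 3, seed = 1)
#' }
#' @export
compare_models <- function(datasets, variants = c("M1", "M2", "M3"),
                           prior = hyper_prior(), n_particles = 100,
                           n_generations = 4, epsilon_quantile = 0.5,
                           n_eval = 10, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_obs <- sum(vapply(datasets, function(d) length(d$timepoints), numeric(1)))
  restricted <- lapply(variants, function(v) restrict_to_variant(datasets, v))
  names(restricted) <- variants
  fits <- lapply(variants, function(v)
    abc_smc_fit(restricted[[v]], prior = prior, n_particles = n_particles,
                n_generations = n_generations,
                epsilon_quantile = epsilon_quantile,
                on_floor = "truncate", ...))
  names(fits) <- variants
  h <- min(vapply(fits, `[[`, numeric(1), "final_epsilon"))
  rows <- lapply(variants, function(v) {
    fit <- fits[[v]]
    k <- length(fit$used_mu) + as.integer(prior$infer_sigma2)
    ll <- surrogate_loglik(fit$particles$distance, h)
    dev <- -2 * ll
    dbar <- sum(fit$particles$weight * dev)
    mu_bar <- rep(NA_real_, 4)
    for (i in fit$used_mu)
      mu_bar[i] <- sum(fit$particles$weight * fit$particles[[paste0("mu", i)]])
    s2_bar <- sum(fit$particles$weight * fit$particles$sigma2)
    dhat <- point_deviance(mu_bar, s2_bar, restricted[[v]], h, n_eval)
    p_d <- max(dbar - dhat, 0)
    data.frame(model = v, k = k, final_epsilon = fit$final_epsilon,
               bandwidth = h, max_loglik = max(ll),
               aic = -2 * max(ll) + 2 * k,
               bic = -2 * max(ll) + k * log(n_obs),
               mean_deviance = dbar, p_d = p_d, dic = dbar + p_d)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
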