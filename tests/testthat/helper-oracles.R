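# Independent closed-form oracles and small fixture builders used across the
# test files. Everything here is analytic or brute-force, never a call into
# the code paths under test.

# CDF of the completion time of one break through a two-step channel:
# Exp(a) recruitment followed by Exp(b) ligation (hypoexponential).
hypoexp_cdf <- function(t, a, b) {
  if (abs(a - b) < 1e-9) {
    # Erlang(2) limit
    1 - exp(-a * t) * (1 + a * t)
  } else {
    1 - (b * exp(-a * t) - a * exp(-b * t)) / (b - a)
  }
}

# a single-channel dataset with curve generated by an independent
# deterministic two-compartment solution plus optional noise -- used where a
# fixture must not come from the simulator under test
analytic_curve <- function(dose, tp, a, b) {
  dose * (1 - hypoexp_cdf(tp, a, b))
}

make_single_channel_dataset <- function(id = "D1", dose = 20, K = 0.3,
                                        Kprime = 0.3, channel = "aej",
                                        noise_sd = 0, tp = default_timepoints(),
                                        mu_index = 3) {
  pw <- list(fast = list(mode = "absent", mu = NA_integer_),
             slow = list(mode = "absent", mu = NA_integer_),
             aej = list(mode = "absent", mu = NA_integer_))
  pw[[channel]] <- list(mode = "full", mu = as.integer(mu_index))
  obs <- analytic_curve(dose, tp, K, Kprime)
  if (noise_sd > 0) obs <- pmax(obs + rnorm(length(tp), 0, noise_sd), 0)
  ds <- dataset_spec(id, dose, tp, obs, pw)
  stats::setNames(list(ds), id)
}

# minimal hand-built ensemble: particles at given mu vectors (list of
# length-4 numeric), equal weights unless given
make_ensemble <- function(mus, sigma2 = 1e-6, datasets, weights = NULL) {
  n <- length(mus)
  pm <- do.call(rbind, mus)
  particles <- data.frame(pm)
  names(particles) <- paste0("mu", 1:4)
  particles$sigma2 <- sigma2
  particles$weight <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  particles$distance <- 0
  structure(list(particles = particles, log = data.frame(),
                 prior = hyper_prior(), used_mu = 1:4, datasets = datasets,
                 distance_scale = "log", final_epsilon = 1),
            class = "dsb_posterior")
}
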