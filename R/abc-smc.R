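# Likelihood-free fitting of the hierarchy by ABC sequential Monte Carlo.
# Particles live in hyperparameter space; per-dataset rates are integrated
# out by redrawing them from the hierarchy at every proposal, and only the
# hyperparameters are perturbed between generations.

#' Distance between simulated and observed repair-curve suites
#'
#' Per-dataset Euclidean distance between simulated and observed repair
#' curves, summed over datasets. Two residual scales are provided:
#' \describe{
#'   \item{log (default)}{residuals on \code{log(curve + floor)} with
#'     \code{floor = floor_frac * dose}. Repair curves are exponential-like
#'     decays spanning two orders of magnitude, so log residuals weight the
#'     late slow-repair tail and the early fast drop symmetrically -- a rate
#'     that is too fast and one that is too slow misfit by comparable
#'     amounts. The additive floor, set at the measurement-noise scale,
#'     stops empty-curve values from dominating. Log residuals are
#'     scale-free, so doses contribute comparably without further
#'     normalisation.}
#'   \item{dose}{raw dose-equivalent residuals (Gy), each dataset divided
#'     by its dose so 20 Gy and 80 Gy assays contribute on the same scale
#'     (set \code{normalise = FALSE} for plain Gy residuals).}
#' }
#'
#' @param sim_curves named list of simulated dose-equivalent vectors, one per
#'   dataset, on the dataset's own timepoints.
#' @param datasets named list of \code{\link{dataset_spec}} objects.
#' @param scale "log" or "dose".
#' @param floor_frac additive floor for the log scale, as a fraction of each
#'   dataset's dose (default 0.05, the generator's default noise level).
#' @param normalise dose scale only: divide each dataset's contribution by
#'   its dose (default TRUE).
#' @return non-negative scalar; zero iff every curve matches exactly.
#' @export
abc_distance <- function(sim_curves, datasets, scale = c("log", "dose"),
                         floor_frac = 0.05, normalise = TRUE) {
  scale <- match.arg(scale)
  total <- 0
  for (id in names(datasets)) {
    d <- datasets[[id]]
    sim <- sim_curves[[id]]
    if (is.null(sim)) stop("no simulated curve for dataset ", id)
    if (length(sim) != length(d$timepoints))
      stop("grid mismatch for ", id, ": ", length(sim), " simulated vs ",
           length(d$timepoints), " observed points")
    contrib <- if (scale == "log") {
      delta <- floor_frac * d$dose_gy
      sqrt(sum((log(sim + delta) - log(d$observed + delta))^2))
    } else {
      e <- sqrt(sum((sim - d$observed)^2))
      if (normalise) e / d$dose_gy else e
    }
    total <- total + contrib
  }
  total
}

#' Uniform perturbation kernel on the hyperparameters
#'
#' Component-wise uniform kernel centred on a particle, with half-width equal
#' to half the previous population's range in that component. Proposals
#' falling outside the prior box are redrawn (componentwise) until inside.
#' Components with zero population spread are left unchanged.
#'
#' @param mu numeric vector, the particle to perturb (NA components pass
#'   through untouched).
#' @param prev_mu matrix of the previous population (rows = particles).
#' @param lower,upper prior bounds per component.
#' @param seed optional integer seed.
#' @return perturbed vector of the same length.
#' @export
abc_perturb <- function(mu, prev_mu, lower, upper, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale <- kernel_scale(prev_mu)
  out <- mu
  for (i in seq_along(mu)) {
    if (is.na(mu[i]) || scale[i] == 0) next
    repeat {
      prop <- runif(1, mu[i] - scale[i], mu[i] + scale[i])
      if (prop >= lower[i] && prop <= upper[i]) { out[i] <- prop; break }
    }
  }
  out
}

# half the componentwise range of the previous population (NA-safe)
kernel_scale <- function(prev_mu) {
  apply(prev_mu, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) 0 else (max(v) - min(v)) / 2
  })
}

#' Importance weights of an ABC SMC generation
#'
#' Standard sequential importance weights for a uniform prior and the
#' truncated uniform perturbation kernel: \code{w_m} proportional to
#' \code{1 / sum_j w_j^prev K(mu_m | mu_j^prev)}. First-generation
#' populations (sampled from the prior) get uniform weights.
#'
#' @param curr_mu matrix of current-generation particles.
#' @param prev_mu,prev_w previous population and its normalised weights;
#'   pass NULL for the first generation.
#' @param scale kernel half-widths (as used to generate \code{curr_mu}).
#' @return normalised weight vector.
#' @export
abc_smc_weights <- function(curr_mu, prev_mu = NULL, prev_w = NULL,
                            scale = NULL) {
  n <- nrow(curr_mu)
  if (is.null(prev_mu)) return(rep(1 / n, n))
  if (is.null(scale)) scale <- kernel_scale(prev_mu)
  active <- which(!is.na(curr_mu[1, ]) & scale > 0)
  w <- vapply(seq_len(n), function(m) {
    dens <- rep(1, nrow(prev_mu))
    for (i in active) {
      dens <- dens * (abs(curr_mu[m, i] - prev_mu[, i]) <= scale[i] + 1e-12) /
        (2 * scale[i])
    }
    denom <- sum(prev_w * dens)
    if (denom <= 0) stop("zero kernel denominator: proposal outside the ",
                         "support of every previous particle")
    1 / denom
  }, numeric(1))
  w / sum(w)
}

# systematic resampling: returns indices
systematic_resample <- function(w, n = length(w)) {
  u <- (runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w) / sum(w)) + 1L
}

# column names for the flattened per-dataset rate draws, e.g. K1D1, K1D1p
rate_col_names <- function(datasets) {
  cols <- character(0)
  for (id in names(datasets)) {
    dnum <- sub("^D", "", id)
    for (i in seq_along(CHANNELS)) {
      p <- datasets[[id]]$pathways[[CHANNELS[i]]]
      if (p$mode == "absent") next
      cols <- c(cols, sprintf("K%d%s", i, paste0("D", dnum)))
      if (p$mode == "full")
        cols <- c(cols, sprintf("K%d%sp", i, paste0("D", dnum)))
    }
  }
  cols
}

# draw rates for all datasets, simulate, and score one hyperparameter vector;
# returns the distance and the flattened K draws actually used for scoring
score_hyper <- function(hyper, datasets, n_replicates = 1,
                        distance_scale = "log") {
  sims <- list()
  kdraw <- numeric(0)
  for (id in names(datasets)) {
    d <- datasets[[id]]
    rates <- sample_rates(hyper, d$pathways)
    dnum <- sub("^D", "", id)
    for (i in seq_along(CHANNELS)) {
      ch <- CHANNELS[i]
      if (d$pathways[[ch]]$mode == "absent") next
      kdraw[sprintf("K%d%s", i, paste0("D", dnum))] <- rates$K[ch]
      if (d$pathways[[ch]]$mode == "full")
        kdraw[sprintf("K%d%sp", i, paste0("D", dnum))] <- rates$Kprime[ch]
    }
    x0 <- dose_to_dsb(d$dose_gy)
    acc <- 0
    for (r in seq_len(n_replicates))
      acc <- acc + measured_curve(simulate_repair(rates, x0, d$timepoints))
    sims[[id]] <- acc / n_replicates
  }
  list(distance = abc_distance(sims, datasets, scale = distance_scale),
       kdraw = kdraw)
}

#' Fit the hierarchical repair model by ABC SMC
#'
#' Sequential Monte Carlo approximation to the posterior of the
#' hyperparameters given all repair curves jointly. Generation 1 samples
#' hyperparameters from the prior (every draw accepted); each later
#' generation proposes from the weighted previous population through the
#' uniform perturbation kernel, redraws all per-dataset rates fresh from the
#' hierarchy (marginalising over them), simulates every dataset by the exact
#' stochastic algorithm, and accepts when the summed normalised distance is
#' below the generation's epsilon. Epsilon follows an adaptive schedule: the
#' \code{epsilon_quantile} quantile of the previous generation's accepted
#' distances (strictly decreasing).
#'
#' @param datasets named list of \code{\link{dataset_spec}} objects.
#' @param prior a \code{\link{hyper_prior}}.
#' @param n_particles particles per generation (>= 2).
#' @param n_generations total generations including the prior generation.
#' @param epsilon_quantile quantile of accepted distances used as the next
#'   epsilon (default 0.5, the median).
#' @param n_replicates stochastic simulations averaged per dataset per
#'   proposal (default 1: the model kernel stays stochastic).
#' @param distance_scale residual scale of \code{\link{abc_distance}}:
#'   "log" (default) or "dose".
#' @param min_acceptance floor on the per-generation acceptance rate
#'   (default 0.001).
#' @param on_floor what to do when the acceptance rate falls below the
#'   floor: "stop" (default) aborts with a diagnostic; "truncate" keeps the
#'   last completed generation and returns early with a warning (used by
#'   model comparison, where an under-specified variant legitimately stalls
#'   at its misfit floor).
#' @param seed optional integer seed; the full fit is deterministic given it.
#' @param verbose print per-generation progress.
#' @return object of class \code{dsb_posterior}: list with \code{particles}
#'   (data.frame: mu1..mu4, sigma2, weight, distance and the per-dataset K
#'   draws named as in the hierarchy, e.g. K1D1, K1D1p), \code{log}
#'   (per-generation epsilon, acceptance, ESS), \code{prior},
#'   \code{used_mu}, \code{datasets}, \code{final_epsilon}.
#' @export
abc_smc_fit <- function(datasets, prior = hyper_prior(), n_particles = 500,
                        n_generations = 8, epsilon_quantile = 0.5,
                        n_replicates = 1, distance_scale = c("log", "dose"),
                        min_acceptance = 0.001,
                        on_floor = c("stop", "truncate"), seed = NULL,
                        verbose = FALSE) {
  distance_scale <- match.arg(distance_scale)
  on_floor <- match.arg(on_floor)
  stopifnot(length(datasets) >= 1, n_particles >= 2, n_generations >= 1,
            epsilon_quantile > 0, epsilon_quantile < 1)
  if (!is.null(seed)) set.seed(seed)
  used <- used_mu_indices(datasets)
  kcols <- rate_col_names(datasets)
  N <- n_particles

  # particle coordinates: mu1..mu4 (unused components NA) plus sigma2, which
  # is a proper particle dimension when inferred and a constant column when
  # fixed (a constant column has zero kernel scale, so it is never perturbed
  # and drops out of the weights)
  lower <- c(prior$alpha, if (prior$infer_sigma2) prior$sigma2[1] else -Inf)
  upper <- c(prior$beta, if (prior$infer_sigma2) prior$sigma2[2] else Inf)
  draw_prior <- function() {
    th <- rep(NA_real_, 5)
    th[used] <- runif(length(used), prior$alpha[used], prior$beta[used])
    th[5] <- if (prior$infer_sigma2) runif(1, prior$sigma2[1], prior$sigma2[2])
             else prior$sigma2
    th
  }
  as_hyper <- function(th) list(mu = th[1:4], sigma2 = th[5])

  # generation 1: plain prior sampling, epsilon = Inf
  th_mat <- matrix(NA_real_, N, 5)
  dist_vec <- numeric(N)
  kmat <- matrix(NA_real_, N, length(kcols), dimnames = list(NULL, kcols))
  for (m in seq_len(N)) {
    th <- draw_prior()
    sc <- score_hyper(as_hyper(th), datasets, n_replicates, distance_scale)
    th_mat[m, ] <- th
    dist_vec[m] <- sc$distance
    kmat[m, names(sc$kdraw)] <- sc$kdraw
  }
  w <- rep(1 / N, N)
  log_df <- data.frame(generation = 1L, epsilon = Inf, n_proposals = N,
                       acceptance = 1, ess = N,
                       dist_q25 = unname(quantile(dist_vec, 0.25)),
                       dist_q75 = unname(quantile(dist_vec, 0.75)))
  if (verbose) message(sprintf("gen 1: eps=Inf  median dist=%.3f",
                               median(dist_vec)))
  eps <- Inf

  for (g in seq_len(n_generations - 1L) + 1L) {
    eps_new <- unname(quantile(dist_vec, epsilon_quantile))
    if (!(eps_new < eps)) eps_new <- eps * 0.99  # guard against ties
    eps <- eps_new
    if (sum(w^2) > 0 && 1 / sum(w^2) < N / 2) {
      idx <- systematic_resample(w, N)
      th_mat <- th_mat[idx, , drop = FALSE]
      dist_vec <- dist_vec[idx]
      kmat <- kmat[idx, , drop = FALSE]
      w <- rep(1 / N, N)
    }
    scale <- kernel_scale(th_mat)
    prev_th <- th_mat; prev_w <- w
    new_th <- matrix(NA_real_, N, 5)
    new_dist <- numeric(N)
    new_k <- matrix(NA_real_, N, length(kcols), dimnames = list(NULL, kcols))
    proposals <- 0L
    max_proposals <- ceiling(N / min_acceptance)
    floor_hit <- FALSE
    for (m in seq_len(N)) {
      repeat {
        proposals <- proposals + 1L
        if (proposals > max_proposals) {
          if (on_floor == "stop")
            stop(sprintf(paste0("ABC SMC aborted in generation %d: ",
                                "acceptance rate below %.4f at epsilon %.4g"),
                         g, min_acceptance, eps))
          floor_hit <- TRUE
          break
        }
        j <- sample.int(N, 1, prob = prev_w)
        th_prop <- abc_perturb(prev_th[j, ], prev_th, lower, upper)
        sc <- score_hyper(as_hyper(th_prop), datasets, n_replicates,
                          distance_scale)
        if (sc$distance <= eps) {
          new_th[m, ] <- th_prop
          new_dist[m] <- sc$distance
          new_k[m, names(sc$kdraw)] <- sc$kdraw
          break
        }
      }
      if (floor_hit) break
    }
    if (floor_hit) {
      warning(sprintf(paste0("generation %d acceptance below %.4f at epsilon ",
                             "%.4g; keeping generation %d"),
                      g, min_acceptance, eps, g - 1L), call. = FALSE)
      eps <- log_df$epsilon[nrow(log_df)]  # the kept population's epsilon
      break
    }
    w <- abc_smc_weights(new_th, prev_th, prev_w, scale)
    th_mat <- new_th; dist_vec <- new_dist; kmat <- new_k
    log_df <- rbind(log_df, data.frame(
      generation = g, epsilon = eps, n_proposals = proposals,
      acceptance = N / proposals, ess = 1 / sum(w^2),
      dist_q25 = unname(quantile(dist_vec, 0.25)),
      dist_q75 = unname(quantile(dist_vec, 0.75))))
    if (verbose) message(sprintf(
      "gen %d: eps=%.4f  acc=%.1f%%  ess=%.0f", g, eps,
      100 * N / proposals, 1 / sum(w^2)))
  }

  particles <- data.frame(th_mat[, 1:4, drop = FALSE],
                          sigma2 = th_mat[, 5], weight = w,
                          distance = dist_vec)
  names(particles)[1:4] <- paste0("mu", 1:4)
  particles <- cbind(particles, as.data.frame(kmat))
  structure(list(particles = particles, log = log_df, prior = prior,
                 used_mu = used, datasets = datasets,
                 distance_scale = distance_scale,
                 final_epsilon = if (is.finite(eps)) eps else
                   unname(median(dist_vec))),
            class = "dsb_posterior")
}

#' @export
print.dsb_posterior <- function(x, ...) {
  cat("ABC SMC posterior:", nrow(x$particles), "particles,",
      nrow(x$log), "generations, final epsilon",
      signif(x$final_epsilon, 4), "\n")
  mu <- paste0("mu", x$used_mu)
  med <- vapply(mu, function(col)
    weighted_quantile(x$particles[[col]], x$particles$weight, 0.5),
    numeric(1))
  cat("posterior median log-rates:",
      paste(mu, signif(med, 3), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dsb_posterior <- function(x, ...) x$particles

#' Weighted quantiles by inversion of the weighted empirical CDF
#'
#' Lower-interpolation convention: the smallest observed value whose
#' cumulative weight reaches the requested probability.
#'
#' @param x numeric sample.
#' @param w non-negative weights (need not be normalised).
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = 0.5) {
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(rep(NA_real_, length(probs)))
  ord <- order(x)
  x <- x[ord]; cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}
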