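#' @useDynLib dsbkinetics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile median ks.test cor approx
#' @importFrom utils read.csv write.csv
NULL

# canonical channel order used throughout the package
CHANNELS <- c("fast", "slow", "aej")

# PFGE dose-equivalent calibration: one double-strand break per 0.0286 Gy
GY_PER_DSB <- 0.0286

#' Convert radiation dose to an initial DSB count
#'
#' Uses the pulsed-field gel electrophoresis calibration 1 DSB = 0.0286 Gy to
#' convert an absorbed dose in Gray into the initial number of double-strand
#' breaks in the modelled cell population.
#'
#' @param dose_gy absorbed dose in Gray; must be non-negative.
#' @return integer DSB count, rounded to the nearest break.
#' @examples
#' dose_to_dsb(20)   # 699 breaks
#' dsb_to_dose(699)  # back to ~20 Gy
#' @export
dose_to_dsb <- function(dose_gy) {
  stopifnot(is.numeric(dose_gy))
  if (any(dose_gy < 0)) stop("dose must be non-negative (got ", min(dose_gy), " Gy)")
  as.integer(round(dose_gy / GY_PER_DSB))
}

#' Convert a DSB count to its dose equivalent
#'
#' @param n number of double-strand breaks.
#' @return dose equivalent in Gray.
#' @export
dsb_to_dose <- function(n) {
  stopifnot(is.numeric(n))
  n * GY_PER_DSB
}

#' Half-time of a first-order repair step
#'
#' The half-time of a step with rate constant \code{K} (per hour) is
#' \code{log(2)/K}, i.e. the median waiting time of the exponential step.
#'
#' @param K rate constant in 1/hr, strictly positive.
#' @return half-time in hours.
#' @examples
#' half_time(3.06)  # fast recruitment, ~0.23 h
#' half_time(0.04)  # slow recruitment, ~17.3 h
#' @export
half_time <- function(K) {
  stopifnot(is.numeric(K))
  if (any(K <= 0)) stop("rate constant K must be > 0")
  log(2) / K
}

#' Per-channel rate parameters for the repair reaction system
#'
#' Bundles recruitment (\code{K}) and ligation (\code{Kprime}) rate constants
#' with each channel's mode. Channels are \code{fast} (NHEJ), \code{slow}
#' (SSA) and \code{aej} (alternative end joining). Modes:
#' \describe{
#'   \item{full}{recruitment and ligation both active.}
#'   \item{binding_only}{the recruitment protein binds but downstream repair
#'     is ablated: ligation propensity is identically zero and complexes
#'     persist, sequestering breaks.}
#'   \item{absent}{the channel does not participate at all.}
#' }
#'
#' @param K named numeric vector of recruitment rates (1/hr); channels not
#'   named are absent.
#' @param Kprime named numeric vector of ligation rates (1/hr); required for
#'   \code{full} channels.
#' @param mode named character vector of modes; defaults to \code{full} for
#'   every channel named in \code{K}.
#' @return an object of class \code{rate_params}: list with unit-length-3
#'   vectors \code{K}, \code{Kprime}, \code{mode} in canonical channel order.
#' @examples
#' rate_params(K = c(fast = 3.06, slow = 0.04, aej = 0.34),
#'             Kprime = c(fast = 2.87, slow = 0.04, aej = 0.40))
#' @export
rate_params <- function(K, Kprime = NULL, mode = NULL) {
  Kf <- Kpf <- stats::setNames(numeric(3), CHANNELS)
  mf <- stats::setNames(rep("absent", 3), CHANNELS)
  bad <- setdiff(names(K), CHANNELS)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  Kf[names(K)] <- K
  if (!is.null(Kprime)) Kpf[names(Kprime)] <- Kprime
  if (is.null(mode)) {
    mf[names(K)] <- "full"
  } else {
    if (!all(mode %in% c("full", "binding_only", "absent")))
      stop("mode must be one of full, binding_only, absent")
    mf[names(mode)] <- mode
  }
  for (ch in CHANNELS) {
    if (mf[ch] == "absent") { Kf[ch] <- 0; Kpf[ch] <- 0 }
    if (mf[ch] == "binding_only") {
      if (Kf[ch] <= 0) stop("binding_only channel '", ch, "' needs K > 0")
      Kpf[ch] <- 0
    }
    if (mf[ch] == "full" && (Kf[ch] <= 0 || Kpf[ch] <= 0))
      stop("full channel '", ch, "' needs K > 0 and Kprime > 0")
  }
  structure(list(K = Kf, Kprime = Kpf, mode = mf), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("repair rate parameters (1/hr):\n")
  print(data.frame(channel = CHANNELS, mode = unname(x$mode),
                   K = unname(x$K), Kprime = unname(x$Kprime)))
  invisible(x)
}

#' Reaction propensities of the repair system
#'
#' For each channel i the recruitment propensity is
#' \code{K[i] * x * (E[i]/C[i])} -- mass action in the number of free breaks
#' and the free fraction of the conserved recruitment-protein pool (the pool
#' factor is absorbed into \code{K}, so \code{K} is the per-break recruitment
#' rate at an unoccupied pool). The ligation propensity is
#' \code{Kprime[i] * y[i]}, zero for binding-only channels.
#'
#' @param state list with fields \code{x} (free breaks), \code{y}
#'   (per-channel complexes, length 3) and \code{C} (per-channel pool totals).
#' @param params a \code{\link{rate_params}} object.
#' @return list with numeric vectors \code{recruit} and \code{ligate}
#'   (1/hr, canonical channel order).
#' @export
repair_propensities <- function(state, params) {
  stopifnot(inherits(params, "rate_params"))
  x <- state$x; y <- rep_len(state$y, 3); C <- rep_len(state$C, 3)
  if (x < 0 || any(y < 0) || any(C - y < -1e-9))
    stop("invalid state: counts must be non-negative and y <= C")
  recruit <- ifelse(C > 0, params$K * x * (C - y) / C, 0)
  ligate <- ifelse(params$mode == "full", params$Kprime * y, 0)
  list(recruit = stats::setNames(recruit, CHANNELS),
       ligate = stats::setNames(ligate, CHANNELS))
}

#' Simulate one stochastic realisation of DSB repair
#'
#' Exact Gillespie simulation of the recruitment/ligation reaction system
#' with conserved per-channel enzyme pools. The state is piecewise constant
#' between reaction events and is reported at the requested output grid
#' (last-event hold, preserving integer semantics).
#'
#' @param params a \code{\link{rate_params}} object.
#' @param x0 initial number of double-strand breaks (all unbound at t = 0).
#' @param t_grid strictly increasing output times in hours, starting at 0.
#' @param C per-channel recruitment-protein pool sizes; default \code{x0} for
#'   every non-absent channel (non-limiting pools).
#' @param seed optional integer; if given, \code{set.seed} is called so the
#'   trajectory is fully reproducible.
#' @return an object of class \code{repair_trajectory}: list with \code{time},
#'   integer matrix-like columns \code{x}, \code{y}, cumulative event tallies
#'   \code{cum_recruit} and \code{cum_ligate}, and \code{entry_integral}, the
#'   exact pathway-entry integral of the recruitment propensity along the
#'   realised path.
#' @examples
#' p <- rate_params(K = c(fast = 3.06), Kprime = c(fast = 2.87))
#' tr <- simulate_repair(p, x0 = 100, t_grid = c(0, 0.5, 1, 2, 4), seed = 1)
#' measured_curve(tr)
#' @export
simulate_repair <- function(params, x0, t_grid, C = NULL, seed = NULL) {
  stopifnot(inherits(params, "rate_params"))
  if (length(t_grid) == 0) stop("t_grid must be non-empty")
  if (t_grid[1] < 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and start at >= 0")
  if (x0 < 0) stop("x0 must be non-negative")
  if (is.null(C)) C <- ifelse(params$mode == "absent", 0, x0)
  C <- rep_len(C, 3)
  if (!is.null(seed)) set.seed(seed)
  m <- ssa_repair_cpp(as.numeric(params$K), as.numeric(params$Kprime),
                      as.integer(params$mode == "full"),
                      as.integer(x0), as.numeric(C), as.numeric(t_grid))
  nm <- function(base) paste0(base, "_", CHANNELS)
  traj <- list(
    time = m[, 1], x = m[, 2],
    y = `colnames<-`(m[, 3:5, drop = FALSE], nm("y")),
    cum_recruit = `colnames<-`(m[, 6:8, drop = FALSE], nm("recruit")),
    cum_ligate = `colnames<-`(m[, 9:11, drop = FALSE], nm("ligate")),
    entry_integral = `colnames<-`(m[, 12:14, drop = FALSE], nm("entry")),
    x0 = x0, C = stats::setNames(C, CHANNELS), params = params)
  class(traj) <- "repair_trajectory"
  traj
}

#' @export
print.repair_trajectory <- function(x, ...) {
  cat("repair trajectory: x0 =", x$x0, "breaks,",
      length(x$time), "output times over [0,", max(x$time), "] h\n")
  cat("  final remaining (x + sum y):",
      x$x[length(x$time)] + sum(x$y[length(x$time), ]), "breaks\n")
  invisible(x)
}

#' Dose-equivalent repair curve of a trajectory
#'
#' The PFGE observable: a break registers as damage until it is ligated, so
#' the measured signal at time t is \code{(x(t) + sum_i y_i(t)) * 0.0286} Gy.
#' Bound-but-unligated complexes (including those on binding-only channels)
#' still count as broken DNA.
#'
#' @param traj a \code{\link{simulate_repair}} trajectory.
#' @return numeric vector of dose equivalents (Gy) at the trajectory's grid.
#' @export
measured_curve <- function(traj) {
  stopifnot(inherits(traj, "repair_trajectory"))
  dsb_to_dose(traj$x + rowSums(traj$y))
}

#' Write a trajectory to CSV
#'
#' Columns: time_hr, x, y_fast, y_slow, y_aej, cum_ligated_fast,
#' cum_ligated_slow, cum_ligated_aej, dose_equiv_gy.
#'
#' @param traj a \code{repair_trajectory}.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "repair_trajectory"))
  df <- data.frame(time_hr = traj$time, x = traj$x,
                   y_fast = traj$y[, 1], y_slow = traj$y[, 2],
                   y_aej = traj$y[, 3],
                   cum_ligated_fast = traj$cum_ligate[, 1],
                   cum_ligated_slow = traj$cum_ligate[, 2],
                   cum_ligated_aej = traj$cum_ligate[, 3],
                   dose_equiv_gy = measured_curve(traj))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
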