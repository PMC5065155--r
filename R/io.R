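# Tabular and configuration I/O shared by all stages. Repair curves travel
# as long-format CSV (dataset_id, time_hr, dose_equiv_gy); the experiment
# structure (doses, phases, channel modes, hyperparameter assignments, prior)
# as a YAML config. The package functions themselves are the pipeline
# interface; scripts compose them.

#' Write repair-curve datasets to CSV
#'
#' Long format with columns dataset_id, time_hr, dose_equiv_gy.
#'
#' @param datasets named list of \code{\link{dataset_spec}} objects.
#' @param path output CSV path.
#' @export
write_repair_curves <- function(datasets, path) {
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(dataset_id = d$id, time_hr = d$timepoints,
               dose_equiv_gy = d$observed)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read repair-curve datasets from CSV
#'
#' Expects columns dataset_id, time_hr, dose_equiv_gy; rows are grouped by
#' dataset and joined with the pathway configuration and dose table to build
#' full dataset specifications.
#'
#' @param path CSV path.
#' @param pathways pathway configuration keyed by dataset id (default
#'   \code{\link{default_pathway_config}}).
#' @param dataset_table data.frame with id, dose_gy, phase (default
#'   \code{\link{default_dataset_table}}).
#' @return named list of \code{\link{dataset_spec}} objects.
#' @export
read_repair_curves <- function(path, pathways = default_pathway_config(),
                               dataset_table = default_dataset_table()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("dataset_id", "time_hr", "dose_equiv_gy")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (any(df$time_hr < 0) || any(df$dose_equiv_gy < 0))
    stop("time_hr and dose_equiv_gy must be non-negative")
  out <- list()
  for (id in unique(df$dataset_id)) {
    row <- match(id, dataset_table$id)
    if (is.na(row)) stop("unknown dataset id '", id,
                         "': not present in the dataset table")
    if (is.null(pathways[[id]]))
      stop("no pathway configuration for dataset ", id)
    sub <- df[df$dataset_id == id, ]
    sub <- sub[order(sub$time_hr), ]
    if (anyDuplicated(sub$time_hr))
      stop(id, ": duplicate timepoints")
    out[[id]] <- dataset_spec(id, dataset_table$dose_gy[row], sub$time_hr,
                              sub$dose_equiv_gy, pathways[[id]],
                              dataset_table$phase[row])
  }
  out
}

#' Write the fitted ensemble to CSV
#'
#' One row per particle: particle_id, the hyperparameters mu1..mu4 and
#' sigma2, weight, distance, and every per-dataset rate draw (K1D1, K1D1p,
#' ...).
#'
#' @param ensemble a \code{\link{abc_smc_fit}} posterior.
#' @param path output CSV path.
#' @export
write_posterior <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "dsb_posterior"))
  df <- cbind(particle_id = seq_len(nrow(ensemble$particles)),
              ensemble$particles)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read the experiment configuration as YAML
#'
#' Serialises the dataset table (dose, phase), the per-dataset channel modes
#' and hyperparameter assignments, and the hyperprior, so a whole experiment
#' is reproducible from one plain-text file. The package ships a default
#' config reproducing the eight-knockout design in
#' \code{inst/extdata/default_experiment.yaml}.
#'
#' @param path YAML file path.
#' @param pathways pathway configuration.
#' @param dataset_table dose/phase table.
#' @param prior a \code{\link{hyper_prior}}.
#' @return \code{read_experiment_config}: list with elements
#'   \code{dataset_table}, \code{pathways}, \code{prior}.
#' @export
write_experiment_config <- function(path,
                                    pathways = default_pathway_config(),
                                    dataset_table = default_dataset_table(),
                                    prior = hyper_prior()) {
  cfg <- list(
    datasets = lapply(seq_len(nrow(dataset_table)), function(i) {
      id <- dataset_table$id[i]
      list(id = id, dose_gy = dataset_table$dose_gy[i],
           phase = dataset_table$phase[i],
           channels = lapply(pathways[[id]], function(p)
             list(mode = p$mode,
                  mu = if (is.na(p$mu)) NULL else p$mu)))
    }),
    prior = list(alpha = prior$alpha, beta = prior$beta,
                 sigma2 = prior$sigma2))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(cfg$datasets, function(d)
    data.frame(id = d$id, dose_gy = d$dose_gy, phase = d$phase,
               stringsAsFactors = FALSE)))
  pw <- lapply(cfg$datasets, function(d)
    lapply(d$channels, function(ch)
      pathway(ch$mode, if (is.null(ch$mu)) NA_integer_ else ch$mu)))
  names(pw) <- tab$id
  s2 <- unlist(cfg$prior$sigma2)
  list(dataset_table = tab, pathways = pw,
       prior = hyper_prior(alpha = unlist(cfg$prior$alpha),
                           beta = unlist(cfg$prior$beta), sigma2 = s2))
}
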