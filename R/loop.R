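# The simulate -> infer -> re-simulate -> evaluate loop, and run manifests.

#' Self-consistency loop: calibrate, re-simulate, evaluate
#'
#' The central "one model fits all" check: calibrate the model on a
#' time-stamped dataset, re-simulate a dataset on the same schedule from the
#' calibrated network and from the null network (all interactions removed,
#' per-gene parameters identical), and evaluate both against the input with
#' [compare_datasets()]. A calibration that captured the coupling should
#' dominate the null model — smaller mean EMD and more KS-green cells.
#'
#' @param data a [snapshot_data()] (or a path to a counts file readable by
#'   [read_counts()]).
#' @param d0,d1,penalty passed to [fit_grn()].
#' @param cells_per_timepoint cells per timepoint of the re-simulated
#'   datasets; defaults to the median per-timepoint cell count of `data`.
#' @param seed integer root seed.
#' @param out_dir optional directory: when given, the inferred network, both
#'   re-simulated datasets, the fidelity digests and a run manifest are
#'   written there.
#' @return A list of class `grn_loop`: `fit`, `sim_network`, `sim_null`,
#'   `report_network`, `report_null`.
#' @export
self_consistency_loop <- function(data, d0, d1 = 0.1, penalty = 0.01,
                                  cells_per_timepoint = NULL, seed = 0,
                                  out_dir = NULL) {
  if (is.character(data)) data <- read_counts(data)
  stopifnot(inherits(data, "snapshot_data"))
  cells_per_timepoint <- cells_per_timepoint %||%
    as.integer(median(table(data$time)))
  fit <- fit_grn(data, d0 = d0, d1 = d1, penalty = penalty, seed = seed)
  schedule <- simulation_schedule(fit$timepoints, cells_per_timepoint)
  sim_net <- simulate(fit, seed = derive_seed(seed, 1L), schedule = schedule)
  sim_null <- simulate(fit, seed = derive_seed(seed, 2L),
                       schedule = schedule, null_network = TRUE)
  rep_net <- compare_datasets(data, sim_net, seed = derive_seed(seed, 3L))
  rep_null <- compare_datasets(data, sim_null, seed = derive_seed(seed, 3L))
  out <- structure(list(fit = fit, sim_network = sim_net,
                        sim_null = sim_null, report_network = rep_net,
                        report_null = rep_null),
                   class = "grn_loop")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_network(fit$params, file.path(out_dir, "inferred"))
    for (k in seq_along(fit$per_timepoint)) {
      write.table(fit$per_timepoint[[k]],
                  file.path(out_dir, sprintf("theta_transition_%02d.tsv", k)),
                  sep = "\t", quote = FALSE)
    }
    write_counts(sim_net, file.path(out_dir, "resimulated_network.tsv"))
    write_counts(sim_null, file.path(out_dir, "resimulated_null.tsv"))
    write.table(rep_net$ks_pvalues, file.path(out_dir, "ks_pvalues.tsv"),
                sep = "\t", quote = FALSE)
    digest <- list(
      mean_emd_network = unname(rep_net$emd_by_time),
      mean_emd_null = unname(rep_null$emd_by_time),
      mean_pvalue_network = unname(rep_net$mean_pvalue_by_time),
      mean_pvalue_null = unname(rep_null$mean_pvalue_by_time),
      green_fraction_network = rep_net$green_fraction,
      green_fraction_null = rep_null$green_fraction)
    jsonlite::write_json(digest, file.path(out_dir, "fidelity.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, list(command = "loop", seed = seed, d0 = d0,
                                 d1 = d1, penalty = penalty,
                                 cells_per_timepoint = cells_per_timepoint))
  }
  out
}

#' @export
print.grn_loop <- function(x, ...) {
  cat("Self-consistency loop (calibrate -> re-simulate -> evaluate)\n\n")
  cat("With inferred network:\n")
  print(x$report_network)
  cat("\nWith null network (interactions removed):\n")
  print(x$report_null)
  invisible(x)
}

#' Write a machine-readable run manifest
#'
#' Records the seed, configuration and package version of a run alongside
#' its outputs, so any stage can be reproduced independently.
#'
#' @param out_dir output directory.
#' @param config named list of run options.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config) {
  manifest <- list(
    package = "burstgrn",
    version = as.character(utils::packageVersion("burstgrn")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
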