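#' Run the full correlation study on the bundled dataset
#'
#' One-shot reproduction of the complete analysis: fits all 25
#' density-based and 3 association models to the bundled Regorafenib
#' monohydrate dataset with the multistart AARD objective, extracts the
#' dissolution/vaporization/solvation enthalpies, detects the
#' crossover-pressure band, runs the four self-consistency diagnostics,
#' and writes the results plus a run manifest sufficient to re-run the
#' analysis bit-identically.
#'
#' @param dir Output directory (created if needed); `NULL` writes no
#'   files.
#' @param seed Seed for the multistart draws.  The default makes the
#'   run deterministic out of the box.
#' @param n_starts Multistart points per model.
#' @param models Registry names to fit; `NULL` for all.
#' @param dataset Dataset to analyse; default the bundled fixture.
#' @return Invisibly, a list with `report` (an `scf_fit_report`),
#'   `enthalpy`, `crossover`, `consistency` and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- reproduce_study(dir = NULL, n_starts = 8)
#' res$report$group_means
#' }
reproduce_study <- function(dir = "scfsolub-report", seed = 1L,
                            n_starts = 64L, models = NULL,
                            dataset = reg_dataset()) {
  cfg <- fit_config(objective = "aard", n_starts = n_starts, seed = seed)
  report <- fit_report(dataset, models = models, config = cfg)
  enth <- enthalpies(dataset)
  cross <- crossover(dataset)
  cons <- lapply(setNames(nm = c("bartle", "mendez_teja", "kumar_johnston",
                                 "chrastil")),
                 function(m) self_consistency(dataset, m))
  manifest <- list(
    command = "reproduce_study",
    package = "scfsolub",
    version = as.character(packageVersion("scfsolub")),
    seed = seed, n_starts = n_starts,
    objective = "aard",
    models = if (is.null(models)) names(model_registry()) else models,
    n_records = n_records(dataset),
    dataset_checksum = dataset_checksum(dataset),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report$table, file.path(dir, "fit_report.csv"),
              row.names = FALSE)
    write.csv(report$group_means, file.path(dir, "group_means.csv"),
              row.names = FALSE)
    write.csv(data.frame(
      quantity = c("dH_tot_chrastil", "dH_tot_kumar_johnston",
                   "dH_tot_mean", "dH_vap", "dH_sol_signed",
                   "dH_sol_magnitude"),
      kJ_per_mol = c(enth$dH_tot_chrastil, enth$dH_tot_kumar_johnston,
                     enth$dH_tot_mean, enth$dH_vap, enth$dH_sol,
                     enth$dH_sol_magnitude)),
      file.path(dir, "enthalpies.csv"), row.names = FALSE)
    write.csv(cross$crossings, file.path(dir, "crossover.csv"),
              row.names = FALSE)
    write.csv(data.frame(model = names(cons),
                         pooled_R2 = vapply(cons, function(x) x$r2, 1)),
              file.path(dir, "self_consistency.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(report = report, enthalpy = enth, crossover = cross,
                 consistency = cons, manifest = manifest))
}

dataset_checksum <- function(dataset) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_solubility(dataset, tmp)
  unname(tools::md5sum(tmp))
}
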