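# CSV report writers and the run manifest. Every output set is accompanied
# by a manifest naming the config, fixture provenance, master seed and
# package version, which is sufficient to reproduce the run exactly.

#' Write a run manifest
#'
#' @param dir output directory.
#' @param command the command that produced the outputs.
#' @param config_path configuration file used (`NA` for defaults).
#' @param fixtures the `bbm_fixtures` bundle used.
#' @param seed master seed of the run.
#' @param extra optional named list of additional entries.
#' @return path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(dir, command, config_path, fixtures, seed,
                               extra = list()) {
  manifest <- c(
    list(
      command = command,
      config = if (is.null(config_path)) NA else config_path,
      fixture_provenance = fixtures$provenance,
      fixture_version = fixtures$version,
      fixture_seed = fixtures$seed,
      master_seed = seed,
      package = "bbmcea",
      version = as.character(packageVersion("bbmcea")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    extra
  )
  path <- file.path(dir, "run_manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Write an intermediate-outcomes comparison table to CSV
#'
#' Mirrors the published layout: one row per intermediate outcome and cost
#' component, columns for each pathway and their difference.
#'
#' @param comparison a `bbm_comparison` from [compare_strategies()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_intermediate_csv <- function(comparison, path) {
  tab <- comparison$diff_table
  names(tab) <- c("metric", comparison$reference$pathway,
                  comparison$intervention$pathway, "difference")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write the cost-effectiveness block of a comparison to CSV
#'
#' @param comparison a `bbm_comparison`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_csv <- function(comparison, path) {
  ref <- comparison$reference$econ
  int <- comparison$intervention$econ
  fields <- c("total_cost", "diagnosis_cost", "disease_cost", "dmt_cost",
              "life_years", "qalys")
  tab <- data.frame(
    metric = fields,
    ref = vapply(fields, function(f) ref[[f]], numeric(1)),
    int = vapply(fields, function(f) int[[f]], numeric(1))
  )
  names(tab) <- c("metric", comparison$reference$pathway,
                  comparison$intervention$pathway)
  tab$difference <- tab[[3]] - tab[[2]]
  write.csv(tab, path, row.names = FALSE)
  ce <- comparison$ce
  lines <- c(
    sprintf("icer,%s", format(ce$icer, digits = 15)),
    sprintf("quadrant,%s", ce$quadrant),
    sprintf("decision_at_wtp,%s", ce$decision_at_wtp)
  )
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Export a trajectory to long-format CSV
#'
#' @param trajectory a `bbm_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  occ <- trajectory$occupancy
  dims <- dim(occ)
  long <- data.frame(
    group = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    cycle = rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3]),
    state = rep(STATES, each = dims[1] * dims[2]),
    occupancy = as.vector(occ)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
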