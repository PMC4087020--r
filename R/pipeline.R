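#' Run a configured analysis pipeline
#'
#' Executes the requested stages on file inputs and writes machine-readable
#' artifacts: per-stage CSV outputs plus a JSON summary. The configuration
#' can be a named list or the path to a YAML file with the same structure.
#'
#' Recognised stages (any subset, in this order):
#' \describe{
#'   \item{`thermo`}{`input`: CSV with columns `temperature_C`, `cmc1_mM`,
#'     `cmc2_mM`, `cmc_mix_mM`, `alpha1` (or `input: "packaged"` for the
#'     packaged NaCA + SDS table). Writes `thermo.csv` with the Clint and
#'     Rubingh columns appended.}
#'   \item{`fit_cmc`}{`input`: CSV with columns `concentration_mM`,
#'     `response`; `kind`: `titration`, `conductivity` or `tension`.
#'     Writes `fit_cmc.json` with all fit fields.}
#'   \item{`simulate`}{Parameters of [toy_sim_spec()] (e.g. `n_sds`,
#'     `n_ca`, `n_steps`, `seed`). Writes `trajectory.gro` and analyses it
#'     if an `analyze` stage is present.}
#'   \item{`analyze`}{`trajectory`: GRO/XYZ path (optional when `simulate`
#'     ran); `cutoff` (default 7), `block_ns` (default 100), `window_us`
#'     (default the full trajectory span). Writes `noc.csv`,
#'     `size_distribution.csv`, `sds_content.csv`, `shape.csv`,
#'     `ions.csv`.}
#' }
#'
#' @param config Named list or YAML file path.
#' @param out_dir Output directory (created if needed).
#' @return The summary list (also written to `summary.json`), invisibly.
#' @export
run_micelle_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || !length(config)) {
    abort("Empty pipeline configuration: provide at least one stage (thermo, fit_cmc, simulate, analyze).")
  }
  known <- c("thermo", "fit_cmc", "simulate", "analyze")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(paste0("Unknown pipeline stage(s): ", paste(unknown, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(package = "micellemix",
                  version = as.character(utils::packageVersion("micellemix")),
                  config = config, outputs = list())
  traj <- NULL

  if (!is.null(config$thermo)) {
    inp <- config$thermo$input %||% "packaged"
    tbl <- if (identical(inp, "packaged")) nacasds_cmc_table() else {
      if (!file.exists(inp)) abort(paste0("thermo input not found: ", inp))
      readr::read_csv(inp, show_col_types = FALSE)
    }
    res <- rubingh_analysis(tbl)
    path <- file.path(out_dir, "thermo.csv")
    readr::write_csv(res, path)
    summary$outputs$thermo <- basename(path)
    summary$thermo <- as.list(glance(res))
  }

  if (!is.null(config$fit_cmc)) {
    st <- config$fit_cmc
    if (is.null(st$input) || !file.exists(st$input)) {
      abort("fit_cmc stage needs an existing `input` CSV.")
    }
    raw <- readr::read_csv(st$input, show_col_types = FALSE)
    if (!all(c("concentration_mM", "response") %in% names(raw))) {
      abort(paste0("fit_cmc input must have columns concentration_mM, response: ",
                   st$input))
    }
    cur <- measurement_curve(raw$concentration_mM, raw$response,
                             kind = st$kind %||% "titration")
    fit <- fit_cmc(cur)
    path <- file.path(out_dir, "fit_cmc.json")
    jsonlite::write_json(as.list(glance(fit)), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
    summary$outputs$fit_cmc <- basename(path)
    summary$fit_cmc <- as.list(glance(fit))
  }

  if (!is.null(config$simulate)) {
    spec <- do.call(toy_sim_spec, config$simulate)
    traj <- run_toy_aggregation(spec)
    path <- file.path(out_dir, "trajectory.gro")
    write_gro(traj, path)
    summary$outputs$trajectory <- basename(path)
    summary$simulate <- list(n_frames = length(traj$frames),
                             box_A = spec$box, seed = spec$seed)
  }

  if (!is.null(config$analyze)) {
    st <- config$analyze
    if (is.null(traj)) {
      if (is.null(st$trajectory) || !file.exists(st$trajectory)) {
        abort("analyze stage needs a `trajectory` file (or a simulate stage).")
      }
      traj <- if (grepl("\\.gro$", st$trajectory)) read_gro(st$trajectory)
              else read_xyz(st$trajectory)
      if (inherits(traj, "cg_frame")) traj <- cg_trajectory(list(traj))
    }
    cutoff <- st$cutoff %||% 7
    block_ns <- st$block_ns %||% 100
    times <- trajectory_times(traj)
    window <- st$window_us %||% range(times)
    noc <- noc_series(traj, cutoff = cutoff, block_ns = block_ns,
                      window_us = window)
    readr::write_csv(noc$series, file.path(out_dir, "noc.csv"))
    sdist <- size_distribution(traj, cutoff = cutoff, window_us = window)
    readr::write_csv(sdist, file.path(out_dir, "size_distribution.csv"))
    x2 <- sds_content_by_size(traj, cutoff = cutoff, window_us = window)
    readr::write_csv(x2, file.path(out_dir, "sds_content.csv"))
    shp <- shape_by_size(traj, cutoff = cutoff, window_us = window)
    readr::write_csv(shp, file.path(out_dir, "shape.csv"))
    ions <- ion_series(traj, cutoff = cutoff, block_ns = block_ns,
                       window_us = window)
    readr::write_csv(ions$partition, file.path(out_dir, "ions.csv"))
    summary$outputs$analyze <- c("noc.csv", "size_distribution.csv", "sds_content.csv",
                 "shape.csv", "ions.csv")
    summary$analyze <- list(
      cutoff_A = cutoff, block_ns = block_ns, window_us = window,
      noc_mean = noc$mean, noc_sd = noc$sd,
      x2_mean = attr(x2, "global_mean"), x2_sd = attr(x2, "global_sd"),
      condensed_mean = ions$condensed$mean, free_mean = ions$free$mean,
      frac_free = free_monomer_stats(traj, cutoff = cutoff,
                                     window_us = window)$frac_free)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summary)
}
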