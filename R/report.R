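#' Summarize one nucleus
#'
#' Collects per-cell quantities: total and axis-associated focus counts,
#' total axis length (um and mm), synapsis percentage and median
#' curvature.
#'
#' @param records association tibble from [object_axis_distances()].
#' @param axis_length tibble from [skeleton_total_length()], or `NULL`.
#' @param synapsis tibble from [synapsis_fraction()], or `NULL`.
#' @param curvature a `kappa_distribution`, or `NULL`.
#' @param cell_id identifier.
#' @param stage_label free-text prophase substage (user-supplied; staging
#'   is not computed).
#' @return One-row `CellSummary` tibble.
#' @export
summarize_cell <- function(records, axis_length = NULL, synapsis = NULL,
                           curvature = NULL, cell_id = "cell1",
                           stage_label = "") {
  n_total <- nrow(records)
  n_assoc <- if (n_total) sum(records$is_axis_associated) else 0L
  tibble::tibble(cell_id = cell_id, stage_label = stage_label,
                 n_foci_total = as.integer(n_total),
                 n_foci_axis_associated = as.integer(n_assoc),
                 axis_total_length_um =
                   if (is.null(axis_length)) NA_real_ else
                     axis_length$total_length_um,
                 axis_total_length_mm =
                   if (is.null(axis_length)) NA_real_ else
                     axis_length$total_length_mm,
                 percent_synapsed =
                   if (is.null(synapsis)) NA_real_ else
                     synapsis$percent_synapsed,
                 median_kappa =
                   if (is.null(curvature)) NA_real_ else curvature$median)
}

#' Proportion of positive cells
#'
#' The printed style of positive-cell proportions: a cell is positive
#' when its focus count reaches `min_foci`; the percentage is rounded to
#' one decimal, half up (7/74 gives 9.5, 4/37 gives 10.8).
#'
#' @param per_cell_counts integer focus counts, one per cell.
#' @param min_foci minimum count for a positive cell (default 1).
#' @return Tibble: `n_positive`, `n_cells`, `percent`.
#' @export
proportion_positive_cells <- function(per_cell_counts, min_foci = 1) {
  if (!length(per_cell_counts)) stop("no cells supplied", call. = FALSE)
  num <- sum(per_cell_counts >= min_foci)
  den <- length(per_cell_counts)
  pct <- floor(100 * num / den * 10 + 0.5) / 10  # half-up, one decimal
  tibble::tibble(n_positive = as.integer(num), n_cells = as.integer(den),
                 percent = pct)
}

default_pipeline_config <- function() {
  list(
    input = list(focus_tif = NULL, axis_tif = NULL, synapsis_tif = NULL,
                 spacing = c(0.125, 0.04, 0.04)),
    simulate = NULL,                      # a simulation_config list, or NULL
    spots = unclass(spot_params()),
    axes = unclass(axis_params()),
    distances = list(bin_width = 0.1),
    metrics = list(window = 7, resample_um = 0.3),
    report = list(cell_id = "cell1", stage_label = "", min_foci = 1),
    seed = 1L)
}

check_config_keys <- function(cfg, ref = default_pipeline_config(),
                              path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config key: ", paste0(path, unknown[1]), call. = FALSE)
  for (k in names(cfg)) {
    if (k %in% c("simulate")) next      # validated by simulation_config
    if (is.list(cfg[[k]]) && is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(cfg)
}

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()], with one block per stage.
#' Unknown keys are rejected; the resolved configuration is echoed
#' verbatim into the output directory.
#'
#' @param ... named overrides of the default blocks (`input`,
#'   `simulate`, `spots`, `axes`, `distances`, `metrics`, `report`,
#'   `seed`). Blocks are merged element-wise.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  cfg <- default_pipeline_config()
  check_config_keys(over)
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]]) && k != "simulate") {
      if (k != "input") check_config_keys(over[[k]], cfg[[k]], paste0(k, "."))
      cfg[[k]] <- modifyList(cfg[[k]], over[[k]])
    } else cfg[[k]] <- over[[k]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [read_pipeline_config()]: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @return [write_pipeline_config()]: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), function(x) x, how = "replace"),
                   path)
  invisible(path)
}

pipeline_log <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  if (!is.null(con)) writeLines(line, con)
  message(msg)
}

#' Run the full analysis pipeline on one nucleus
#'
#' Orchestrates simulation (or TIFF input), spot segmentation, axis
#' skeletonization, the 3D distance map, axis-association
#' classification, axis metrics and the per-cell summary, writing every
#' intermediate table, a manifest and a log to `out_dir`. Deterministic
#' given the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return List: `summary` (CellSummary tibble), `objects` (association
#'   table), `distance_distribution`, `skeleton`, `curvature`,
#'   `threshold`, plus `synapsis` when a synapsis channel was present.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  logcon <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(out_dir, "pipeline.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    pipeline_log(logcon, "INFO",
                 sprintf("stage %s done in %.1f s", name,
                         as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }
  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- if (inherits(config$simulate, "simulation_config"))
      config$simulate else do.call(simulation_config, config$simulate)
    nuc <- stage("simulate", simulate_nucleus(sim_cfg))
    focus_img <- nuc$channels$focus
    axis_img <- nuc$channels$axis
    syn_img <- nuc$channels$synapsis
    truth <- nuc$truth
  } else {
    sp <- config$input$spacing
    if (is.null(config$input$focus_tif) || is.null(config$input$axis_tif))
      stop("config must supply either a simulate block or input TIFF paths",
           call. = FALSE)
    focus_img <- stage("read_focus",
                       read_stack(config$input$focus_tif, sp, "focus"))
    axis_img <- stage("read_axis",
                      read_stack(config$input$axis_tif, sp, "axis"))
    syn_img <- if (!is.null(config$input$synapsis_tif))
      stage("read_synapsis",
            read_stack(config$input$synapsis_tif, sp, "synapsis")) else NULL
  }
  sp_par <- do.call(spot_params, config$spots)
  spots <- stage("spots", segment_spot_channel(focus_img, sp_par))
  pipeline_log(logcon, "INFO",
               sprintf("spots: threshold %.1f, %d seeds, %d objects",
                       spots$threshold, nrow(spots$seeds),
                       spots$labels$n_objects))
  ax_par <- do.call(axis_params, config$axes)
  axes <- stage("axes", segment_axis_channel(axis_img, ax_par))
  dmap <- stage("distance_map", distance_map_3d(axes$skeleton))
  records <- stage("distances",
                   object_axis_distances(spots$labels, spots$objects, dmap))
  ddist <- stage("distance_distribution",
                 distance_distribution(records, config$distances$bin_width))
  alen <- skeleton_total_length(axes$skeleton)
  curv <- stage("curvature",
                cell_curvature_distribution(
                  branch_curvatures(axes$skeleton,
                                    window = config$metrics$window,
                                    resample_um = config$metrics$resample_um)))
  syn <- NULL
  if (!is.null(syn_img)) {
    syn_seg <- stage("synapsis_axes", tryCatch(
      segment_axis_channel(syn_img, ax_par), error = function(e) NULL))
    syn <- synapsis_fraction(if (is.null(syn_seg)) NULL else syn_seg$skeleton,
                             axes$skeleton)
  }
  summary <- summarize_cell(records, alen, syn, curv,
                            cell_id = config$report$cell_id,
                            stage_label = config$report$stage_label)
  pipeline_log(logcon, "INFO",
               sprintf("summary: %d foci, %d axis-associated, axis %.1f um",
                       summary$n_foci_total, summary$n_foci_axis_associated,
                       summary$axis_total_length_um))
  result <- list(summary = summary, objects = records,
                 distance_distribution = ddist, skeleton = axes$skeleton,
                 curvature = curv, threshold = spots$threshold,
                 synapsis = syn, truth = truth)
  if (!is.null(out_dir)) {
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    spot_cols <- c("object_id", "CX", "CY", "CZ", "Vol_voxels", "Vol_um3",
                   "Comp", "DC_min", "DC_max", "AtCenter", "IntDen", "Min",
                   "Mean", "dist_at_center_um", "dist_min_um",
                   "dist_mean_um", "is_axis_associated")
    readr::write_csv(records[, spot_cols], file.path(out_dir, "objects.csv"))
    readr::write_csv(ddist$bins, file.path(out_dir,
                                           "distance_distribution.csv"))
    readr::write_csv(trace_branches(axes$skeleton),
                     file.path(out_dir, "skeleton_branches.csv"))
    readr::write_csv(summary, file.path(out_dir, "cell_summary.csv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("axofoci")),
      seed = config$seed,
      n_objects = summary$n_foci_total,
      n_axis_associated = summary$n_foci_axis_associated,
      threshold = spots$threshold,
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' Build a cohort table from several cell summaries
#'
#' @param summaries list of [summarize_cell()] rows (or a tibble).
#' @param group group/genotype labels, recycled.
#' @return Tibble with a `group` column and the per-cell fraction of
#'   axis-associated foci.
#' @export
cohort_table <- function(summaries, group = "wt") {
  tb <- if (is.data.frame(summaries)) summaries else
    dplyr::bind_rows(summaries)
  dplyr::mutate(tb, group = rep(group, length.out = nrow(tb)),
                frac_axis_associated =
                  ifelse(.data$n_foci_total > 0,
                         .data$n_foci_axis_associated / .data$n_foci_total,
                         NA_real_))
}
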