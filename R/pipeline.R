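#' Pipeline configuration
#'
#' Collects the knobs shared by the pipeline commands. Defaults follow the
#' measurement conventions of the source workflow: the calibration reference
#' is the `"100um_cube"` object at 1,000,000 µm³; the extracellular cuticle is
#' excluded from volume-fraction analyses; distribution thresholds are 200
#' and 1,000 µm³; defective meshes are excluded (not silently repaired).
#'
#' @param input_root directory with the `<tissue>/<cell>.<ext>` mesh layout.
#' @param anatomy_path anatomy CSV ([load_anatomy()] schema).
#' @param rules_path optional regroup-rules JSON ([load_regroup_rules()]);
#'   `NULL` means identity rules over the observed collections.
#' @param calibration_name name of the reference mesh within the collection.
#' @param known_volume_um3 its known physical volume.
#' @param policy defective-mesh policy, `"exclude"` or `"repair"`.
#' @param include_germline include the non-somatic germline pseudo-record?
#' @param exclude tissues dropped from fraction analyses.
#' @param thresholds_um3 distribution cutoffs, positive and sorted.
#' @param output_dir where the CSV reports go.
#' @param seed RNG seed (used by [pipeline_simulate()]).
#' @param timestamp write a timestamp line in CSV headers? Off by default so
#'   identical inputs give byte-identical outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_root = NULL,
                            anatomy_path = NULL,
                            rules_path = NULL,
                            calibration_name = "100um_cube",
                            known_volume_um3 = 1e6,
                            policy = c("exclude", "repair"),
                            include_germline = TRUE,
                            exclude = "cuticle",
                            thresholds_um3 = c(200, 1000),
                            output_dir = NULL,
                            seed = 1L,
                            timestamp = FALSE) {
  policy <- match.arg(policy)
  if (any(thresholds_um3 <= 0) || is.unsorted(thresholds_um3))
    stop("thresholds must be positive and sorted")
  structure(list(input_root = input_root, anatomy_path = anatomy_path,
                 rules_path = rules_path, calibration_name = calibration_name,
                 known_volume_um3 = known_volume_um3, policy = policy,
                 include_germline = include_germline, exclude = exclude,
                 thresholds_um3 = thresholds_um3, output_dir = output_dir,
                 seed = as.integer(seed), timestamp = timestamp),
            class = "pipeline_config")
}

.write_report_csv <- function(df, path, config) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("# wormvolumes %s",
                     as.character(utils::packageVersion("wormvolumes"))), con)
  if (isTRUE(config$timestamp))
    writeLines(sprintf("# generated %s", format(Sys.time(), tz = "UTC")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate every mesh in a collection
#'
#' @param root collection root directory.
#' @return A data.frame of [validate_mesh()] reports (one row per mesh) with
#'   `attr(, "any_defective")`.
#' @export
pipeline_validate <- function(root) {
  meshes <- read_collection(root)
  reps <- lapply(meshes, validate_mesh)
  out <- do.call(rbind, lapply(seq_along(meshes), function(i) {
    r <- reps[[i]]
    data.frame(cell = r$name, tissue = meshes[[i]]$collection,
               watertight = r$watertight,
               boundary_edges = r$boundary_edge_count,
               non_manifold_edges = r$non_manifold_edge_count,
               orientation_consistent = isTRUE(r$orientation_consistent),
               duplicate_vertices = r$duplicate_vertex_count,
               stringsAsFactors = FALSE)
  }))
  attr(out, "any_defective") <-
    any(!out$watertight | !out$orientation_consistent)
  out
}

#' Measure calibrated cell volumes for a collection
#'
#' Reads the collection, locates the calibration reference by name,
#' calibrates, measures every other mesh under the configured policy, applies
#' regroup rules (identity when none are configured), and writes
#' `cell_volumes.csv` to the output directory when one is set.
#'
#' @param config a [pipeline_config()] with `input_root` set.
#' @return The measurement data.frame (see [measure_cells()]), with the
#'   calibration attached as `attr(, "calibration")`.
#' @export
pipeline_measure <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  meshes <- read_collection(config$input_root)
  nm <- vapply(meshes, `[[`, "", "name")
  ref_i <- which(nm == config$calibration_name)
  if (!length(ref_i))
    stop("calibration reference '", config$calibration_name,
         "' not found in ", config$input_root)
  cal <- calibrate(meshes[[ref_i]], config$known_volume_um3)
  cells <- meshes[-ref_i]
  # drop any sibling meshes of the reference collection (calibration objects)
  keep <- vapply(cells, function(m)
    m$collection != meshes[[ref_i]]$collection, TRUE)
  cells <- cells[keep]
  if (!length(cells)) stop("no cell meshes besides the calibration reference")
  meas <- measure_cells(cells, cal, policy = config$policy)
  rules <- if (is.null(config$rules_path)) identity_rules(meas$tissue)
           else load_regroup_rules(config$rules_path)
  meas <- regroup(meas, rules)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report_csv(meas[, c("cell", "tissue", "raw_volume",
                               "calibrated_volume_um3", "watertight",
                               "excluded")],
                      file.path(config$output_dir, "cell_volumes.csv"), config)
  }
  attr(meas, "calibration") <- cal
  meas
}

#' Aggregate measurements into the tissue-composition report
#'
#' Produces the composition analytics: per-tissue summaries with and without
#' the germline, the gonad-merged tissue ranking, per-cell volumes per
#' diploid genome, and threshold distribution statistics over (a) raw cell
#' volumes and (b) volumes per diploid genome (somatic cells with defined
#' genome equivalents only). Writes `tissue_summary.csv` and
#' `distribution.csv` when an output directory is configured.
#'
#' @param measurements a [pipeline_measure()] result (or any
#'   [measure_cells()] data.frame).
#' @param records an anatomy data.frame; when `NULL`, loaded from
#'   `config$anatomy_path`.
#' @param config a [pipeline_config()].
#' @return A list: `summary` (per `config$include_germline`),
#'   `summary_incl_germline`, `summary_excl_germline`, `ranking` (gonads
#'   merged), `per_genome`, `dist_volume`, `dist_per_genome`, `extremes`.
#' @export
pipeline_report <- function(measurements, records = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(records)) {
    if (is.null(config$anatomy_path)) stop("no anatomy records or anatomy_path")
    records <- load_anatomy(config$anatomy_path)
  }
  s_incl <- summarize_tissues(measurements, records, include_germline = TRUE,
                              exclude = config$exclude)
  s_excl <- summarize_tissues(measurements, records, include_germline = FALSE,
                              exclude = config$exclude)
  ranking <- rank_tissues(merge_gonads(s_incl))
  pg <- volume_per_genome(measurements, records)
  # single-cell analyses cover somatic cells proper: the germline/rachis
  # pseudo-record and zero-nucleus extracellular structures (cuticle) are out
  somatic_cells <- records$cell[records$somatic & records$nuclei > 0L]
  pg_somatic <- pg[pg$cell %in% somatic_cells & !is.na(pg$volume_per_genome), ]
  vols_somatic <- measurements[!measurements$excluded &
                                 measurements$cell %in% somatic_cells, ]
  dist_v <- distribution_stats(vols_somatic$calibrated_volume_um3,
                               config$thresholds_um3)
  dist_pg <- distribution_stats(pg_somatic$volume_per_genome,
                                config$thresholds_um3)
  extremes <- extreme_ratios(
    measurements[measurements$cell %in% somatic_cells, , drop = FALSE], records)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    chosen <- if (config$include_germline) s_incl else s_excl
    .write_report_csv(chosen,
                      file.path(config$output_dir, "tissue_summary.csv"), config)
    dist_df <- data.frame(
      quantity = rep(c("cell_volume", "volume_per_genome"),
                     each = length(config$thresholds_um3)),
      threshold_um3 = rep(config$thresholds_um3, 2L),
      fraction_below = c(dist_v$fractions_below, dist_pg$fractions_below),
      fraction_at_or_below = c(dist_v$fractions_at_or_below,
                               dist_pg$fractions_at_or_below))
    .write_report_csv(dist_df,
                      file.path(config$output_dir, "distribution.csv"), config)
  }
  list(summary = if (config$include_germline) s_incl else s_excl,
       summary_incl_germline = s_incl,
       summary_excl_germline = s_excl,
       ranking = ranking,
       per_genome = pg,
       dist_volume = dist_v,
       dist_per_genome = dist_pg,
       extremes = extremes)
}

#' Simulate a synthetic worm per the configuration
#'
#' Thin wrapper over [generate_worm()] writing into `config$output_dir`.
#'
#' @param config a [pipeline_config()]; `output_dir` and `seed` are used.
#' @param ... passed to [generate_worm()].
#' @return The manifest, invisibly.
#' @export
pipeline_simulate <- function(config, ...) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$output_dir)) stop("output_dir required to simulate")
  generate_worm(config$output_dir, seed = config$seed, ...)
}
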