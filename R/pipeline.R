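#' Run the staged contact-point pipeline from a config
#'
#' Executes slice-level detection input (simulated from a synthetic bud, or
#' loaded from external detector/segmenter output), false-positive filtering,
#' 3D integration, clustering over a threshold sweep, and (when ground truth
#' is available) positional evaluation. Each stage writes its outputs and a
#' JSON manifest into its own subdirectory of `out_dir`, so any stage can be
#' re-run from its recorded inputs.
#'
#' The config is a named list (typically from a YAML or JSON file, see
#' [read_pipeline_config()]) with entries:
#' \describe{
#'   \item{bud}{synthetic-bud parameters (passed to [bud_spec()]); either
#'     this or `detections`+`masks_dir` must be present.}
#'   \item{noise}{optional [noise_spec()] parameters.}
#'   \item{interval_deg}{slicing increment in degrees.}
#'   \item{detections, masks_dir, center_xy, width}{external-input mode:
#'     a detection CSV, a directory of per-slice mask TIFFs named
#'     `<slice_id>.tif`, the shared rotation centre and slice width.}
#'   \item{d_sweep}{cluster-threshold sweep values (default 1, 10, 20, 30,
#'     40, 50).}
#'   \item{d}{threshold used for the reported estimates (default: the
#'     largest sweep value, or the synthetic default of
#'     [simulate_pipeline()]).}
#'   \item{seed}{RNG seed recorded in the manifest.}
#' }
#'
#' @param config named list as above.
#' @param out_dir run directory, created if missing.
#' @return (invisibly) a list with `points`, `sweep`, `contact_points`,
#'   `evaluation` (NULL without ground truth) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$bud) && is.null(config$detections))
    stop("config must name either a synthetic `bud` or external `detections`")
  if (is.null(config$interval_deg) && is.null(config$detections))
    stop("config must set `interval_deg`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  gt <- NULL

  if (!is.null(config$bud)) {
    bud_args <- config$bud
    bud_args$seed <- seed
    spec <- do.call(bud_spec, bud_args)
    noise <- do.call(noise_spec, if (is.null(config$noise)) list() else config$noise)
    sim <- simulate_pipeline(spec, config$interval_deg, noise,
                             d = config[["d"]])
    kept <- sim$kept; removed <- sim$removed; pts <- sim$points
    gt <- sim$gt_points
    d_used <- sim$d
    sim_dir <- file.path(out_dir, "simulate")
    dir.create(sim_dir, showWarnings = FALSE)
    write_detections(sim$detections, file.path(sim_dir, "detections.csv"))
    write_points(gt, file.path(sim_dir, "gt_points.csv"))
  } else {
    dets <- read_detections(config$detections)
    kept_l <- list(); removed_l <- list()
    for (sid in unique(dets$slice_id)) {
      dk <- dets[dets$slice_id == sid, , drop = FALSE]
      mask <- read_mask(file.path(config$masks_dir, paste0(sid, ".tif")),
                        theta_deg = dk$theta_deg[1], slice_id = sid)
      f <- filter_detections(dk, mask)
      kept_l[[sid]] <- f$kept; removed_l[[sid]] <- f$removed
    }
    kept <- do.call(rbind, kept_l); removed <- do.call(rbind, removed_l)
    pts <- backproject_detections(kept, config$center_xy, config$width)
    d_used <- if (!is.null(config[["d"]])) config[["d"]] else 40
  }

  filt_dir <- file.path(out_dir, "filter")
  dir.create(filt_dir, showWarnings = FALSE)
  kept$kept <- rep(TRUE, nrow(kept))
  removed$kept <- rep(FALSE, nrow(removed))
  write_detections(rbind(kept, removed), file.path(filt_dir, "detections.csv"))

  int_dir <- file.path(out_dir, "integrate")
  dir.create(int_dir, showWarnings = FALSE)
  write_points(pts, file.path(int_dir, "points.csv"))
  write_ply(pts, file.path(int_dir, "points.ply"))

  d_sweep <- if (!is.null(config$d_sweep)) unlist(config$d_sweep)
             else c(1, 10, 20, 30, 40, 50)
  sweep <- sweep_cluster_counts(pts, d_sweep)
  cl <- agglomerate(pts, d_used)
  cps <- estimate_contact_points(cl)
  clu_dir <- file.path(out_dir, "cluster")
  dir.create(clu_dir, showWarnings = FALSE)
  utils::write.csv(sweep, file.path(clu_dir, "cluster_count_vs_d.csv"),
                   row.names = FALSE)
  write_points(pts, file.path(clu_dir, "clustered_points.csv"),
               cluster_id = cl$assignment)
  write_points(cps$estimates, file.path(clu_dir, "estimates.csv"))
  write_ply(cps$estimates, file.path(clu_dir, "estimates.ply"))

  evaluation <- NULL
  if (!is.null(gt)) {
    ctr <- if (!is.null(config$bud$center_xy)) config$bud$center_xy else c(0, 0)
    evaluation <- evaluate_positions(cps, gt, axis_xy = ctr)
    eval_dir <- file.path(out_dir, "evaluate")
    dir.create(eval_dir, showWarnings = FALSE)
    utils::write.csv(
      data.frame(error = evaluation$errors, nearest_gt = evaluation$nearest_gt,
                 axis_distance = evaluation$axis_distance),
      file.path(eval_dir, "position_errors.csv"), row.names = FALSE)
  }

  manifest <- list(config = config[setdiff(names(config), "profile")],
                   seed = seed, d = d_used,
                   n_detections = nrow(kept) + nrow(removed),
                   n_kept = nrow(kept), n_removed = nrow(removed),
                   n_points = nrow(pts),
                   n_clusters = nrow(cps$estimates),
                   sweep = sweep,
                   package_version = as.character(utils::packageVersion("capitulum3d")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(points = pts, sweep = sweep, contact_points = cps,
                 evaluation = evaluation, manifest = manifest))
}

#' Load a pipeline config from YAML or JSON
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return named list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
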