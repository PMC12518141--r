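# End-to-end orchestration: image stack -> all analyses, and
# simulation -> all analyses, with deterministic CSV/JSON outputs and a
# manifest of content hashes.

#' Read a grayscale TIFF stack into image frames
#'
#' Accepts single- or multi-page TIFFs (8/16-bit integer or float); RGB pages
#' are averaged to grayscale.
#'
#' @param path TIFF file path.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval_h hours between frames (default 1/3 = 20 min).
#' @return list of [image_frame()] objects.
#' @export
read_image_stack <- function(path, pixel_size, frame_interval_h = 1 / 3) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(f) {
    m <- pages[[f]]
    if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
    image_frame(m, pixel_size = pixel_size, time = (f - 1) * frame_interval_h)
  })
}

#' Write a synthetic image stack to a TIFF file
#'
#' @param frames list of [image_frame()] objects.
#' @param path output path.
#' @export
write_image_stack <- function(frames, path) {
  imgs <- lapply(frames, function(fr) {
    m <- fr$intensity
    m <- (m - min(m)) / max(max(m) - min(m), .Machine$double.eps)
    m
  })
  tiff::writeTIFF(imgs, path)
  invisible(path)
}

#' Run configuration for the analysis pipeline
#'
#' @param pixel_size micrometres per pixel of the input images.
#' @param frame_interval_h hours between frames.
#' @param box_size,step structure-tensor box and node step in micrometres.
#' @param detect_threshold,detect_subsample defect-detection settings.
#' @param detect_min_separation merge distance for detected cores in
#'   micrometres (default 2 * box_size).
#' @param max_displacement,max_gap,min_duration trajectory-linking settings
#'   (micrometres per frame, frames, hours).
#' @param k_list neighbour orders for the kNN statistics.
#' @param string_min_nodes minimum string component size in nodes.
#' @param order_window window of the local order parameter in micrometres.
#' @param order_points sample points for the global order.
#' @param n_boot,ci_level bootstrap settings.
#' @param seed integer seed for all stochastic stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(pixel_size = 1, frame_interval_h = 1 / 3,
                       box_size = 130, step = 5.2,
                       detect_threshold = 0.1, detect_subsample = 5,
                       detect_min_separation = 2 * box_size,
                       max_displacement = 50, max_gap = 1, min_duration = 4,
                       k_list = 0:3, string_min_nodes = 3,
                       order_window = 50, order_points = 400,
                       n_boot = 1000, ci_level = 0.95, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Analyze an image stack end to end
#'
#' Per frame: director extraction, defect detection, string maps and
#' lengths, rejection field and global order. Per run: defect trajectories,
#' kth-nearest-neighbour series, coarsening series with bootstrap CI on the
#' global order, correlation curves and 1/e lengths along both axes, and
#' operational phase boundaries.
#'
#' @param frames list of [image_frame()] objects (or a TIFF path, read with
#'   the config's calibration).
#' @param config a [run_config()].
#' @param out_dir optional output directory: writes per-stage CSV tables and
#'   a JSON manifest with content hashes.
#' @return object of class `analysis_bundle`.
#' @export
analyze_stack <- function(frames, config = run_config(), out_dir = NULL) {
  if (is.character(frames))
    frames <- read_image_stack(frames, config$pixel_size,
                               config$frame_interval_h)
  if (!length(frames)) stop("need at least one frame")
  n_frames <- length(frames)
  dir_fields <- vector("list", n_frames)
  det_list <- vector("list", n_frames)
  string_rows <- list(); string_summ <- list(); series_rows <- list()
  curves_par <- vector("list", n_frames); curves_perp <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- frames[[f]]
    dirf <- extract_orientation(fr, box_size = config$box_size,
                                step = config$step)
    dir_fields[[f]] <- dirf
    qf <- director_to_q(dirf, order = 1)
    cd <- charge_density(qf)
    det <- detect_defects(cd, threshold = config$detect_threshold,
                          subsample = config$detect_subsample,
                          min_separation = config$detect_min_separation,
                          frame = f)
    det_list[[f]] <- det
    sm <- string_maps(dual_angle_maps(dirf))
    ss <- measure_strings(sm, min_nodes = config$string_min_nodes)
    if (nrow(ss$strings)) {
      st <- ss$strings; st$frame <- f
      string_rows[[f]] <- st[, c("frame", "class", "string_id", "length_um")]
    }
    su <- ss$summary; su$frame <- f
    string_summ[[f]] <- su[, c("frame", "class", "median_um", "iqr_low",
                               "iqr_high", "n_strings")]
    rej <- rejection_and_domains(dirf)
    lop <- local_order_parameter(dirf, window = config$order_window,
                                 sample_points = config$order_points)
    ci <- if (sum(is.finite(lop$values)) >= 2)
      bootstrap_ci(lop$values[is.finite(lop$values)], n_boot = config$n_boot,
                   level = config$ci_level, seed = config$seed)
    else c(lower = NA_real_, upper = NA_real_)
    xi_par <- tryCatch(
      correlation_length(correlation_function(rej, "parallel"))$xi_um,
      error = function(e) NA_real_)
    xi_perp <- tryCatch(
      correlation_length(correlation_function(rej, "perpendicular"))$xi_um,
      error = function(e) NA_real_)
    if (f <= n_frames) {
      curves_par[[f]] <- tryCatch(correlation_function(rej, "parallel"),
                                  error = function(e) NULL)
      curves_perp[[f]] <- tryCatch(correlation_function(rej, "perpendicular"),
                                   error = function(e) NULL)
    }
    series_rows[[f]] <- data.frame(
      frame = f, time_h = fr$time, defect_count = nrow(det),
      global_order = lop$mean, order_ci_low = ci[["lower"]],
      order_ci_high = ci[["upper"]], xi_parallel = xi_par, xi_perp = xi_perp,
      fraction_positive = rej$fraction_positive)
  }
  series <- do.call(rbind, series_rows)
  detections <- do.call(rbind, det_list)
  tracks <- link_trajectories(detections,
                              max_displacement = config$max_displacement,
                              max_gap = config$max_gap,
                              min_duration = config$min_duration,
                              frame_interval_h = config$frame_interval_h)
  knn_src <- if (nrow(tracks)) tracks else detections
  knn <- knn_opposite_distances(knn_src, k_list = config$k_list)
  phases <- if (nrow(series) >= 5)
    tryCatch(phase_boundaries(series$time_h, series$defect_count),
             error = function(e) NULL) else NULL
  bundle <- structure(list(
    series = series, detections = detections, tracks = tracks, knn = knn,
    strings = if (length(string_rows)) do.call(rbind, string_rows) else
      data.frame(frame = integer(0), class = character(0),
                 string_id = integer(0), length_um = numeric(0)),
    string_summary = do.call(rbind, string_summ),
    curves_parallel = curves_par, curves_perp = curves_perp,
    phase_boundaries = phases, director_fields = dir_fields,
    config = config), class = "analysis_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  s <- x$series
  cat(sprintf("<analysis_bundle> %d frames; defects %s; order %.3f -> %.3f\n",
              nrow(s), paste(range(s$defect_count), collapse = "-"),
              s$global_order[1], s$global_order[nrow(s)]))
  invisible(x)
}

#' Run a simulation and push it through the identical analysis chain
#'
#' The director is taken from the in-plane eigenvector of the simulated Q;
#' defects, strings, correlation lengths and the regime label come from the
#' same operations used on image-derived fields.
#'
#' @param params a [sim_params()].
#' @param duration total simulated time.
#' @param record_every recording cadence in time units.
#' @param out_dir optional output directory (CSV + manifest).
#' @param ... passed to [run_experiment()].
#' @return list with the `coarsening_series`, per-frame string summaries,
#'   kNN series, the `regime_label` and phase boundaries.
#' @export
simulate_and_analyze <- function(params, duration, record_every = 10,
                                 out_dir = NULL, ...) {
  ex <- run_experiment(params, duration, record_every = record_every,
                       correlations = TRUE, keep_snapshots = TRUE, ...)
  string_summ <- list()
  for (f in seq_along(ex$snapshots)) {
    st <- list(Q = ex$snapshots[[f]], t = ex$series$time[f])
    class(st) <- "sim_state"
    dirf <- sim_director(st)
    sm <- string_maps(dual_angle_maps(dirf))
    ss <- measure_strings(sm)
    su <- ss$summary; su$frame <- f; su$time <- ex$series$time[f]
    string_summ[[f]] <- su
  }
  knn <- knn_opposite_distances(do.call(rbind, ex$detections))
  regime <- classify_regime(ex)
  phases <- tryCatch(phase_boundaries(ex$series$time, ex$series$defect_count),
                     error = function(e) NULL)
  out <- list(experiment = ex, series = ex$series,
              string_summary = do.call(rbind, string_summ), knn = knn,
              regime = regime, phase_boundaries = phases)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ex$series, file.path(out_dir, "series.csv"),
                     row.names = FALSE)
    utils::write.csv(out$string_summary,
                     file.path(out_dir, "string_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(knn$summary, file.path(out_dir, "knn_summary.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(regime = regime$label, seed = params$seed))
  }
  out
}

# Write an analysis bundle as CSV tables plus a JSON manifest.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$series, file.path(out_dir, "series.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$detections, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$knn$summary, file.path(out_dir, "knn_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$strings, file.path(out_dir, "strings.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$string_summary,
                   file.path(out_dir, "string_summary.csv"), row.names = FALSE)
  # per-frame director tables
  dir.create(file.path(out_dir, "director"), showWarnings = FALSE)
  for (f in seq_along(bundle$director_fields)) {
    d <- bundle$director_fields[[f]]
    idx <- which(d$mask, arr.ind = TRUE)
    utils::write.csv(data.frame(
      x_um = (idx[, 2] - 1) * d$spacing, y_um = (idx[, 1] - 1) * d$spacing,
      alpha_rad = d$alpha[idx], coherence = d$coherence[idx]),
      file.path(out_dir, "director", sprintf("frame_%04d.csv", f)),
      row.names = FALSE)
  }
  write_manifest(out_dir, list(seed = bundle$config$seed,
                               config = unclass(bundle$config)))
  invisible(out_dir)
}

# JSON manifest: every output file with its md5 content hash, plus run
# metadata; reruns with the same inputs reproduce the hashes.
write_manifest <- function(out_dir, meta = list()) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  rel <- sub(paste0("^", out_dir, "/?"), "", files)
  manifest <- list(
    meta = meta,
    files = stats::setNames(as.list(unname(tools::md5sum(files))), rel))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read or write a run/simulation configuration as YAML
#'
#' @param params a [sim_params()] or [run_config()] to write, or a path to
#'   read.
#' @param path file path.
#' @return for `read_config`, a list; seeds are mandatory in config files.
#' @export
write_config <- function(params, path) {
  obj <- unclass(params)
  obj$.class <- class(params)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$seed)) stop("config must carry a seed for reproducibility")
  cls <- obj$.class %||% "run_config"
  obj$.class <- NULL
  if (cls == "sim_params") {
    obj$field_axis <- unlist(obj$field_axis)
    do.call(sim_params, obj[names(obj) %in% names(formals(sim_params))])
  } else {
    do.call(run_config, obj[names(obj) %in% names(formals(run_config))])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
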