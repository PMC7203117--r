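track_cols <- c("video_id", "group_id", "track_id", "frame", "x", "y")

#' Write / read a tracks table
#'
#' CSV dialect: header `video_id,group_id,track_id,frame,x,y`; frames are
#' 0-based integers and must be contiguous within each track; `x` is the
#' column and `y` the row coordinate in float px.  Reading validates the
#' header and the contiguity invariant, naming the offending track.
#'
#' @param tracks data.frame in the tracks dialect.
#' @param path file path.
#' @return `read_tracks` returns the validated data.frame.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(track_cols %in% names(tracks)))
  utils::write.csv(tracks[, track_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tr), track_cols))
    stop("bad tracks header: expected ", paste(track_cols, collapse = ","))
  for (key in split(seq_len(nrow(tr)),
                    paste(tr$video_id, tr$track_id, sep = "/"))) {
    fr <- sort(tr$frame[key])
    if (length(fr) && !all(diff(fr) == 1L))
      stop("track ", tr$track_id[key[1]], " in video ", tr$video_id[key[1]],
           " has non-contiguous frames (first record at line ",
           min(key) + 1L, ")")
  }
  tr
}

detection_cols <- c("video_id", "frame", "x", "y", "r", "score")

#' Write / read a detections table
#'
#' CSV dialect: header `video_id,frame,x,y,r,score`, 0-based frames.
#'
#' @param detections data.frame in the detections dialect.
#' @param path file path.
#' @export
write_detections <- function(detections, path) {
  stopifnot(all(detection_cols %in% names(detections)))
  utils::write.csv(detections[, detection_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), detection_cols))
    stop("bad detections header: expected ",
         paste(detection_cols, collapse = ","))
  d
}

#' Write / read a video stack as multi-page 8-bit grayscale TIFF
#'
#' @param frames array `height x width x n_frames`, values in \[0, 1\].
#' @param path file path.
#' @return `read_video_tiff` returns the array (8-bit quantized).
#' @export
write_video_tiff <- function(frames, path) {
  pages <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_video_tiff
#' @export
read_video_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
}

#' Write / read a consensus report as JSON
#'
#' The JSON carries the three-level balanced accuracies per fold turn and
#' averaged, plus the track-level confusion matrices; reading restores that
#' structure (not the per-track tables).
#'
#' @param report a `consensus_report`.
#' @param path file path.
#' @param meta optional named list (seed, config hash, ...) embedded for
#'   reproducibility.
#' @export
write_report <- function(report, path, meta = NULL) {
  stopifnot(inherits(report, "consensus_report"))
  out <- list(
    folds = lapply(report$folds, function(f)
      list(turn = f$turn, track_acc = f$track_acc,
           group_acc = f$group_acc, video_acc = f$video_acc)),
    averages = report$averages,
    confusion = lapply(report$confusion, function(cm)
      as.list(as.data.frame(cm))))
  if (!is.null(meta)) out$meta <- meta
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Pipeline configuration
#'
#' One JSON-serializable object holding every tunable of the pipeline:
#' acquisition scale (applied at reporting time only), detector, tracker,
#' atlas, backbone, feature-selection and classifier parameters, and the
#' seed.
#'
#' @param frame_interval_min minutes between frames.
#' @param pixel_size_um micrometres per pixel.
#' @param detector list: `radius_range`, `sensitivity`, `edge_frac`.
#' @param tracker a [tracker_config()].
#' @param atlas list: `R` (`NULL` = data-driven), `grouping` (one of
#'   `"tumor_neighborhood"`, `"cluster"`, `"self"`), `neighborhood_radius`,
#'   `linkage_distance`.
#' @param backbone a [backbone_spec()].
#' @param selection list: `prop` and/or `threshold` for [select_features()].
#' @param svm_cost SVM regularization constant.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(frame_interval_min = 1, pixel_size_um = 0.66,
                            detector = list(radius_range = c(3, 6),
                                            sensitivity = 0.5,
                                            edge_frac = 0.25),
                            tracker = tracker_config(),
                            atlas = list(R = NULL,
                                         grouping = "tumor_neighborhood",
                                         neighborhood_radius = 100,
                                         linkage_distance = 50),
                            backbone = backbone_spec(),
                            selection = list(prop = 0.5),
                            svm_cost = 1,
                            seed = 1L) {
  if (frame_interval_min <= 0 || pixel_size_um <= 0)
    stop("physical parameters must be positive")
  atlas$grouping <- match.arg(atlas$grouping,
                              c("tumor_neighborhood", "cluster", "self"))
  structure(list(frame_interval_min = frame_interval_min,
                 pixel_size_um = pixel_size_um, detector = detector,
                 tracker = tracker, atlas = atlas, backbone = backbone,
                 selection = selection, svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown top-level keys are rejected; missing ones fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (k in intersect(names(raw), known)) args[[k]] <- raw[[k]]
  if (!is.null(args$tracker)) {
    tk <- args$tracker[names(args$tracker) %in% names(formals(tracker_config))]
    args$tracker <- do.call(tracker_config, tk)
  }
  if (!is.null(args$backbone)) {
    bk <- args$backbone[names(args$backbone) %in% names(formals(backbone_spec))]
    args$backbone <- do.call(backbone_spec, bk)
  }
  if (!is.null(args$atlas) && !is.null(args$atlas$R) &&
      !length(args$atlas$R)) args$atlas$R <- NULL
  do.call(pipeline_config, args)
}
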