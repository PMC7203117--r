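# round half away from zero; base round() rounds half to even
round_half_away <- function(z) sign(z) * floor(abs(z) + 0.5)

#' Encode one track as a binary trajectory image
#'
#' Projects a track onto a (2R+1) x (2R+1) binary image centred on a
#' reference point: every pixel visited by the track (offset from the
#' reference, rounded to the nearest integer) is set to 1.  A stopped cell
#' leaves a single white pixel; pure drift leaves a straight line; revisited
#' pixels collapse, so the white-pixel count never exceeds the track length.
#' Points outside the region are clipped; a track entirely outside the
#' region is an error (the image would be blank).
#'
#' @param track data.frame with `x, y` (px; x = column, y = row, 0-based).
#' @param reference length-2 reference point `(xc, yc)` in the same frame of
#'   coordinates.
#' @param R region radius (px); the image is `(2R+1) x (2R+1)` and the
#'   reference maps to its centre pixel.
#' @return object of class `trajectory_image`: an integer 0/1 matrix with
#'   attributes `R` and `reference`.
#' @export
track_to_image <- function(track, reference, R) {
  if (R < 1) stop("region radius R must be >= 1")
  if (nrow(track) == 0L) stop("track is empty")
  R <- as.integer(R)
  dx <- round_half_away(track$x - reference[1])
  dy <- round_half_away(track$y - reference[2])
  keep <- abs(dx) <= R & abs(dy) <= R
  if (!any(keep))
    stop("track lies entirely outside the region (blank image)")
  img <- matrix(0L, 2L * R + 1L, 2L * R + 1L)
  img[cbind(dy[keep] + R + 1L, dx[keep] + R + 1L)] <- 1L
  structure(img, R = R, reference = as.numeric(reference),
            class = c("trajectory_image", class(img)))
}

#' Assign tracks to tumor-cell neighborhoods
#'
#' Each track is assigned to the nearest reference centre (tumor cell) whose
#' distance from the track's first position is at most `radius`; ties go to
#' the lower-indexed centre, and tracks farther than `radius` from every
#' centre are excluded.  Operates per video.
#'
#' @param tracks data.frame `video_id, track_id, frame, x, y`.
#' @param centers data.frame `video_id, group_id, xc, yc`.
#' @param radius neighborhood radius (px).
#' @return data.frame `video_id, group_id, track_id, xc, yc`, one row per
#'   assigned track.
#' @export
assign_tumor_neighborhoods <- function(tracks, centers, radius) {
  if (radius <= 0) stop("radius must be positive")
  if (nrow(centers) == 0L)
    return(data.frame(video_id = character(0), group_id = integer(0),
                      track_id = integer(0), xc = numeric(0),
                      yc = numeric(0)))
  out <- list()
  for (v in unique(tracks$video_id)) {
    tv <- tracks[tracks$video_id == v, , drop = FALSE]
    cv <- centers[centers$video_id == v, , drop = FALSE]
    if (nrow(cv) == 0L) next
    cv <- cv[order(cv$group_id), , drop = FALSE]
    for (id in unique(tv$track_id)) {
      tt <- tv[tv$track_id == id, , drop = FALSE]
      s <- tt[which.min(tt$frame), , drop = FALSE]
      d <- sqrt((cv$xc - s$x)^2 + (cv$yc - s$y)^2)
      best <- which.min(d)    # first minimum = lower-indexed centre on ties
      if (d[best] <= radius)
        out[[length(out) + 1L]] <-
          data.frame(video_id = v, group_id = cv$group_id[best],
                     track_id = id, xc = cv$xc[best], yc = cv$yc[best])
    }
  }
  if (!length(out))
    return(data.frame(video_id = character(0), group_id = integer(0),
                      track_id = integer(0), xc = numeric(0),
                      yc = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group tracks into spatial clusters
#'
#' Single-linkage agglomerative clustering of track geometric centres with a
#' distance cutoff, per video; each cluster's reference point is the mean of
#' its member track centres.  Cluster ids are ordered by the lowest member
#' track id, so the grouping is independent of input order.
#'
#' @param tracks data.frame `video_id, track_id, frame, x, y`.
#' @param linkage_distance single-linkage cut height (px).
#' @return data.frame `video_id, group_id, track_id, xc, yc`.
#' @export
cluster_tracks <- function(tracks, linkage_distance) {
  if (linkage_distance <= 0) stop("linkage_distance must be positive")
  out <- list()
  for (v in unique(tracks$video_id)) {
    tv <- tracks[tracks$video_id == v, , drop = FALSE]
    ids <- sort(unique(tv$track_id))
    cx <- vapply(ids, function(id) mean(tv$x[tv$track_id == id]), numeric(1))
    cy <- vapply(ids, function(id) mean(tv$y[tv$track_id == id]), numeric(1))
    if (length(ids) == 1L) {
      memb <- 1L
    } else {
      hc <- stats::hclust(stats::dist(cbind(cx, cy)), method = "single")
      memb <- stats::cutree(hc, h = linkage_distance)
    }
    # renumber clusters by their lowest member track id
    first_id <- vapply(unique(memb), function(m) min(ids[memb == m]),
                       numeric(1))
    relab <- match(memb, unique(memb)[order(first_id)])
    for (g in sort(unique(relab))) {
      sel <- relab == g
      out[[length(out) + 1L]] <-
        data.frame(video_id = v, group_id = g, track_id = ids[sel],
                   xc = mean(cx[sel]), yc = mean(cy[sel]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group tracks on themselves
#'
#' The "self" reference mode: each track forms its own group and its
#' reference point is its own geometric centre.
#'
#' @param tracks data.frame `video_id, track_id, frame, x, y`.
#' @return data.frame `video_id, group_id, track_id, xc, yc`.
#' @export
self_groups <- function(tracks) {
  out <- list()
  for (v in unique(tracks$video_id)) {
    tv <- tracks[tracks$video_id == v, , drop = FALSE]
    ids <- sort(unique(tv$track_id))
    out[[length(out) + 1L]] <- data.frame(
      video_id = v, group_id = seq_along(ids), track_id = ids,
      xc = vapply(ids, function(id) mean(tv$x[tv$track_id == id]), numeric(1)),
      yc = vapply(ids, function(id) mean(tv$y[tv$track_id == id]), numeric(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Data-driven default region radius
#'
#' The 98.5th percentile of the Euclidean offset of all grouped track points
#' from their reference point, rounded up; almost every point of the dataset
#' then falls inside the `(2R+1)^2` region.
#'
#' @param tracks data.frame `video_id, track_id, frame, x, y`.
#' @param groups group assignment from [assign_tumor_neighborhoods()],
#'   [cluster_tracks()] or [self_groups()].
#' @param prob percentile (default 0.985).
#' @return integer radius (px), at least 1.
#' @export
default_region_radius <- function(tracks, groups, prob = 0.985) {
  m <- merge(tracks, groups, by = c("video_id", "track_id"))
  if (nrow(m) == 0L) stop("no grouped track points")
  off <- sqrt((m$x - m$xc)^2 + (m$y - m$yc)^2)
  max(1L, as.integer(ceiling(stats::quantile(off, prob, names = FALSE))))
}

#' Build the visual atlas of trajectories
#'
#' One binary trajectory image per grouped track, referenced to the group's
#' reference point, plus a manifest linking each image to its video, group,
#' track, and condition label.  When `out_dir` is given the images are
#' written as 8-bit PNGs (background 0, trajectory 255) with deterministic
#' file names and the manifest gains an `image_path` column.  Tracks whose
#' image would be blank are skipped with a warning and recorded in the
#' manifest with `skipped = TRUE`.
#'
#' @param tracks data.frame `video_id, track_id, frame, x, y`.
#' @param groups group assignment (see [default_region_radius()]).
#' @param labels data.frame `video_id, label`.
#' @param R region radius (px); default from [default_region_radius()].
#' @param out_dir optional directory for PNG output.
#' @return list of class `atlas`: `images` (list of `trajectory_image`,
#'   `NULL` where skipped) and `manifest` (data.frame `video_id, group_id,
#'   track_id, label, skipped[, image_path]`).
#' @export
build_atlas <- function(tracks, groups, labels, R = NULL, out_dir = NULL) {
  if (is.null(R)) R <- default_region_radius(tracks, groups)
  groups <- groups[order(groups$video_id, groups$group_id,
                         groups$track_id), , drop = FALSE]
  n <- nrow(groups)
  images <- vector("list", n)
  skipped <- logical(n)
  path <- character(n)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (k in seq_len(n)) {
    g <- groups[k, ]
    tt <- tracks[tracks$video_id == g$video_id &
                   tracks$track_id == g$track_id, , drop = FALSE]
    img <- tryCatch(track_to_image(tt, c(g$xc, g$yc), R),
                    error = function(e) NULL)
    if (is.null(img)) {
      skipped[k] <- TRUE
      warning("track ", g$track_id, " in ", g$video_id,
              " lies outside the region; skipped", call. = FALSE)
      next
    }
    images[[k]] <- img
    if (!is.null(out_dir)) {
      path[k] <- file.path(out_dir, sprintf("%s_g%03d_t%06d.png",
                                            g$video_id, g$group_id,
                                            g$track_id))
      png::writePNG(img * 1.0, path[k])
    }
  }
  manifest <- data.frame(video_id = groups$video_id,
                         group_id = groups$group_id,
                         track_id = groups$track_id,
                         label = labels$label[match(groups$video_id,
                                                    labels$video_id)],
                         skipped = skipped)
  if (!is.null(out_dir)) manifest$image_path <- path
  structure(list(images = images, manifest = manifest, R = R),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat("Trajectory atlas:", sum(!x$manifest$skipped), "images",
      sprintf("(%dx%d px, R = %d),", 2 * x$R + 1, 2 * x$R + 1, x$R),
      sum(x$manifest$skipped), "skipped\n")
  invisible(x)
}
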