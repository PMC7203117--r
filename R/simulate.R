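#' Motility parameters for the random-walk cell motion model
#'
#' Cell motion is modelled as a 2D random walk with time-varying drift and
#' volatility: the per-frame displacement on each axis is
#' \eqn{\Delta x(t) = \mu_x(t) + \sigma_x(t) w(t)} with \eqn{w(t)} white
#' noise (standard Gaussian by default), independently across axes and time.
#' The drift can be a constant vector or, when `attraction > 0`, a vector of
#' that magnitude pointing from the current position toward a reference point
#' (modelling the attractiveness of a tumor cell or cluster centre).
#'
#' @param drift numeric length-2, constant drift (px/frame) on x and y.
#'   Ignored when `attraction > 0`.
#' @param volatility numeric length-2, per-frame displacement standard
#'   deviation (px/frame) on x and y; must be non-negative.
#' @param attraction non-negative scalar; when positive, the drift at every
#'   step has this magnitude (px/frame) and points toward the reference point
#'   supplied to [simulate_track()].
#' @param noise label for the white-noise distribution; only `"gaussian"`
#'   is built in.
#' @return an object of class `motility_params`.
#' @export
motility_params <- function(drift = c(0, 0), volatility = c(1, 1),
                            attraction = 0, noise = "gaussian") {
  drift <- rep_len(as.numeric(drift), 2L)
  volatility <- rep_len(as.numeric(volatility), 2L)
  if (any(!is.finite(drift)) || any(!is.finite(volatility)))
    stop("drift and volatility must be finite")
  if (any(volatility < 0))
    stop("volatility must be non-negative")
  if (!is.numeric(attraction) || length(attraction) != 1L || attraction < 0)
    stop("attraction must be a non-negative scalar")
  noise <- match.arg(noise, "gaussian")
  structure(
    list(drift_x = drift[1], drift_y = drift[2],
         volatility_x = volatility[1], volatility_y = volatility[2],
         attraction = attraction, noise = noise),
    class = "motility_params")
}

#' Simulate a single cell track
#'
#' Draws `n_steps` displacements from the drift/volatility random walk and
#' accumulates them from `start`.  With zero volatility the track is exactly
#' the cumulative sum of the drifts.
#'
#' @param params a [motility_params()] object.
#' @param start numeric length-2 starting position (x, y) in px.
#' @param n_steps number of displacements (track has `n_steps + 1` points).
#' @param reference optional length-2 point the attraction drift points at;
#'   required when `params$attraction > 0`.
#' @param t0 0-based frame index of the first point.
#' @return data.frame with columns `frame`, `x`, `y` (`n_steps + 1` rows,
#'   frames contiguous from `t0`).
#' @export
simulate_track <- function(params, start = c(0, 0), n_steps = 1L,
                           reference = NULL, t0 = 0L) {
  stopifnot(inherits(params, "motility_params"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("n_steps must be >= 1")
  n_steps <- as.integer(n_steps)
  start <- rep_len(as.numeric(start), 2L)
  if (params$attraction > 0 && is.null(reference))
    stop("attraction > 0 requires a reference point")
  x <- numeric(n_steps + 1L)
  y <- numeric(n_steps + 1L)
  x[1] <- start[1]; y[1] <- start[2]
  wx <- stats::rnorm(n_steps)
  wy <- stats::rnorm(n_steps)
  if (params$attraction == 0) {
    # constant drift: vectorized cumulative sum
    x[-1] <- start[1] + cumsum(params$drift_x + params$volatility_x * wx)
    y[-1] <- start[2] + cumsum(params$drift_y + params$volatility_y * wy)
  } else {
    for (t in seq_len(n_steps)) {
      v <- c(reference[1] - x[t], reference[2] - y[t])
      nv <- sqrt(sum(v^2))
      mu <- if (nv > 1e-12) params$attraction * v / nv else c(0, 0)
      x[t + 1L] <- x[t] + mu[1] + params$volatility_x * wx[t]
      y[t + 1L] <- y[t] + mu[2] + params$volatility_y * wy[t]
    }
  }
  data.frame(frame = seq.int(t0, length.out = n_steps + 1L), x = x, y = y)
}

#' Sample heterogeneous track lengths
#'
#' Track durations in long time-lapse experiments are strongly right-skewed:
#' many tracks are much shorter than the observation window (cells enter and
#' leave the field of view, die, or divide).  Lengths are drawn from a
#' lognormal matched by moments to the target mean/sd, rounded, and clamped
#' to `[min_length, max_length]`.
#'
#' @param n number of lengths to draw.
#' @param mean_length,sd_length target mean and standard deviation (frames).
#' @param max_length truncation bound, usually the observation window.
#' @param min_length smallest usable track (>= 2 points).
#' @return integer vector of `n` lengths in `[min_length, max_length]`.
#' @export
sample_track_lengths <- function(n, mean_length, sd_length, max_length,
                                 min_length = 2L) {
  if (n < 1) stop("n must be >= 1")
  if (max_length < 2) stop("truncation bound must be >= 2")
  if (sd_length < 0 || !is.finite(sd_length)) stop("invalid dispersion")
  if (mean_length <= 0) stop("mean_length must be positive")
  if (sd_length == 0) {
    len <- rep.int(round(mean_length), n)
  } else {
    s2 <- log(1 + (sd_length / mean_length)^2)
    len <- round(stats::rlnorm(n, meanlog = log(mean_length) - s2 / 2,
                               sdlog = sqrt(s2)))
  }
  as.integer(pmin(pmax(len, min_length), max_length))
}

#' Describe a synthetic two-condition motility experiment
#'
#' Bundles everything [simulate_experiment()] needs: how many videos per
#' condition, how many reference points (tumor cells or cluster centres) per
#' video, how many tracks move around each, the observation window, the
#' track-length distribution, the per-condition motility parameters, and the
#' frame geometry used when videos are rendered.
#'
#' Defaults emulate a long co-culture observation window: 72 frames with
#' right-skewed track lengths (mean 23, sd 17 frames), untreated cells
#' drifting toward their reference point at 0.8 px/frame and treated cells
#' at 0.1 px/frame, both with 1.2 px/frame volatility, so the conditions
#' overlap at the single-track level (short tracks barely move under
#' either condition) but separate after consensus.
#'
#' @param n_videos_per_condition,n_groups_per_video,n_tracks_per_group counts.
#' @param observation_frames length of the observation window (frames).
#' @param track_length list with `mean` and `sd` (frames) for
#'   [sample_track_lengths()].
#' @param conditions named list of [motility_params()], names must be
#'   `"treated"` and `"untreated"`.
#' @param frame list with `height`, `width` (px) and `radius` (cell radius,
#'   px) used by [render_video()].
#' @param group_spacing minimum distance between reference points (px).
#' @param start_radius tracks are born uniformly within this distance of
#'   their reference point (px).
#' @param seed integer seed making the dataset reproducible bit-for-bit.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(n_videos_per_condition = 4L,
                              n_groups_per_video = 5L,
                              n_tracks_per_group = 40L,
                              observation_frames = 72L,
                              track_length = list(mean = 23, sd = 17),
                              conditions = list(
                                untreated = motility_params(
                                  volatility = c(1.2, 1.2), attraction = 0.8),
                                treated = motility_params(
                                  volatility = c(1.2, 1.2), attraction = 0.1)),
                              frame = list(height = 512, width = 512,
                                           radius = 4),
                              group_spacing = 120,
                              start_radius = 40,
                              seed = 1L) {
  counts <- c(n_videos_per_condition, n_groups_per_video, n_tracks_per_group)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (observation_frames < 2) stop("observation_frames must be >= 2")
  if (!setequal(names(conditions), c("treated", "untreated")))
    stop("conditions must be named 'treated' and 'untreated'")
  for (p in conditions) stopifnot(inherits(p, "motility_params"))
  structure(
    list(n_videos_per_condition = as.integer(n_videos_per_condition),
         n_groups_per_video = as.integer(n_groups_per_video),
         n_tracks_per_group = as.integer(n_tracks_per_group),
         observation_frames = as.integer(observation_frames),
         track_length = track_length,
         conditions = conditions,
         frame = frame,
         group_spacing = group_spacing,
         start_radius = start_radius,
         seed = as.integer(seed)),
    class = "experiment_design")
}

# place n points uniformly in the frame (with a margin) at least min_sep apart
place_references <- function(n, height, width, margin, min_sep) {
  pts <- matrix(NA_real_, n, 2)
  k <- 0L; tries <- 0L
  while (k < n) {
    cand <- c(stats::runif(1, margin, width - 1 - margin),
              stats::runif(1, margin, height - 1 - margin))
    ok <- k == 0L ||
      all(sqrt((pts[seq_len(k), 1] - cand[1])^2 +
               (pts[seq_len(k), 2] - cand[2])^2) >= min_sep)
    tries <- tries + 1L
    if (ok) { k <- k + 1L; pts[k, ] <- cand }
    if (tries > 10000L) stop("cannot place reference points: frame too small ",
                             "for the requested group spacing")
  }
  pts
}

#' Simulate a full two-condition experiment
#'
#' Generates every video of the design: per video, reference points are
#' placed with a minimum separation, and around each reference
#' `n_tracks_per_group` tracks are simulated with the condition's motility
#' parameters, born at a uniformly random frame so each track fits inside
#' the observation window.  The same `(design, seed)` always yields a
#' bit-identical dataset.
#'
#' @param design an [experiment_design()] object.
#' @return an object of class `synthetic_dataset`: a list with
#'   * `tracks`: data.frame `video_id, group_id, track_id, frame, x, y`,
#'   * `references`: data.frame `video_id, group_id, xc, yc`,
#'   * `labels`: data.frame `video_id, label, experiment`,
#'   * `design`: the input design.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  n_vid <- 2L * design$n_videos_per_condition
  # interleave conditions so both experiments/folds see both classes
  cond <- rep(c("untreated", "treated"), design$n_videos_per_condition)
  video_id <- sprintf("vid%02d", seq_len(n_vid))
  # first half of the videos of each condition = experiment 1, rest = 2
  experiment <- ifelse(seq_len(n_vid) <= n_vid / 2, 1L, 2L)
  margin <- max(design$start_radius + 10, 50)
  tl <- design$track_length
  tracks <- vector("list", n_vid)
  refs <- vector("list", n_vid)
  tid <- 0L
  for (v in seq_len(n_vid)) {
    pts <- place_references(design$n_groups_per_video,
                            design$frame$height, design$frame$width,
                            margin, design$group_spacing)
    refs[[v]] <- data.frame(video_id = video_id[v],
                            group_id = seq_len(design$n_groups_per_video),
                            xc = pts[, 1], yc = pts[, 2])
    params <- design$conditions[[cond[v]]]
    per_group <- vector("list", design$n_groups_per_video)
    for (g in seq_len(design$n_groups_per_video)) {
      lens <- sample_track_lengths(design$n_tracks_per_group, tl$mean, tl$sd,
                                   design$observation_frames)
      gtr <- vector("list", design$n_tracks_per_group)
      for (k in seq_len(design$n_tracks_per_group)) {
        tid <- tid + 1L
        n_steps <- lens[k] - 1L
        birth <- sample.int(design$observation_frames - lens[k] + 1L, 1L) - 1L
        theta <- stats::runif(1, 0, 2 * pi)
        rr <- design$start_radius * sqrt(stats::runif(1))
        start <- c(pts[g, 1] + rr * cos(theta), pts[g, 2] + rr * sin(theta))
        tr <- simulate_track(params, start, n_steps,
                             reference = pts[g, ], t0 = birth)
        gtr[[k]] <- data.frame(video_id = video_id[v], group_id = g,
                               track_id = tid, frame = tr$frame,
                               x = tr$x, y = tr$y)
      }
      per_group[[g]] <- do.call(rbind, gtr)
    }
    tracks[[v]] <- do.call(rbind, per_group)
  }
  structure(
    list(tracks = do.call(rbind, tracks),
         references = do.call(rbind, refs),
         labels = data.frame(video_id = video_id, label = cond,
                             experiment = experiment),
         design = design),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic motility dataset\n")
  cat("  videos:", nrow(x$labels),
      sprintf("(%d treated / %d untreated)\n",
              sum(x$labels$label == "treated"),
              sum(x$labels$label == "untreated")))
  cat("  groups:", nrow(x$references), "\n")
  cat("  tracks:", length(unique(x$tracks$track_id)),
      " points:", nrow(x$tracks), "\n")
  invisible(x)
}

#' Per-frame detection tables with ground-truth identities
#'
#' Turns the simulated tracks of one video into the detection tables the
#' tracker consumes, keeping the generating `track_id` so links can be scored
#' against the ground truth.
#'
#' @param dataset a `synthetic_dataset`.
#' @param video a `video_id` present in the dataset.
#' @param jitter_sd optional Gaussian localization noise (px) added to the
#'   true positions.
#' @return data.frame `frame, x, y, true_track` sorted by frame.
#' @export
detections_from_tracks <- function(dataset, video, jitter_sd = 0) {
  tr <- dataset$tracks[dataset$tracks$video_id == video, ]
  if (nrow(tr) == 0L) stop("unknown video: ", video)
  out <- data.frame(frame = tr$frame,
                    x = tr$x + stats::rnorm(nrow(tr), 0, jitter_sd),
                    y = tr$y + stats::rnorm(nrow(tr), 0, jitter_sd),
                    true_track = tr$track_id)
  out[order(out$frame), ]
}

#' Render one video as a grayscale image stack
#'
#' Draws each live cell as a filled disk of the configured radius on a black
#' background, one frame per time index, with optional additive Gaussian
#' noise.  Intensities are in \[0, 1\] (cells at 1).
#'
#' @param tracks data.frame with `frame, x, y` (and anything else) for one
#'   video; positions are 0-based px with x = column, y = row.
#' @param geometry list with `height`, `width`, `radius` (px).
#' @param n_frames number of frames; defaults to `max(frame) + 1`.
#' @param noise_sd sd of additive Gaussian noise (intensity units).
#' @return numeric array `height x width x n_frames` with values in \[0, 1\].
#' @export
render_video <- function(tracks, geometry, n_frames = NULL, noise_sd = 0) {
  h <- geometry$height; w <- geometry$width; r <- geometry$radius
  if (r <= 0 || 2 * r >= min(h, w))
    stop("frame geometry too small for the configured cell radius")
  if (is.null(n_frames)) n_frames <- max(tracks$frame) + 1L
  frames <- array(0, c(h, w, n_frames))
  # pixel centers at 0-based integer coordinates: row index i -> y = i - 1
  for (t in seq_len(n_frames) - 1L) {
    at <- tracks[tracks$frame == t, , drop = FALSE]
    if (nrow(at)) {
      fr <- frames[, , t + 1L]
      for (k in seq_len(nrow(at))) {
        rows <- max(1L, floor(at$y[k] - r) + 1L):min(h, ceiling(at$y[k] + r) + 1L)
        cols <- max(1L, floor(at$x[k] - r) + 1L):min(w, ceiling(at$x[k] + r) + 1L)
        if (!length(rows) || !length(cols)) next
        dy2 <- ((rows - 1) - at$y[k])^2
        dx2 <- ((cols - 1) - at$x[k])^2
        fr[rows, cols][outer(dy2, dx2, "+") <= r^2] <- 1
      }
      frames[, , t + 1L] <- fr
    }
  }
  if (noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), 0, noise_sd)
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  frames
}
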