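#' Low-level kinematic series and scalars for one track
#'
#' The eight low-level features of the kinematic baseline, with the time
#' step taken as one frame (physical units are applied at reporting time):
#' * `f1` tangential speed magnitude per step (px/frame),
#' * `f2` discrete curvature: turning angle divided by the local arc length
#'   (the mean of the two adjacent segment lengths),
#' * `f3` angular speed magnitude (turning angle per frame),
#' * `f4` turning angle between consecutive displacement vectors, taken as
#'   magnitude in \[0, pi\],
#' * `f5` distance of each point to the track's geometric centre (px),
#' * `f6` mean distance of track points to the group (cancer-cell/cluster)
#'   centre (px),
#' * `f7` diffusion coefficient (px^2/frame): slope/4 of an ordinary
#'   least-squares fit to the mean squared displacement over the first
#'   quartile of lags, floored at 0,
#' * `f8` directional persistence: net displacement over total path length,
#'   in \[0, 1\] (0 for a closed or degenerate path).
#'
#' @param track data.frame with `x, y` ordered in time (>= 3 points).
#' @param group_center length-2 reference point for `f6`.
#' @return list with vectors `f1..f5` and scalars `f6, f7, f8`.
#' @export
low_level_series <- function(track, group_center) {
  L <- nrow(track)
  if (L < 3L)
    stop("kinematic descriptors need a track of at least 3 points")
  x <- track$x; y <- track$y
  dx <- diff(x); dy <- diff(y)
  seg <- sqrt(dx^2 + dy^2)
  f1 <- seg                                  # dt = 1 frame
  # turning angle between consecutive displacement vectors
  a <- atan2(dy, dx)
  dth <- diff(a)
  dth <- atan2(sin(dth), cos(dth))           # wrap to (-pi, pi]
  f4 <- abs(dth)
  f3 <- f4                                   # per frame
  arc <- (seg[-length(seg)] + seg[-1]) / 2
  f2 <- ifelse(arc > 0, f4 / arc, 0)
  cx <- mean(x); cy <- mean(y)
  f5 <- sqrt((x - cx)^2 + (y - cy)^2)
  f6 <- mean(sqrt((x - group_center[1])^2 + (y - group_center[2])^2))
  f7 <- max(0, msd_slope(x, y) / 4)
  total <- sum(seg)
  net <- sqrt((x[L] - x[1])^2 + (y[L] - y[1])^2)
  f8 <- if (total > 0) min(1, net / total) else 0
  list(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5,
       f6 = f6, f7 = f7, f8 = f8)
}

# OLS slope of MSD(tau) over lags 1..max(2, floor((L-1)/4))
msd_slope <- function(x, y) {
  L <- length(x)
  max_lag <- max(2L, min(L - 1L, (L - 1L) %/% 4L))
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(tau) {
    i <- seq_len(L - tau)
    mean((x[i + tau] - x[i])^2 + (y[i + tau] - y[i])^2)
  }, numeric(1))
  unname(stats::coef(stats::lm(msd ~ lags))[2])
}

# Shannon entropy (bits) of a series from a fixed-bin-count equal-width
# histogram over the series' own range; constant series -> 0
shannon_entropy <- function(z, bins = 16L) {
  z <- z[is.finite(z)]
  if (length(z) == 0L) return(0)
  rng <- range(z)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  p <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  p <- p[p > 0] / length(z)
  -sum(p * log2(p))
}

# mean, variance, skewness, kurtosis, entropy of a series; degenerate
# (constant or too-short) series get 0 by convention for the shape moments
series_moments <- function(z, bins = 16L) {
  m <- mean(z)
  v <- if (length(z) > 1L) stats::var(z) else 0
  if (!is.finite(v)) v <- 0
  sk <- if (v > 0) e1071::skewness(z, type = 1) else 0
  ku <- if (v > 0) e1071::kurtosis(z, type = 1) else 0
  if (!is.finite(sk)) sk <- 0
  if (!is.finite(ku)) ku <- 0
  c(mean = m, var = v, skew = sk, kurt = ku,
    entropy = shannon_entropy(z, bins))
}

#' The 28-descriptor kinematic vector of one track
#'
#' For each of the five series `f1..f5`, the first four statistical moments
#' (mean, variance, skewness, kurtosis) plus the Shannon entropy along time
#' (25 values), followed by the three scalars `f6` (mean distance to group
#' centre), `f7` (diffusion coefficient) and `f8` (directional
#' persistence): 28 values in a fixed documented order.
#'
#' @param track data.frame with `x, y` (>= 3 points).
#' @param group_center length-2 reference point.
#' @param entropy_bins bin count of the entropy histogram.
#' @return named numeric vector of length 28
#'   (`f1_mean, f1_var, ..., f5_entropy, f6, f7, f8`).
#' @export
descriptor_vector <- function(track, group_center, entropy_bins = 16L) {
  s <- low_level_series(track, group_center)
  out <- c(vapply(1:5, function(i)
    series_moments(s[[paste0("f", i)]], entropy_bins), numeric(5)))
  names(out) <- as.vector(outer(c("mean", "var", "skew", "kurt", "entropy"),
                                paste0("f", 1:5),
                                function(a, b) paste(b, a, sep = "_")))
  out <- c(out, f6 = s$f6, f7 = s$f7, f8 = s$f8)
  stopifnot(length(out) == 28L, all(is.finite(out)))
  out
}

#' Kinematic feature table for a set of grouped tracks
#'
#' One row per grouped track: identifiers plus the 28 named kinematic
#' descriptors, each computed against the track's group reference point.
#' Tracks shorter than 3 points are dropped with a warning.
#'
#' @param tracks data.frame `video_id, track_id, frame, x, y`.
#' @param groups group assignment (`video_id, group_id, track_id, xc, yc`).
#' @return data.frame with `video_id, group_id, track_id` + 28 columns.
#' @export
kinematic_table <- function(tracks, groups) {
  rows <- vector("list", nrow(groups))
  drop <- 0L
  for (k in seq_len(nrow(groups))) {
    g <- groups[k, ]
    tt <- tracks[tracks$video_id == g$video_id &
                   tracks$track_id == g$track_id, , drop = FALSE]
    tt <- tt[order(tt$frame), , drop = FALSE]
    if (nrow(tt) < 3L) { drop <- drop + 1L; next }
    v <- descriptor_vector(tt, c(g$xc, g$yc))
    rows[[k]] <- cbind(data.frame(video_id = g$video_id,
                                  group_id = g$group_id,
                                  track_id = g$track_id),
                       as.data.frame(as.list(v)))
  }
  if (drop > 0L)
    warning(drop, " track(s) shorter than 3 points dropped", call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
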