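#' Windowed drift/volatility estimates for one track
#'
#' Under the random-walk motion model the drift and squared volatility are
#' the expected value and variance of the per-frame displacement.  Assuming
#' local ergodicity they are estimated, per axis independently, as the sample
#' mean and the mean squared deviation (about the window mean) of the `T`
#' most recent displacements ending at frame `t`.
#'
#' A track with fewer than two displacements carries no usable history; it
#' gets cold-start defaults (zero drift, a population-prior volatility) and
#' is flagged.
#'
#' @param track data.frame with `frame, x, y`, frames contiguous.
#' @param t frame at which to estimate; defaults to the track's last frame.
#' @param window maximum number of recent displacements `T` to use.
#' @param cold_sd prior per-axis displacement sd (px/frame) for cold starts.
#' @return object of class `drift_volatility`: list with `mu_x, mu_y, var_x,
#'   var_y`, `window_T` (displacements actually used; 0 for cold start) and
#'   `cold_start` flag.
#' @export
estimate_drift_volatility <- function(track, t = NULL, window = 10L,
                                      cold_sd = 2) {
  if (window < 1) stop("window must be >= 1")
  if (is.null(t)) t <- max(track$frame)
  tr <- track[track$frame <= t, , drop = FALSE]
  tr <- tr[order(tr$frame), , drop = FALSE]
  dx <- diff(tr$x); dy <- diff(tr$y)
  n <- length(dx)
  if (n < 2L) {
    return(structure(list(mu_x = 0, mu_y = 0,
                          var_x = cold_sd^2, var_y = cold_sd^2,
                          window_T = 0L, cold_start = TRUE),
                     class = "drift_volatility"))
  }
  use <- min(window, n)
  dx <- dx[(n - use + 1L):n]; dy <- dy[(n - use + 1L):n]
  mx <- mean(dx); my <- mean(dy)
  structure(list(mu_x = mx, mu_y = my,
                 var_x = mean((dx - mx)^2), var_y = mean((dy - my)^2),
                 window_T = use, cold_start = FALSE),
            class = "drift_volatility")
}

# return a copy with per-axis sd floored (half-pixel by default) so locally
# stationary cells never produce infinite densities
floor_volatility <- function(dv, sigma_floor = 0.5) {
  dv$var_x <- max(dv$var_x, sigma_floor^2)
  dv$var_y <- max(dv$var_y, sigma_floor^2)
  dv
}

#' Gaussian displacement likelihood
#'
#' Joint density of an (x, y) displacement under the track's current
#' drift/volatility estimate, assuming independent axes:
#' \deqn{f(dx, dy) = \frac{1}{2\pi\sigma_x\sigma_y}
#'   e^{-\left(\frac{(dx-\mu_x)^2}{2\sigma_x^2} +
#'             \frac{(dy-\mu_y)^2}{2\sigma_y^2}\right)}}
#'
#' @param dx,dy displacement (px).
#' @param dv a `drift_volatility` (variances must be positive, i.e. already
#'   floored).
#' @return the density value.
#' @export
displacement_likelihood <- function(dx, dy, dv) {
  if (any(!is.finite(c(dx, dy)))) stop("non-finite displacement")
  if (dv$var_x <= 0 || dv$var_y <= 0)
    stop("variances must be positive (apply the sigma floor first)")
  1 / (2 * pi * sqrt(dv$var_x * dv$var_y)) *
    exp(-((dx - dv$mu_x)^2 / (2 * dv$var_x) +
          (dy - dv$mu_y)^2 / (2 * dv$var_y)))
}

# inverse density at a Mahalanobis distance of 3 on each axis: the
# non-assignment gate for a track with this drift/volatility
gate_cost <- function(dv) {
  2 * pi * sqrt(dv$var_x * dv$var_y) * exp(9)
}

#' Build the frame-to-frame assignment cost matrix
#'
#' Entry (n, m) is the inverse of the probability density that track `n`
#' (at its last position, moving per its drift/volatility estimate) produced
#' detection `m` in the next frame; minimizing total cost maximizes the
#' overall assignment probability.  Entries are capped at a finite maximum.
#'
#' @param tails data.frame `x, y`: last position of each active track.
#' @param detections data.frame `x, y`: candidate positions in the next frame.
#' @param dvs list of `drift_volatility`, one per row of `tails`.
#' @param sigma_floor half-pixel volatility floor (px).
#' @param cold_sd prior sd for brand-new tracks (px/frame), used for the
#'   new-track gate on the detection side.
#' @param max_cost cap on matrix entries.
#' @return object of class `cost_matrix`: list with `entries` (n x m),
#'   `row_gates` (per-track non-assignment cost), `col_gates` (per-detection
#'   new-track cost).
#' @export
build_cost_matrix <- function(tails, detections, dvs, sigma_floor = 0.5,
                              cold_sd = 2, max_cost = 1e12) {
  n <- nrow(tails); m <- nrow(detections)
  entries <- matrix(numeric(0), n, m)
  row_gates <- numeric(n)
  if (n > 0L) {
    dvs <- lapply(dvs, floor_volatility, sigma_floor = sigma_floor)
    row_gates <- vapply(dvs, gate_cost, numeric(1))
    if (m > 0L) {
      entries <- matrix(0, n, m)
      for (i in seq_len(n)) {
        d <- displacement_likelihood(detections$x - tails$x[i],
                                     detections$y - tails$y[i], dvs[[i]])
        entries[i, ] <- pmin(1 / d, max_cost)
      }
    }
  }
  cold <- structure(list(mu_x = 0, mu_y = 0, var_x = cold_sd^2,
                         var_y = cold_sd^2, window_T = 0L, cold_start = TRUE),
                    class = "drift_volatility")
  structure(list(entries = entries,
                 row_gates = pmin(row_gates, max_cost),
                 col_gates = rep(min(gate_cost(cold), max_cost), m)),
            class = "cost_matrix")
}

#' Gated one-to-one assignment of tracks to detections
#'
#' Solves the rectangular assignment problem by augmenting the cost matrix
#' with non-assignment rows/columns at the gate costs, then runs the
#' shortest-augmenting-path solver.  A matched pair whose cost exceeds the
#' track's gate is unmatched (the track terminates, the detection is free to
#' seed a new track).
#'
#' @param cm a `cost_matrix` from [build_cost_matrix()].
#' @return list with `matches` (data.frame `row, col`), `unmatched_rows`,
#'   `unmatched_cols`.
#' @export
assign_detections <- function(cm) {
  stopifnot(inherits(cm, "cost_matrix"))
  n <- length(cm$row_gates); m <- length(cm$col_gates)
  if (n == 0L || m == 0L) {
    return(list(matches = data.frame(row = integer(0), col = integer(0)),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)))
  }
  big <- 1e15
  A <- matrix(big, n + m, n + m)
  A[seq_len(n), seq_len(m)] <- cm$entries
  A[cbind(seq_len(n), m + seq_len(n))] <- cm$row_gates
  A[cbind(n + seq_len(m), seq_len(m))] <- cm$col_gates
  A[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- solve_assignment(A)
  row <- integer(0); col <- integer(0)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && cm$entries[i, j] <= cm$row_gates[i]) {
      row <- c(row, i); col <- c(col, j)
    }
  }
  list(matches = data.frame(row = row, col = col),
       unmatched_rows = setdiff(seq_len(n), row),
       unmatched_cols = setdiff(seq_len(m), col))
}

#' Default tracker configuration
#'
#' @param window drift/volatility estimation window `T` (displacements).
#' @param sigma_floor volatility floor (px).
#' @param cold_sd cold-start prior displacement sd (px/frame).
#' @param prior_strength pseudo-displacement count by which the volatility
#'   entering the assignment cost is shrunk toward the cold-start prior;
#'   regularizes the very noisy 2-5-sample variance estimates of young
#'   tracks so genuine displacements are not gated away.
#' @param max_cost cap on cost-matrix entries.
#' @return named list.
#' @export
tracker_config <- function(window = 10L, sigma_floor = 0.5, cold_sd = 2,
                           prior_strength = 2, max_cost = 1e12) {
  stopifnot(window >= 1, sigma_floor > 0, cold_sd > 0, prior_strength >= 0,
            max_cost > 0)
  list(window = as.integer(window), sigma_floor = sigma_floor,
       cold_sd = cold_sd, prior_strength = prior_strength,
       max_cost = max_cost)
}

# shrink a windowed volatility estimate toward the cold-start prior by
# `a` pseudo-displacements (cost-stage regularization; the estimator
# itself stays the exact windowed sample variance)
shrink_volatility <- function(dv, cold_sd, a) {
  n <- dv$window_T
  dv$var_x <- (n * dv$var_x + a * cold_sd^2) / (n + a)
  dv$var_y <- (n * dv$var_y + a * cold_sd^2) / (n + a)
  dv
}

#' Link detections across frames into tracks
#'
#' Strictly pairwise frame i to frame i+1 linking: for every consecutive
#' frame pair, a gated optimal assignment (inverse Gaussian displacement
#' likelihood costs) extends, terminates, or creates tracks.  Unmatched
#' detections seed new tracks; unmatched tracks terminate immediately (no
#' gap closing).
#'
#' @param detections data.frame with `frame, x, y` (0-based contiguous frame
#'   indices; a frame with no detections terminates all active tracks).
#' @param config a [tracker_config()].
#' @param video_id id stamped on the output tracks.
#' @return data.frame `video_id, group_id, track_id, frame, x, y` (group_id
#'   is `NA`; grouping is a later, atlas-stage concern).  Track ids are in
#'   birth order.
#' @export
link_video <- function(detections, config = tracker_config(),
                       video_id = "vid01") {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  if (nrow(detections) == 0L)
    return(data.frame(video_id = character(0), group_id = integer(0),
                      track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  frames <- seq.int(min(detections$frame), max(detections$frame))
  active <- list()    # each: list(frames, xs, ys)
  done <- list()
  next_id <- 1L
  start_tracks <- function(det) {
    lapply(seq_len(nrow(det)), function(k)
      list(frames = det$frame[k], xs = det$x[k], ys = det$y[k]))
  }
  first <- detections[detections$frame == frames[1], , drop = FALSE]
  active <- start_tracks(first)
  for (t in frames[-1]) {
    det <- detections[detections$frame == t, , drop = FALSE]
    n <- length(active)
    if (n == 0L) { active <- start_tracks(det); next }
    tails <- data.frame(
      x = vapply(active, function(a) a$xs[length(a$xs)], numeric(1)),
      y = vapply(active, function(a) a$ys[length(a$ys)], numeric(1)))
    dvs <- lapply(active, function(a) {
      dv <- estimate_drift_volatility(data.frame(frame = a$frames, x = a$xs,
                                                 y = a$ys),
                                      window = config$window,
                                      cold_sd = config$cold_sd)
      shrink_volatility(dv, config$cold_sd, config$prior_strength)
    })
    cm <- build_cost_matrix(tails, det, dvs,
                            sigma_floor = config$sigma_floor,
                            cold_sd = config$cold_sd,
                            max_cost = config$max_cost)
    sol <- assign_detections(cm)
    new_active <- list()
    if (nrow(sol$matches)) {
      for (k in seq_len(nrow(sol$matches))) {
        i <- sol$matches$row[k]; j <- sol$matches$col[k]
        a <- active[[i]]
        a$frames <- c(a$frames, t)
        a$xs <- c(a$xs, det$x[j])
        a$ys <- c(a$ys, det$y[j])
        new_active[[length(new_active) + 1L]] <- a
      }
    }
    done <- c(done, active[sol$unmatched_rows])
    for (j in sol$unmatched_cols)
      new_active[[length(new_active) + 1L]] <-
        list(frames = t, xs = det$x[j], ys = det$y[j])
    active <- new_active
  }
  done <- c(done, active)
  # birth order: by first frame, then by original creation sequence
  ord <- order(vapply(done, function(a) a$frames[1], numeric(1)))
  done <- done[ord]
  out <- do.call(rbind, lapply(seq_along(done), function(i) {
    a <- done[[i]]
    data.frame(video_id = video_id, group_id = NA_integer_, track_id = i,
               frame = a$frames, x = a$xs, y = a$ys)
  }))
  rownames(out) <- NULL
  out
}
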