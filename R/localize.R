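#' Detect circular cells in a frame by circular Hough transform
#'
#' The frame is normalized and lightly Gaussian-smoothed, the intensity
#' gradient is taken by central differences, and pixels whose gradient
#' magnitude exceeds a fraction of the frame maximum become edge pixels.
#' Each edge pixel casts one vote per candidate radius at the point one
#' radius along its gradient direction (bright cells on a dark background:
#' the gradient points into the cell), so only consistently curved,
#' correctly polarized edges concentrate votes at a common centre --- the
#' gradient-directed form of the circular Hough transform.  The accumulator
#' is pooled over a 3x3 neighborhood, normalized by the expected perimeter
#' support of a full circle, and capped at 1, so scores are comparable
#' across radii; per pixel the best radius is kept.
#'
#' Peaks with score at or above `sensitivity` survive greedy non-maximum
#' suppression (any peak within `r_min` of a higher-scoring one is
#' discarded) and are refined to sub-pixel precision by the centroid of the
#' 3x3 accumulator neighborhood.
#'
#' @param frame grayscale image matrix (any positive scale).
#' @param radius_range length-2 `c(r_min, r_max)` in px, `1 <= r_min <=
#'   r_max`.
#' @param sensitivity normalized accumulator threshold in (0, 1\];
#'   detections need at least this fraction of a full, well-polarized
#'   perimeter in support.
#' @param edge_frac edge threshold as a fraction of the maximum gradient
#'   magnitude.
#' @param blur standard deviation (px) of the Gaussian smoothing applied
#'   before the gradient.
#' @return data.frame `x, y, r, score` sorted by descending score
#'   (possibly empty); `x, y` are 0-based px (x = column, y = row).
#' @export
detect_cells <- function(frame, radius_range, sensitivity = 0.5,
                         edge_frac = 0.25, blur = 1.5) {
  if (length(radius_range) != 2L || radius_range[1] < 1 ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be c(r_min, r_max) with 1 <= r_min <= r_max")
  if (sensitivity <= 0 || sensitivity > 1)
    stop("sensitivity must be in (0, 1]")
  empty <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      score = numeric(0))
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(h) || h < 5L || w < 5L) return(empty)
  m <- matrix(as.numeric(frame), h, w)
  rng <- range(m)
  if (rng[1] == rng[2]) return(empty)
  m <- (m - rng[1]) / (rng[2] - rng[1])
  if (blur > 0) m <- EBImage::imageData(EBImage::gblur(m, sigma = blur))
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  edges <- which(gmag > edge_frac * max(gmag))
  if (!length(edges)) return(empty)
  er <- (edges - 1L) %% h + 1L
  ec <- (edges - 1L) %/% h + 1L
  gn <- gmag[edges]
  ux <- gx[edges] / gn
  uy <- gy[edges] / gn
  radii <- seq(ceiling(radius_range[1]), floor(radius_range[2]))
  if (!length(radii)) radii <- round(mean(radius_range))
  box <- matrix(1, 3, 3)
  best_raw <- matrix(0, h, w)   # uncapped: decides the radius
  best_score <- matrix(0, h, w)
  best_r <- matrix(NA_real_, h, w)
  for (r in radii) {
    rr <- round(er + r * uy)
    cc <- round(ec + r * ux)
    ok <- rr >= 1L & rr <= h & cc <= w & cc >= 1L
    if (!any(ok)) next
    acc <- tabulate(rr[ok] + (cc[ok] - 1L) * h, nbins = h * w)
    # pool split votes, normalize by ~3-px-wide full-perimeter support
    S <- EBImage::imageData(EBImage::filter2(matrix(acc, h, w), box))
    S <- S / (3 * 2 * pi * r)
    upd <- S > best_raw
    best_raw[upd] <- S[upd]
    best_score[upd] <- pmin(S[upd], 1)
    best_r[upd] <- r
  }
  cand <- which(best_score >= sensitivity)
  if (!length(cand)) return(empty)
  cand <- cand[order(best_score[cand], decreasing = TRUE)]
  cr <- (cand - 1L) %% h + 1L
  cc2 <- (cand - 1L) %/% h + 1L
  keep <- integer(0)
  for (i in seq_along(cand)) {
    if (length(keep)) {
      d <- sqrt((cr[keep] - cr[i])^2 + (cc2[keep] - cc2[i])^2)
      if (any(d < radius_range[1])) next
    }
    keep <- c(keep, i)
  }
  res <- lapply(keep, function(i) {
    r0 <- cr[i]; c0 <- cc2[i]
    rows <- max(1L, r0 - 1L):min(h, r0 + 1L)
    cols <- max(1L, c0 - 1L):min(w, c0 + 1L)
    wgt <- best_score[rows, cols, drop = FALSE]
    sw <- sum(wgt)
    data.frame(
      x = if (sw > 0) sum(outer(rep(1, length(rows)), cols - 1L) * wgt) / sw
          else c0 - 1L,
      y = if (sw > 0) sum(outer(rows - 1L, rep(1, length(cols))) * wgt) / sw
          else r0 - 1L,
      r = best_r[cand[i]],
      score = best_score[cand[i]])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect cells in every frame of a video stack
#'
#' @param frames array `height x width x n_frames`.
#' @param radius_range,sensitivity,edge_frac,blur see [detect_cells()].
#' @return data.frame `frame, x, y, r, score` with 0-based frame indices.
#' @export
detect_video <- function(frames, radius_range, sensitivity = 0.5,
                         edge_frac = 0.25, blur = 1.5) {
  out <- lapply(seq_len(dim(frames)[3]), function(t) {
    d <- detect_cells(frames[, , t], radius_range, sensitivity, edge_frac,
                      blur)
    if (nrow(d)) cbind(frame = t - 1L, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      r = numeric(0), score = numeric(0))
  rownames(out) <- NULL
  out
}
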