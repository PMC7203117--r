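#' Specify the convolutional feature-extraction backbone
#'
#' The backbone is an AlexNet-style stack truncated at its second
#' max-pooling stage ("pool2"): conv 11x11/stride 4 with 96 filters, ReLU,
#' 3x3/stride-2 max pool, conv 5x5/pad 2 with 256 filters in two groups,
#' ReLU, 3x3/stride-2 max pool.  For a 227x227x3 input the tap output is
#' 13x13x256, i.e. a 43264-length descriptor per image.  The network is a
#' fixed feature extractor: it is never fine-tuned.
#'
#' Weights are either loaded from a user-supplied file (`weights = path`, an
#' RDS with elements `W1, b1, W2, b2` in the package's layout) or drawn once
#' from a fixed seed (`weights = "fixed_seed_random"`, He-scaled Gaussians).
#' Random convolutional features preserve the geometry of binary trajectory
#' images (oriented edges, blobs, turns), which is what the downstream
#' linear classifier consumes, so the fixed-seed backbone makes the whole
#' pipeline self-contained and deterministic.
#'
#' @param input_size square input side (px); 227 gives the canonical
#'   43264-feature tap.
#' @param weights `"fixed_seed_random"` or a path to an RDS weights file.
#' @param seed seed for the fixed random weights.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(input_size = 227L, weights = "fixed_seed_random",
                          seed = 909L) {
  input_size <- as.integer(input_size)
  o1 <- (input_size - 11L) %/% 4L + 1L
  if (o1 < 3L) stop("input_size too small for the architecture")
  structure(list(architecture = "alexnet_pool2",
                 input_size = input_size, channels = 3L,
                 weights = weights, seed = as.integer(seed)),
            class = "backbone_spec")
}

# linear indices of im2col patches for an (h, w, c) array, kernel k, given
# stride; rows = output positions (row-major along y first), cols = patch
# elements ordered (dy, dx, channel)
im2col_indices <- function(h, w, c, k, stride) {
  out_h <- (h - k) %/% stride + 1L
  out_w <- (w - k) %/% stride + 1L
  patch <- expand.grid(dy = seq_len(k), dx = seq_len(k), ch = seq_len(c))
  off <- patch$dy + (patch$dx - 1L) * h + (patch$ch - 1L) * h * w
  pos_y <- (seq_len(out_h) - 1L) * stride
  pos_x <- (seq_len(out_w) - 1L) * stride
  topleft <- as.vector(outer(pos_y, pos_x * h, "+"))
  list(idx = outer(topleft, off, "+"), out_h = out_h, out_w = out_w)
}

max_pool <- function(a, k = 3L, stride = 2L) {
  d <- dim(a)
  out <- (d[1] - k) %/% stride + 1L
  ys <- (seq_len(out) - 1L) * stride
  res <- array(-Inf, c(out, out, d[3]))
  for (dy in seq_len(k))
    for (dx in seq_len(k))
      res <- pmax(res, a[ys + dy, ys + dx, , drop = FALSE])
  res
}

#' Construct the backbone (weights + cached geometry)
#'
#' @param spec a [backbone_spec()].
#' @return object of class `backbone` ready for [extract_features()].
#' @export
build_backbone <- function(spec = backbone_spec()) {
  stopifnot(inherits(spec, "backbone_spec"))
  s <- spec$input_size
  if (identical(spec$weights, "fixed_seed_random")) {
    rng <- get_rng_state()
    on.exit(restore_rng_state(rng), add = TRUE)
    set.seed(spec$seed)
    W1 <- matrix(stats::rnorm(11 * 11 * 3 * 96, sd = sqrt(2 / (11 * 11 * 3))),
                 11 * 11 * 3, 96)
    b1 <- numeric(96)
    W2 <- array(stats::rnorm(5 * 5 * 48 * 256, sd = sqrt(2 / (5 * 5 * 48))),
                c(5 * 5 * 48, 256))
    b2 <- numeric(256)
  } else {
    wts <- readRDS(spec$weights)
    W1 <- wts$W1; b1 <- wts$b1; W2 <- wts$W2; b2 <- wts$b2
    if (nrow(W1) != 11 * 11 * 3 || ncol(W1) != 96 ||
        nrow(W2) != 5 * 5 * 48 || ncol(W2) != 256)
      stop("weights file does not match the architecture")
  }
  i1 <- im2col_indices(s, s, 3L, 11L, 4L)
  p1 <- (i1$out_h - 3L) %/% 2L + 1L                 # after pool1
  i2 <- im2col_indices(p1 + 4L, p1 + 4L, 48L, 5L, 1L)  # pad 2 each side
  p2 <- (i2$out_h - 3L) %/% 2L + 1L                 # after pool2
  structure(list(spec = spec, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 i1 = i1, i2 = i2, pool1 = p1, pool2 = p2,
                 n_features = p2 * p2 * 256L),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat("Convolutional backbone (", x$spec$architecture, "), input ",
      x$spec$input_size, "x", x$spec$input_size, "x3, tap length ",
      x$n_features, "\n", sep = "")
  cat("  weights:", if (identical(x$spec$weights, "fixed_seed_random"))
    sprintf("fixed-seed random (seed %d)", x$spec$seed) else x$spec$weights,
    "\n")
  invisible(x)
}

#' Condition a trajectory image for the backbone
#'
#' Bilinear resize to the backbone input size and replication to three
#' channels; intensities stay in \[0, 1\] with the background at exactly 0.
#' Trajectory images are sparse, so a zero background keeps every
#' off-trajectory activation at zero through the rectified convolutions:
#' the extracted features describe the trajectory geometry only, not the
#' (constant) background.  Deterministic.
#'
#' @param img binary matrix (a `trajectory_image`) or numeric matrix in
#'   \[0, 1\].
#' @param spec a [backbone_spec()].
#' @return numeric array `input_size x input_size x 3`.
#' @export
preprocess_image <- function(img, spec = backbone_spec()) {
  if (is.null(dim(img)) || any(dim(img) == 0L)) stop("zero-size image")
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  s <- spec$input_size
  if (nrow(m) != s || ncol(m) != s)
    m <- EBImage::imageData(EBImage::resize(m, w = s, h = s))
  array(m, c(s, s, 3L))
}

# forward pass to pool2 for one preprocessed input
backbone_forward <- function(bb, input) {
  X1 <- input[bb$i1$idx]
  dim(X1) <- dim(bb$i1$idx)
  a1 <- X1 %*% bb$W1
  if (any(bb$b1 != 0)) a1 <- a1 + rep(bb$b1, each = nrow(a1))
  a1[a1 < 0] <- 0
  dim(a1) <- c(bb$i1$out_h, bb$i1$out_w, 96L)
  p1 <- max_pool(a1)
  s <- dim(p1)[1]
  pad <- array(0, c(s + 4L, s + 4L, 96L))
  pad[3:(s + 2L), 3:(s + 2L), ] <- p1
  a2 <- array(0, c(bb$i2$out_h, bb$i2$out_w, 256L))
  for (g in 1:2) {
    chans <- if (g == 1L) 1:48 else 49:96
    filt <- if (g == 1L) 1:128 else 129:256
    Xg <- pad[, , chans][bb$i2$idx]
    dim(Xg) <- dim(bb$i2$idx)
    ag <- Xg %*% bb$W2[, filt]
    if (any(bb$b2[filt] != 0)) ag <- ag + rep(bb$b2[filt], each = nrow(ag))
    ag[ag < 0] <- 0
    a2[, , filt] <- ag
  }
  as.vector(max_pool(a2))
}

#' Extract deep descriptors from trajectory images
#'
#' Runs every image through the fixed backbone and returns the flattened
#' pool2 activations, one row per image in input order.  Extraction is
#' deterministic given (images, backbone).
#'
#' @param images list of binary trajectory images (entries may be `NULL`
#'   for skipped tracks; they yield `NA` rows).
#' @param backbone a [build_backbone()] object (or a `backbone_spec`, which
#'   is built on the fly).
#' @param verbose print progress every 200 images.
#' @return numeric matrix `length(images) x 43264` (for the default spec).
#' @export
extract_features <- function(images, backbone = backbone_spec(),
                             verbose = FALSE) {
  if (inherits(backbone, "backbone_spec")) backbone <- build_backbone(backbone)
  stopifnot(inherits(backbone, "backbone"))
  n <- length(images)
  fm <- matrix(NA_real_, n, backbone$n_features)
  for (i in seq_len(n)) {
    if (is.null(images[[i]])) next
    inp <- preprocess_image(images[[i]], backbone$spec)
    fm[i, ] <- backbone_forward(backbone, inp)
    if (verbose && i %% 200L == 0L)
      message("extracted ", i, "/", n, " images")
  }
  fm
}

#' Variance-based unsupervised feature selection
#'
#' Drops low-variability features: small feature variance implies rejection.
#' The criterion never sees class labels.  When `train_rows` is supplied the
#' variances are computed on those rows only and the resulting mask is
#' applied unchanged to all rows, so no test-set information leaks into the
#' selection.
#'
#' Two modes: `threshold` removes columns with variance `<= threshold`;
#' otherwise the bottom `prop` fraction of columns by variance is removed
#' (quantile mode, default half).
#'
#' @param fm numeric feature matrix (rows = images).
#' @param threshold absolute variance threshold, or `NULL` for quantile mode.
#' @param prop fraction of columns to drop in quantile mode.
#' @param train_rows optional row indices on which variances are computed.
#' @return list with `features` (selected columns, all rows), `mask`
#'   (logical per original column), `variances`.
#' @export
select_features <- function(fm, threshold = NULL, prop = 0.5,
                            train_rows = NULL) {
  if (nrow(fm) < 2L) stop("need at least 2 rows to estimate variances")
  rows <- if (is.null(train_rows)) seq_len(nrow(fm)) else train_rows
  if (length(rows) < 2L) stop("need at least 2 training rows")
  x <- fm[rows, , drop = FALSE]
  n <- nrow(x)
  v <- (colMeans(x^2) - colMeans(x)^2) * n / (n - 1)
  v[v < 0] <- 0  # numerical guard
  if (is.null(threshold)) {
    mask <- v > stats::quantile(v, prop, names = FALSE)
  } else {
    if (threshold < 0) stop("threshold must be >= 0")
    mask <- v > threshold
  }
  if (!any(mask)) stop("all features rejected: threshold too high")
  list(features = fm[, mask, drop = FALSE], mask = mask, variances = v)
}

# save/restore the global RNG so fixed-seed weight generation does not
# disturb a caller's random stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
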