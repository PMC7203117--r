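test_that("trajectory images encode stopped cells and drift motility", {
  # stopped cell: a singleton white marker at the centre
  stat <- data.frame(x = rep(10, 5), y = rep(20, 5))
  img <- track_to_image(stat, reference = c(10, 20), R = 8)
  expect_equal(sum(img), 1L)
  expect_equal(img[9, 9], 1L)

  # constant drift: white pixels on a straight line
  drift <- data.frame(x = 0:6, y = 0:6)
  img2 <- track_to_image(drift, reference = c(3, 3), R = 4)
  on <- which(img2 == 1L, arr.ind = TRUE)
  expect_equal(nrow(on), 7)
  expect_true(all(on[, 1] == on[, 2]))
})

test_that("images are invariant to joint translation and rotate with the track", {
  set.seed(21)
  tr <- data.frame(x = cumsum(rnorm(12)), y = cumsum(rnorm(12)))
  ref <- c(0.3, -0.7)
  a <- track_to_image(tr, ref, R = 10)
  b <- track_to_image(data.frame(x = tr$x + 7, y = tr$y - 3),
                      ref + c(7, -3), R = 10)
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
  # 90 degree rotation about the reference rotates the image
  rot <- data.frame(x = ref[1] - (tr$y - ref[2]), y = ref[2] + (tr$x - ref[1]))
  r90 <- track_to_image(rot, ref, R = 10)
  # (dx, dy) -> (-dy, dx): new image at [dx, -dy] = old transposed+flipped
  m <- unclass(a)
  expected <- t(m)[, ncol(m):1]
  expect_equal(unclass(r90), expected, ignore_attr = TRUE)
})

test_that("white pixel count never exceeds track length; clipping works", {
  set.seed(22)
  for (i in 1:10) {
    tr <- data.frame(x = cumsum(rnorm(30, sd = 3)),
                     y = cumsum(rnorm(30, sd = 3)))
    img <- track_to_image(tr, c(0, 0), R = 6)
    expect_lte(sum(img), nrow(tr))
  }
  # far excursion is clipped, not fatal
  tr <- data.frame(x = c(0, 100), y = c(0, 0))
  expect_equal(sum(track_to_image(tr, c(0, 0), R = 5)), 1L)
  # entirely outside -> error
  expect_error(track_to_image(data.frame(x = 100, y = 100), c(0, 0), 5),
               "outside")
})

test_that("neighborhood assignment picks the nearest centre within radius", {
  tracks <- data.frame(video_id = "v1", track_id = rep(1:3, each = 2),
                       frame = rep(0:1, 3),
                       x = c(10, 11, 30, 31, 90, 91),
                       y = c(0, 0, 0, 0, 0, 0))
  centers <- data.frame(video_id = "v1", group_id = 1:2,
                        xc = c(20, 40), yc = c(0, 0))
  g <- assign_tumor_neighborhoods(tracks, centers, radius = 15)
  expect_equal(g$group_id[g$track_id == 1], 1)
  # track 2 starts at 30: equidistant from both centres -> lower index wins
  expect_equal(g$group_id[g$track_id == 2], 1)
  # track 3 farther than the radius from every centre: excluded
  expect_false(3 %in% g$track_id)
  expect_equal(nrow(assign_tumor_neighborhoods(tracks, centers[0, ], 15)), 0)
})

test_that("grouping recovers the generating neighborhoods on synthetic data", {
  ds <- tiny_dataset(seed = 31)
  g <- assign_tumor_neighborhoods(ds$tracks, ds$references, radius = 100)
  truth <- unique(ds$tracks[, c("video_id", "group_id", "track_id")])
  m <- merge(g, truth, by = c("video_id", "track_id"),
             suffixes = c("_got", "_true"))
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$group_id_got == m$group_id_true))
})

test_that("single-linkage clustering respects the distance cutoff", {
  mk <- function(cx, cy, id0) data.frame(
    video_id = "v1", track_id = id0 + 0:2, frame = 0L,
    x = cx + c(-1, 0, 1), y = cy)
  tracks <- rbind(do.call(rbind, lapply(0:2, function(i)
    mk(10 + 2 * i, 0, 1 + 3 * i))),
    mk(200, 0, 10))
  # chain spaced 2 apart links into one cluster at cutoff 5; far group apart
  g <- cluster_tracks(tracks, linkage_distance = 5)
  expect_equal(length(unique(g$group_id)), 2)
  expect_equal(length(unique(g$group_id[g$track_id <= 9])), 1)

  # 5 tight clusters far apart: recovered grouping equals the truth
  set.seed(41)
  centers <- data.frame(cx = c(0, 300, 600, 0, 300), cy = c(0, 0, 0, 300, 300))
  tight <- do.call(rbind, lapply(1:5, function(cl)
    do.call(rbind, lapply(1:4, function(k) {
      tid <- (cl - 1) * 4 + k
      data.frame(video_id = "v1", track_id = tid, frame = 0:2,
                 x = centers$cx[cl] + runif(1, -5, 5) + rnorm(3, sd = 0.5),
                 y = centers$cy[cl] + runif(1, -5, 5) + rnorm(3, sd = 0.5))
    }))))
  g2 <- cluster_tracks(tight, linkage_distance = 50)
  expect_equal(length(unique(g2$group_id)), 5)
  expect_equal(g2$group_id[order(g2$track_id)],
               rep(1:5, each = 4))
  # the cluster reference is the mean of the member track centres
  mem <- g2[g2$group_id == 1, ]
  cx <- vapply(mem$track_id, function(id)
    mean(tight$x[tight$track_id == id]), numeric(1))
  expect_equal(unique(mem$xc), mean(cx))
})

test_that("atlas building writes a deterministic manifest and images", {
  ds <- tiny_dataset(seed = 33)
  g <- assign_tumor_neighborhoods(ds$tracks, ds$references, 100)
  dir1 <- file.path(tempdir(), "atlas1"); dir2 <- file.path(tempdir(), "atlas2")
  a1 <- suppressWarnings(build_atlas(ds$tracks, g, ds$labels, R = 30,
                                     out_dir = dir1))
  a2 <- suppressWarnings(build_atlas(ds$tracks, g, ds$labels, R = 30,
                                     out_dir = dir2))
  ok <- !a1$manifest$skipped
  expect_equal(sum(ok), length(list.files(dir1, pattern = "\\.png$")))
  # byte-identical re-run
  for (k in which(ok))
    expect_identical(readBin(a1$manifest$image_path[k], "raw", 1e6),
                     readBin(a2$manifest$image_path[k], "raw", 1e6))
  # manifest label column matches the generating condition
  expect_equal(a1$manifest$label,
               ds$labels$label[match(a1$manifest$video_id,
                                     ds$labels$video_id)])
  # PNG round trip reproduces the binary matrix
  k <- which(ok)[1]
  back <- round(png::readPNG(a1$manifest$image_path[k]))
  expect_equal(back, unclass(a1$images[[k]]), ignore_attr = TRUE)
})

test_that("default region radius covers almost all offsets", {
  ds <- tiny_dataset(seed = 34)
  g <- assign_tumor_neighborhoods(ds$tracks, ds$references, 100)
  R <- default_region_radius(ds$tracks, g)
  m <- merge(ds$tracks, g, by = c("video_id", "track_id"))
  off <- sqrt((m$x - m$xc)^2 + (m$y - m$yc)^2)
  expect_gte(mean(off <= R), 0.985)
  expect_true(R >= 1 && R == as.integer(R))
})
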