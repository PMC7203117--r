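test_that("drift/volatility estimates follow the windowed sample moments", {
  # constant displacements (2, -1): mu exact, var zero
  tr <- data.frame(frame = 0:5, x = 2 * (0:5), y = -(0:5))
  dv <- estimate_drift_volatility(tr, window = 10)
  expect_equal(dv$mu_x, 2)
  expect_equal(dv$mu_y, -1)
  expect_equal(dv$var_x, 0)
  expect_equal(dv$var_y, 0)
  expect_equal(dv$window_T, 5L)

  # displacements (0,0) then (2,0): window mean 1, mean squared deviation 1
  tr2 <- data.frame(frame = 0:2, x = c(0, 0, 2), y = c(0, 0, 0))
  dv2 <- estimate_drift_volatility(tr2, window = 2)
  expect_equal(dv2$mu_x, 1)
  expect_equal(dv2$var_x, 1)

  # only the window's most recent displacements count
  tr3 <- data.frame(frame = 0:4, x = c(0, 100, 101, 102, 103), y = rep(0, 5))
  dv3 <- estimate_drift_volatility(tr3, window = 3)
  expect_equal(dv3$mu_x, 1)
  expect_equal(dv3$window_T, 3L)
})

test_that("cold start applies below two displacements and is flagged", {
  one <- data.frame(frame = 0, x = 1, y = 2)
  dv <- estimate_drift_volatility(one, cold_sd = 2)
  expect_true(dv$cold_start)
  expect_equal(c(dv$mu_x, dv$mu_y), c(0, 0))
  expect_equal(c(dv$var_x, dv$var_y), c(4, 4))
  two <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 0))
  expect_true(estimate_drift_volatility(two)$cold_start)
})

test_that("windowed estimators recover the generating drift and volatility", {
  set.seed(202)
  p <- motility_params(drift = c(0.5, 0), volatility = c(1, 1))
  Tw <- 1000
  tr <- simulate_track(p, c(0, 0), Tw)
  dv <- estimate_drift_volatility(tr, window = Tw)
  expect_lt(abs(dv$mu_x - 0.5), 3 / sqrt(Tw))
  expect_gt(dv$var_x, qchisq(0.005, Tw - 1) / (Tw - 1))
  expect_lt(dv$var_x, qchisq(0.995, Tw - 1) / (Tw - 1))
})

test_that("displacement likelihood is the bivariate Gaussian density", {
  dv <- structure(list(mu_x = 0.3, mu_y = -0.2, var_x = 1, var_y = 1),
                  class = "drift_volatility")
  expect_equal(displacement_likelihood(0.3, -0.2, dv), 1 / (2 * pi))
  # symmetric displacements around the mean give equal density
  expect_equal(displacement_likelihood(0.3 + 1.7, -0.2, dv),
               displacement_likelihood(0.3 - 1.7, -0.2, dv))
  # integrates to 1 over a +-6 sigma grid (numerical quadrature oracle)
  g <- seq(-6, 6, by = 0.02)
  dens <- outer(g + 0.3, g - 0.2, function(dx, dy)
    displacement_likelihood(dx, dy, dv))
  expect_lt(abs(sum(dens) * 0.02^2 - 1), 1e-3)
  expect_error(displacement_likelihood(NaN, 0, dv), "non-finite")
})

test_that("cost matrix entries are inverse likelihoods, capped and gated", {
  dv <- structure(list(mu_x = 1, mu_y = 0, var_x = 1, var_y = 1,
                       window_T = 5L, cold_start = FALSE),
                  class = "drift_volatility")
  tails <- data.frame(x = 0, y = 0)
  # detection exactly at the predicted mean displacement: cost 2 pi
  det <- data.frame(x = 1, y = 0)
  cm <- build_cost_matrix(tails, det, list(dv))
  expect_equal(cm$entries[1, 1], 2 * pi)
  # farther from the mean -> strictly larger cost
  det3 <- data.frame(x = c(1, 1.5, 3), y = 0)
  cm3 <- build_cost_matrix(tails, det3, list(dv))
  expect_true(all(diff(cm3$entries[1, ]) > 0))
  # empty inputs give empty matrices
  e <- build_cost_matrix(tails[0, ], det[0, ], list())
  expect_equal(dim(e$entries), c(0L, 0L))
})

test_that("assignment equals the brute-force optimum on random instances", {
  set.seed(303)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    sol <- solve_assignment(C)
    expect_equal(sum(C[cbind(seq_len(n), sol)]),
                 trackatlas:::brute_force_assignment(C)$cost)
  }
  # rectangular instances through the gated assignment (gates too large
  # to bind): optimum over all injections
  for (i in 1:20) {
    C <- matrix(runif(5 * 6, 0, 1), 5, 6)
    cm <- structure(list(entries = C, row_gates = rep(100, 5),
                         col_gates = rep(100, 6)), class = "cost_matrix")
    sol <- assign_detections(cm)
    expect_equal(nrow(sol$matches), 5)
    got <- sum(C[cbind(sol$matches$row, sol$matches$col)])
    expect_equal(got, trackatlas:::brute_force_assignment(C)$cost)
  }
})

test_that("gating unmatches implausible pairs", {
  cm <- structure(list(entries = matrix(c(1, 10, 10, 1), 2),
                       row_gates = rep(5, 2), col_gates = rep(5, 2)),
                  class = "cost_matrix")
  sol <- assign_detections(cm)
  expect_equal(sol$matches$col[order(sol$matches$row)], c(1, 2))
  # all entries above the gate: no matches at all
  cm$entries <- matrix(6, 2, 2)
  sol2 <- assign_detections(cm)
  expect_equal(nrow(sol2$matches), 0)
  expect_equal(sol2$unmatched_rows, 1:2)
  expect_equal(sol2$unmatched_cols, 1:2)
})

test_that("linking recovers well-separated simulated cells exactly", {
  set.seed(404)
  starts <- expand.grid(x = c(30, 90, 150), y = c(40, 110))[1:5, ]
  p <- motility_params(volatility = c(0.8, 0.8))
  tracks <- do.call(rbind, lapply(1:5, function(i) {
    tr <- simulate_track(p, c(starts$x[i], starts$y[i]), 29)
    cbind(tr, id = i)
  }))
  det <- tracks[order(tracks$frame), ]
  out <- link_video(data.frame(frame = det$frame, x = det$x, y = det$y))
  expect_equal(length(unique(out$track_id)), 5)
  # every reconstructed track matches one generating cell point-for-point
  for (tid in unique(out$track_id)) {
    got <- out[out$track_id == tid, ]
    truth <- tracks[tracks$id == tracks$id[tracks$x == got$x[1] &
                                           tracks$y == got$y[1]][1], ]
    expect_equal(got$x, truth$x)
    expect_equal(got$y, truth$y)
  }
})

test_that("a single frame yields length-1 tracks", {
  det <- data.frame(frame = 0L, x = c(1, 5, 9), y = c(2, 2, 2))
  out <- link_video(det)
  expect_equal(nrow(out), 3)
  expect_equal(length(unique(out$track_id)), 3)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(505)
  ds <- tiny_dataset()
  det <- detections_from_tracks(ds, "vid01")
  key <- function(tr) {
    s <- split(tr, tr$track_id)
    sort(vapply(s, function(a)
      paste(a$frame, round(a$x, 9), round(a$y, 9), collapse = ";"),
      character(1)))
  }
  out1 <- link_video(det[, c("frame", "x", "y")])
  shuf <- det[sample(nrow(det)), ]
  shuf <- shuf[order(shuf$frame), ]
  out2 <- link_video(shuf[, c("frame", "x", "y")])
  expect_equal(unname(key(out1)), unname(key(out2)))
})

test_that("tracker reaches 99% link accuracy at moderate density", {
  set.seed(606)
  # 20 cells on a jittered grid, >= 10 px apart, sigma = 1 px, 100 frames
  grid <- expand.grid(x = seq(20, 180, by = 40), y = seq(20, 140, by = 40))
  grid <- grid[1:20, ]
  p <- motility_params(volatility = c(1, 1))
  tracks <- do.call(rbind, lapply(1:20, function(i) {
    tr <- simulate_track(p, c(grid$x[i], grid$y[i]), 99)
    cbind(tr, id = i)
  }))
  out <- link_video(data.frame(frame = tracks$frame, x = tracks$x,
                               y = tracks$y))
  # score: fraction of ground-truth consecutive-frame links reproduced
  truth_links <- do.call(rbind, lapply(split(tracks, tracks$id), function(a) {
    a <- a[order(a$frame), ]
    data.frame(f = a$frame[-nrow(a)],
               from = paste(round(a$x[-nrow(a)], 9), round(a$y[-nrow(a)], 9)),
               to = paste(round(a$x[-1], 9), round(a$y[-1], 9)))
  }))
  got_links <- do.call(rbind, lapply(split(out, out$track_id), function(a) {
    if (nrow(a) < 2) return(NULL)
    data.frame(f = a$frame[-nrow(a)],
               from = paste(round(a$x[-nrow(a)], 9), round(a$y[-nrow(a)], 9)),
               to = paste(round(a$x[-1], 9), round(a$y[-1], 9)))
  }))
  hit <- paste(truth_links$f, truth_links$from, truth_links$to) %in%
    paste(got_links$f, got_links$from, got_links$to)
  expect_gte(mean(hit), 0.99)
})
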