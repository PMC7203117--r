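test_that("video folds are stratified, exclusive, and experiment-aware", {
  lab4 <- data.frame(video_id = sprintf("v%02d", 1:4),
                     label = c("treated", "untreated", "treated",
                               "untreated"))
  f <- make_video_folds(lab4)
  expect_equal(as.integer(table(f$fold)), c(2L, 2L))
  for (k in 1:2)
    expect_setequal(unique(f$label[f$fold == k]), c("treated", "untreated"))
  expect_equal(anyDuplicated(f$video_id), 0)

  # two replicated experiments: folds follow the experiment ids
  lab12 <- data.frame(video_id = sprintf("v%02d", 1:12),
                      label = rep(c("untreated", "treated"), 6),
                      experiment = rep(1:2, each = 6))
  f12 <- make_video_folds(lab12)
  expect_equal(f12$fold, rep(1:2, each = 6))

  expect_error(make_video_folds(
    data.frame(video_id = c("a", "b"), label = c("treated", "treated"))),
    "both class")
})

test_that("fold-wise SVM separates separable features and not permuted ones", {
  set.seed(71)
  n_vid <- 8
  manifest <- data.frame(
    video_id = rep(sprintf("v%02d", 1:n_vid), each = 25),
    group_id = rep(rep(1:5, each = 5), n_vid),
    track_id = 1:(n_vid * 25),
    label = rep(rep(c("treated", "untreated"), n_vid / 2), each = 25))
  folds <- make_video_folds(unique(manifest[, c("video_id", "label")]))
  mu <- ifelse(manifest$label == "treated", 4, -4)
  fm <- cbind(mu + rnorm(nrow(manifest)), matrix(rnorm(nrow(manifest) * 9),
                                                 ncol = 9))
  preds <- train_and_predict(fm, manifest, folds,
                             selection = list(threshold = 0))
  expect_true(all(!is.na(preds$pred)))
  expect_equal(balanced_accuracy(preds$label, preds$pred), 100)
  rep <- evaluate_consensus(preds)
  expect_equal(rep$averages$track_acc, 100)
  expect_equal(rep$averages$group_acc, 100)
  expect_equal(rep$averages$video_acc, 100)

  # label permutation: chance-level balanced accuracy
  manifest2 <- manifest
  fm2 <- cbind(rnorm(nrow(manifest)), matrix(rnorm(nrow(manifest) * 9),
                                             ncol = 9))
  preds2 <- train_and_predict(fm2, manifest2, folds,
                              selection = list(threshold = 0))
  acc <- balanced_accuracy(preds2$label, preds2$pred) / 100
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / nrow(manifest2)) + 0.05)
})

test_that("majority voting follows the strict majority and margin tie-break", {
  expect_equal(majority_vote(c("treated", "treated", "untreated")), "treated")
  expect_equal(majority_vote(c("treated", "untreated"),
                             member_margins = c(0.2, -0.9)), "untreated")
  expect_equal(majority_vote(c("treated", "untreated"),
                             member_margins = c(0.9, -0.2)), "treated")
  expect_warning(out <- majority_vote(c("treated", "untreated"),
                                      member_margins = c(0.5, -0.5)),
                 "tied")
  expect_equal(out, "untreated")
  expect_error(majority_vote(character(0)), "empty")
  # unanimity is preserved
  expect_equal(majority_vote(rep("untreated", 5)), "untreated")
})

test_that("balanced accuracy matches closed forms and hand counts", {
  truth <- rep(c("treated", "untreated"), c(7, 3))
  expect_equal(balanced_accuracy(truth, truth), 100)
  expect_equal(balanced_accuracy(truth, rep("treated", 10)), 50)
  # TP=8 FN=2 TN=3 FP=7 -> (0.8 + 0.3)/2 = 55%
  truth2 <- rep(c("treated", "untreated"), each = 10)
  pred2 <- c(rep("treated", 8), rep("untreated", 2),
             rep("treated", 7), rep("untreated", 3))
  expect_equal(balanced_accuracy(truth2, pred2), 55)
  # invariant to class-preserving permutation
  set.seed(72)
  ord <- sample(20)
  expect_equal(balanced_accuracy(truth2[ord], pred2[ord]), 55)
  expect_error(balanced_accuracy(rep("treated", 4), rep("treated", 4)),
               "both classes")
})

test_that("majority voting improves over independent member accuracy", {
  # members correct independently with p = 0.7: over 20 seeds the mean
  # group-level gain is positive
  gains <- vapply(1:20, function(seed) {
    set.seed(seed)
    truth <- rep(c("treated", "untreated"), each = 30)
    group <- rep(1:12, each = 5)
    correct <- runif(60) < 0.7
    flip <- function(l) ifelse(l == "treated", "untreated", "treated")
    pred <- ifelse(correct, truth, flip(truth))
    grp_pred <- vapply(split(seq_len(60), group), function(i)
      suppressWarnings(majority_vote(pred[i])), character(1))
    grp_truth <- vapply(split(truth, group), `[`, character(1), 1)
    mean(grp_pred == grp_truth) - mean(pred == truth)
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("consensus reports are internally consistent and serializable", {
  set.seed(73)
  ds <- tiny_dataset(seed = 74, n_videos = 2, n_groups = 2, n_tracks = 8)
  rep <- run_study(ds, features = "kinematic")
  expect_s3_class(rep, "consensus_report")
  expect_true(all(vapply(rep$folds, function(f)
    all(unlist(f[c("track_acc", "group_acc", "video_acc")]) >= 0 &
        unlist(f[c("track_acc", "group_acc", "video_acc")]) <= 100),
    logical(1))))
  expect_equal(rep$averages$track_acc,
               mean(c(rep$folds[[1]]$track_acc, rep$folds[[2]]$track_acc)))
  # every video predicted exactly once, every track tested exactly once
  expect_equal(nrow(rep$per_video), nrow(ds$labels))
  expect_false(any(is.na(rep$per_track$pred)))
  # JSON round trip preserves the accuracy structure
  path <- tempfile(fileext = ".json")
  write_report(rep, path, meta = list(seed = 74))
  back <- read_report(path)
  expect_equal(back$averages$track_acc, rep$averages$track_acc)
  expect_equal(back$folds$video_acc,
               c(rep$folds[[1]]$video_acc, rep$folds[[2]]$video_acc))
  expect_equal(back$meta$seed, 74)
  expect_output(print(rep), "majority vote")
})
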