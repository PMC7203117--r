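#' Video-exclusive two-fold split
#'
#' Partitions videos into two folds so that no video's tracks are ever split
#' between training and testing.  If an `experiment` column is present the
#' folds are the experiments (the replicated-experiment design); otherwise
#' videos are sorted within each class and assigned alternately, which
#' guarantees both classes in both folds whenever each class has at least
#' two videos.
#'
#' @param labels data.frame `video_id, label` (optionally `experiment`).
#' @return data.frame `video_id, label, fold` (fold in 1:2).
#' @export
make_video_folds <- function(labels) {
  if (nrow(labels) < 2L || length(unique(labels$label)) < 2L)
    stop("need at least 2 videos and both class labels")
  if (!is.null(labels$experiment) && !anyNA(labels$experiment) &&
      length(unique(labels$experiment)) == 2L) {
    fold <- match(labels$experiment, sort(unique(labels$experiment)))
  } else {
    fold <- integer(nrow(labels))
    for (cl in unique(labels$label)) {
      idx <- which(labels$label == cl)
      idx <- idx[order(labels$video_id[idx])]
      fold[idx] <- rep_len(1:2, length(idx))
    }
  }
  out <- data.frame(video_id = labels$video_id, label = labels$label,
                    fold = fold)
  for (f in 1:2)
    if (length(unique(out$label[out$fold == f])) < 2L)
      stop("impossible stratification: fold ", f,
           " would not contain both classes")
  out
}

#' Train the linear SVM fold-wise and predict held-out tracks
#'
#' For each turn of the two-fold procedure, the variance-based feature
#' selection and the linear SVM (C = 1, treated = positive class) are fitted
#' on the training fold only; predictions and signed margins are produced
#' for the test fold.  Across both turns every row is tested exactly once.
#'
#' @param fm feature matrix, one row per track image (manifest order).
#' @param manifest data.frame `video_id, group_id, track_id, label` aligned
#'   with `fm` rows.
#' @param folds a [make_video_folds()] data.frame.
#' @param selection list of arguments for [select_features()]
#'   (`threshold`, `prop`).
#' @param cost SVM regularization constant.
#' @return data.frame: manifest columns + `fold, pred, margin` (margin > 0
#'   leans treated).
#' @export
train_and_predict <- function(fm, manifest, folds,
                              selection = list(prop = 0.5), cost = 1) {
  stopifnot(nrow(fm) == nrow(manifest))
  fold_of <- folds$fold[match(manifest$video_id, folds$video_id)]
  if (anyNA(fold_of)) stop("manifest contains videos missing from folds")
  lab <- factor(manifest$label, levels = c("untreated", "treated"))
  pred <- factor(rep(NA_character_, nrow(fm)),
                 levels = c("untreated", "treated"))
  margin <- rep(NA_real_, nrow(fm))
  for (turn in 1:2) {
    test <- which(fold_of == turn)
    train <- which(fold_of != turn)
    if (length(unique(lab[train])) < 2L)
      stop("training fold has a single class")
    sel <- select_features(fm, threshold = selection$threshold,
                           prop = if (is.null(selection$prop)) 0.5
                                  else selection$prop,
                           train_rows = train)
    fit <- e1071::svm(sel$features[train, , drop = FALSE], lab[train],
                      kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(fit, sel$features[test, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    # libsvm orients decision values toward the first class seen in
    # training; flip so positive always means treated
    sgn <- if (grepl("^treated", colnames(dv)[1])) 1 else -1
    margin[test] <- sgn * dv[, 1]
    pred[test] <- ifelse(margin[test] > 0, "treated", "untreated")
  }
  out <- cbind(manifest, fold = fold_of, pred = pred, margin = margin)
  rownames(out) <- NULL
  out
}

#' Majority vote over a group of per-track decisions
#'
#' The group label is the strict majority of the member labels.  A tied
#' vote is broken by the sign of the summed margins; a zero margin sum
#' falls back to `"untreated"` with a warning.
#'
#' @param member_labels character/factor vector of per-track labels.
#' @param member_margins optional numeric margins (positive = treated).
#' @return `"treated"` or `"untreated"`.
#' @export
majority_vote <- function(member_labels, member_margins = NULL) {
  member_labels <- as.character(member_labels)
  n <- length(member_labels)
  if (n == 0L) stop("empty group")
  pos <- sum(member_labels == "treated")
  if (pos * 2L > n) return("treated")
  if (pos * 2L < n) return("untreated")
  s <- if (is.null(member_margins)) 0 else sum(member_margins)
  if (s > 0) return("treated")
  if (s == 0)
    warning("tied vote with zero margin sum; defaulting to untreated",
            call. = FALSE)
  "untreated"
}

#' Balanced accuracy (percent)
#'
#' Mean of the per-class recalls, times 100; the evaluation metric under
#' class imbalance.
#'
#' @param truth,pred vectors of `"treated"`/`"untreated"` labels.
#' @return percentage in \[0, 100\].
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- unique(truth)
  if (length(classes) < 2L)
    stop("balanced accuracy needs both classes in the truth")
  100 * mean(vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

#' Aggregate per-track predictions into a consensus report
#'
#' From per-track predictions (one test fold per turn), computes majority
#' votes per group (tumor-cell neighborhood or cluster) and per video, and
#' balanced accuracy at track, group, and video level for each fold turn and
#' averaged.
#'
#' @param predictions output of [train_and_predict()].
#' @return object of class `consensus_report`: list with `per_track`,
#'   `per_group`, `per_video` data.frames, `folds` (per-turn metrics),
#'   `averages`, and `confusion` (track-level 2x2 tables per turn).
#' @export
evaluate_consensus <- function(predictions) {
  p <- predictions
  per_group <- do.call(rbind, lapply(split(
    p, list(p$video_id, p$group_id), drop = TRUE), function(g)
      data.frame(video_id = g$video_id[1], group_id = g$group_id[1],
                 fold = g$fold[1], label = g$label[1],
                 n_members = nrow(g),
                 pred = majority_vote(g$pred, g$margin))))
  per_video <- do.call(rbind, lapply(split(p, p$video_id), function(g)
    data.frame(video_id = g$video_id[1], fold = g$fold[1],
               label = g$label[1], n_members = nrow(g),
               pred = majority_vote(g$pred, g$margin))))
  rownames(per_group) <- rownames(per_video) <- NULL
  folds <- lapply(1:2, function(turn) {
    tr <- p[p$fold == turn, ]
    gr <- per_group[per_group$fold == turn, ]
    vi <- per_video[per_video$fold == turn, ]
    list(turn = turn,
         track_acc = balanced_accuracy(tr$label, tr$pred),
         group_acc = balanced_accuracy(gr$label, gr$pred),
         video_acc = balanced_accuracy(vi$label, vi$pred))
  })
  averages <- list(
    track_acc = mean(vapply(folds, `[[`, numeric(1), "track_acc")),
    group_acc = mean(vapply(folds, `[[`, numeric(1), "group_acc")),
    video_acc = mean(vapply(folds, `[[`, numeric(1), "video_acc")))
  confusion <- lapply(1:2, function(turn) {
    tr <- p[p$fold == turn, ]
    table(truth = tr$label, pred = tr$pred)
  })
  structure(list(per_track = p, per_group = per_group,
                 per_video = per_video, folds = folds,
                 averages = averages, confusion = confusion),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Consensus classification report (two-fold, video-exclusive)\n")
  cat(sprintf("  %-28s %6.1f%%  (%.0f%% / %.0f%%)\n", "single-track analysis:",
              x$averages$track_acc, x$folds[[1]]$track_acc,
              x$folds[[2]]$track_acc))
  cat(sprintf("  %-28s %6.1f%%  (%.0f%% / %.0f%%)\n",
              "group-level majority vote:", x$averages$group_acc,
              x$folds[[1]]$group_acc, x$folds[[2]]$group_acc))
  cat(sprintf("  %-28s %6.1f%%  (%.0f%% / %.0f%%)\n",
              "video-level majority vote:", x$averages$video_acc,
              x$folds[[1]]$video_acc, x$folds[[2]]$video_acc))
  cat("  (balanced accuracy; fold-turn values in parentheses)\n")
  invisible(x)
}

#' @export
summary.consensus_report <- function(object, ...) {
  print(object)
  cat("\nTrack-level confusion (per turn):\n")
  for (t in 1:2) { cat(" turn", t, "\n"); print(object$confusion[[t]]) }
  invisible(object)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Convenience wrapper reproducing the study workflow on simulated data:
#' tracks are grouped around their reference points (tumor neighborhoods),
#' encoded as trajectory images, mapped to features (deep backbone or the
#' 28-descriptor kinematic baseline), classified with the fold-restricted
#' linear SVM, and aggregated by majority voting.
#'
#' @param dataset a [simulate_experiment()] result.
#' @param features `"deep"` or `"kinematic"`.
#' @param backbone a [backbone_spec()] (deep mode).
#' @param R region radius; `NULL` for the data-driven default.
#' @param neighborhood_radius assignment radius around each reference (px).
#' @param selection feature-selection arguments (deep mode).
#' @param verbose print stage progress.
#' @return a `consensus_report` (with the atlas radius in `$R`).
#' @export
run_study <- function(dataset, features = c("deep", "kinematic"),
                      backbone = backbone_spec(), R = NULL,
                      neighborhood_radius = 100,
                      selection = list(prop = 0.5), verbose = FALSE) {
  features <- match.arg(features)
  groups <- assign_tumor_neighborhoods(dataset$tracks, dataset$references,
                                       neighborhood_radius)
  folds <- make_video_folds(dataset$labels)
  if (features == "deep") {
    atl <- build_atlas(dataset$tracks, groups, dataset$labels, R = R)
    ok <- !atl$manifest$skipped
    if (verbose) message("extracting features from ", sum(ok), " images")
    fm <- extract_features(atl$images[ok], backbone, verbose = verbose)
    preds <- train_and_predict(fm, atl$manifest[ok, , drop = FALSE],
                               folds, selection = selection)
    rep <- evaluate_consensus(preds)
    rep$R <- atl$R
  } else {
    kt <- kinematic_table(dataset$tracks, groups)
    fm <- as.matrix(kt[, -(1:3)])
    manifest <- kt[, 1:3]
    manifest$label <-
      dataset$labels$label[match(manifest$video_id, dataset$labels$video_id)]
    preds <- train_and_predict(fm, manifest, folds,
                               selection = list(threshold = 0))
    rep <- evaluate_consensus(preds)
  }
  rep
}
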