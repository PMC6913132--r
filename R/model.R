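## Per-motif random-forest training, evaluation, selection and persistence.
##
## The training protocol: known (CLIP-labeled) sites are the positives; all
## other candidate sites of the same motif are treated as negatives even
## though some are truly methylated but unannotated. About 70% of positives
## form the training positives; an equal number of negatives is sampled
## (without replacement) to balance the training set; everything else is the
## test set. Ten forests are fit on ten resampled balanced training sets and
## the one with the highest training accuracy is kept.

.MODEL_FORMAT_VERSION <- "1"

#' Partition labeled windows into a balanced train / full test split
#'
#' Positives are partitioned `round(train_frac * n_pos)` into training with
#' the remainder as test positives. Training negatives are an equal-size
#' sample (without replacement) of the negatives; all remaining negatives go
#' to the test set. The split is fully reproducible from `seed`.
#'
#' @param windows Labeled `m6a_windows`, normally restricted to one motif.
#' @param train_frac Fraction of positives used for training (default 0.7).
#' @param seed Integer seed.
#' @return A `train_test_split`: integer index vectors `train_pos`,
#'   `train_neg`, `test_pos`, `test_neg` into `windows`, plus the seed.
#' @export
make_split <- function(windows, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(windows, "m6a_windows"))
  pos <- which(windows$label == "positive")
  neg <- which(windows$label == "negative")
  if (length(pos) < 2L)
    stop("configuration error: need at least 2 positive windows, have ",
         length(pos))
  n_train_pos <- round(train_frac * length(pos))
  if (n_train_pos >= length(pos))
    stop("configuration error: train_frac ", train_frac,
         " leaves no test positives (", length(pos), " positives)")
  if (n_train_pos < 1L)
    stop("configuration error: train_frac ", train_frac,
         " leaves no training positives")
  if (length(neg) < n_train_pos)
    stop("configuration error: need ", n_train_pos,
         " negatives to balance training, have ", length(neg))
  set.seed(seed)
  train_pos <- sort(sample(pos, n_train_pos))
  train_neg <- sort(sample(neg, n_train_pos))
  structure(list(train_pos = train_pos,
                 train_neg = train_neg,
                 test_pos = setdiff(pos, train_pos),
                 test_neg = setdiff(neg, train_neg),
                 seed = as.integer(seed)),
            class = "train_test_split")
}

.feature_matrix <- function(values) {
  # offset column names like "-10" are not syntactic; use stable V1..Vk
  colnames(values) <- paste0("V", seq_len(ncol(values)))
  values
}

.fit_forest <- function(x, y, n_trees, node_size) {
  # y: factor with levels c("negative", "positive")
  if (length(unique(y)) < 2L)
    stop("configuration error: single-class training set")
  randomForest::randomForest(x = .feature_matrix(x), y = y, ntree = n_trees,
                             nodesize = node_size)
}

.forest_prob <- function(rf, x) {
  unname(stats::predict(rf, newdata = .feature_matrix(x),
                        type = "prob")[, "positive"])
}

#' Train the best-of-n forest for one motif
#'
#' Fixes the 70/30 positive partition once (under `seed`), then fits `n_runs`
#' forests, run `r` drawing a fresh balanced negative training sample under
#' `seed + r`. Keeping the positive test set constant across runs makes the
#' run accuracies comparable. The run with the highest training accuracy —
#' measured out-of-bag on its balanced training set, since plug-in training
#' accuracy of a forest is always near 1 — is returned; ties go to the lowest
#' run index.
#'
#' @param windows Labeled `m6a_windows` for a single motif.
#' @param train_frac Fraction of positives used for training.
#' @param n_runs Number of resampled training sets (default 10).
#' @param n_trees Trees per forest (default 100).
#' @param node_size Minimum terminal-node size (default 1).
#' @param seed Integer seed.
#' @return A `motif_model`: the fitted forest, its hyperparameters, the
#'   winning run's split, the per-run training accuracies and the selected
#'   `training_accuracy`.
#' @export
train_motif_model <- function(windows, train_frac = 0.7, n_runs = 10L,
                              n_trees = 100L, node_size = 1L, seed = 1L) {
  stopifnot(inherits(windows, "m6a_windows"), n_runs >= 1L)
  motif <- unique(windows$sites$motif)
  if (length(motif) != 1L)
    stop("train_motif_model expects windows of a single motif, got: ",
         paste(motif, collapse = ", "))
  pos <- which(windows$label == "positive")
  neg <- which(windows$label == "negative")
  if (length(pos) < 2L)
    stop("configuration error: need at least 2 positive windows for ", motif)
  n_train_pos <- round(train_frac * length(pos))
  if (n_train_pos >= length(pos) || n_train_pos < 1L)
    stop("configuration error: train_frac ", train_frac,
         " gives a degenerate positive split for ", motif)
  if (length(neg) < n_train_pos)
    stop("configuration error: need ", n_train_pos,
         " negatives to balance training for ", motif, ", have ",
         length(neg))
  set.seed(seed)
  train_pos <- sort(sample(pos, n_train_pos))
  test_pos <- setdiff(pos, train_pos)
  runs <- vector("list", n_runs)
  acc <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    train_neg <- sort(sample(neg, n_train_pos))
    idx <- c(train_pos, train_neg)
    y <- factor(windows$label[idx], levels = c("negative", "positive"))
    rf <- .fit_forest(windows$values[idx, , drop = FALSE], y, n_trees,
                      node_size)
    acc[r] <- 1 - unname(rf$err.rate[n_trees, "OOB"])
    runs[[r]] <- list(rf = rf, train_neg = train_neg)
  }
  best <- which.max(acc)                       # ties -> lowest run index
  split <- structure(list(train_pos = train_pos,
                          train_neg = runs[[best]]$train_neg,
                          test_pos = test_pos,
                          test_neg = setdiff(neg, runs[[best]]$train_neg),
                          seed = as.integer(seed)),
                     class = "train_test_split")
  train_rows <- c(train_pos, runs[[best]]$train_neg)
  structure(list(motif = motif,
                 classifier = runs[[best]]$rf,
                 train_keys = paste(windows$sites$ref[train_rows],
                                    windows$sites$a_pos[train_rows],
                                    windows$sites$strand[train_rows],
                                    sep = "\r"),
                 hyperparameters = list(n_trees = as.integer(n_trees),
                                        node_size = as.integer(node_size),
                                        train_frac = train_frac,
                                        n_runs = as.integer(n_runs),
                                        seed = as.integer(seed),
                                        best_run = as.integer(best)),
                 training_accuracy = acc[best],
                 run_accuracies = acc,
                 split = split,
                 flank = windows$flank),
            class = "motif_model")
}

#' Evaluate a motif model on its held-out test set
#'
#' Three metrics over the test set, at call threshold `threshold` on the
#' predicted probability:
#' * `clip_detection_rate` — fraction of test positives (held-out known sites)
#'   called positive; this is the protocol's "accuracy".
#' * `precision` — TP / (TP + FP) over the pooled test positives + negatives
#'   (`NA` if nothing is called positive).
#' * `roc_auc` — threshold-free AUC over the same pool.
#'
#' Because unannotated true sites sit in the negative pool, precision and AUC
#' are systematically understated on real data; the qualification thresholds
#' account for that.
#'
#' @param model A `motif_model`.
#' @param windows The `m6a_windows` the model's split indexes into.
#' @param split Optionally a different `train_test_split`; defaults to the
#'   model's own.
#' @param threshold Call threshold on predicted probability (default 0.5).
#' @return A one-row data frame of metrics and counts.
#' @export
evaluate_model <- function(model, windows, split = model$split,
                           threshold = 0.5) {
  stopifnot(inherits(model, "motif_model"), inherits(windows, "m6a_windows"))
  if (length(split$test_pos) == 0L)
    stop("undefined metric: empty test positive set")
  pool <- c(split$test_pos, split$test_neg)
  truth <- c(rep(1L, length(split$test_pos)),
             rep(0L, length(split$test_neg)))
  prob <- .forest_prob(model$classifier,
                       windows$values[pool, , drop = FALSE])
  call_pos <- prob >= threshold
  tp <- sum(call_pos & truth == 1L)
  fp <- sum(call_pos & truth == 0L)
  data.frame(motif = model$motif,
             clip_detection_rate = mean(prob[truth == 1L] >= threshold),
             precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
             roc_auc = roc_auc(prob[truth == 1L], prob[truth == 0L]),
             n_train_pos = length(split$train_pos),
             n_test_pos = length(split$test_pos),
             n_test_neg = length(split$test_neg),
             training_accuracy = model$training_accuracy,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Threshold-free AUC for positive-class scores against negative-class
#' scores, computed with `pROC`.
#'
#' @param pos_scores Scores of true positives.
#' @param neg_scores Scores of true negatives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    return(NA_real_)
  scores <- c(pos_scores, neg_scores)
  labels <- c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores)))
  if (length(unique(scores)) == 1L) return(0.5)
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0L, 1L),
                                 direction = "<", quiet = TRUE)))
}

#' Train per-motif random-forest classifiers
#'
#' The central fitting function: for every requested DRACH 5-mer with enough
#' labeled windows it runs the best-of-`n_runs` training protocol
#' ([train_motif_model()]) and evaluates the winner on its held-out test set.
#'
#' @param windows Labeled `m6a_windows` covering one or more motifs.
#' @param motifs Motifs to train; `NULL` (default) trains every motif present
#'   with at least 2 positives and enough negatives to balance. Explicitly
#'   requested motifs lacking data raise an error.
#' @param train_frac,n_runs,n_trees,node_size See [train_motif_model()].
#' @param threshold Call threshold used for the evaluation metrics.
#' @param seed Integer seed. Motif `m` (in sorted order) trains under
#'   `seed + 1000 * (rank(m) - 1)` so per-motif streams are disjoint.
#' @return An `m6a_model_set` with one `motif_model` per motif, the shared
#'   flank, and an evaluation-metrics table (one row per motif).
#' @seealso [predict.m6a_model_set()], [select_qualifying_motifs()]
#' @export
m6a_train <- function(windows, motifs = NULL, train_frac = 0.7,
                      n_runs = 10L, n_trees = 100L, node_size = 1L,
                      threshold = 0.5, seed = 1L) {
  stopifnot(inherits(windows, "m6a_windows"))
  present <- sort(unique(windows$sites$motif))
  explicit <- !is.null(motifs)
  if (!explicit) motifs <- present
  motifs <- sort(motifs)
  models <- list()
  metrics <- list()
  for (m in motifs) {
    idx <- which(windows$sites$motif == m)
    w <- windows[idx]
    n_pos <- sum(w$label == "positive")
    n_neg <- sum(w$label == "negative")
    feasible <- n_pos >= 2L && round(train_frac * n_pos) < n_pos &&
      n_neg >= round(train_frac * n_pos)
    if (!feasible) {
      if (explicit)
        stop("configuration error: motif ", m, " has ", n_pos,
             " positives / ", n_neg, " negatives; cannot train")
      next
    }
    seed_m <- seed + 1000L * (match(m, motifs) - 1L)
    fit <- train_motif_model(w, train_frac = train_frac, n_runs = n_runs,
                             n_trees = n_trees, node_size = node_size,
                             seed = seed_m)
    models[[m]] <- fit
    metrics[[m]] <- evaluate_model(fit, w, threshold = threshold)
  }
  if (length(models) == 0L)
    stop("configuration error: no motif has enough labeled windows to train")
  structure(list(models = models,
                 flank = windows$flank,
                 threshold = threshold,
                 metrics = do.call(rbind, c(metrics,
                                            make.row.names = FALSE)),
                 format_version = .MODEL_FORMAT_VERSION),
            class = "m6a_model_set")
}

#' Evaluation metrics of a model set
#'
#' @param models An `m6a_model_set`.
#' @return Data frame with one row per motif: `clip_detection_rate`,
#'   `precision`, `roc_auc` and the split counts.
#' @export
motif_metrics <- function(models) {
  stopifnot(inherits(models, "m6a_model_set"))
  models$metrics
}

#' Select motifs whose models qualify for prediction
#'
#' A motif is retained only when all three strict inequalities hold:
#' CLIP-detection rate > `acc_min`, precision > `prec_min` and ROC AUC >
#' `auc_min`. Motifs with an undefined (`NA`) metric never qualify.
#'
#' @param metrics Metrics table from [motif_metrics()] (or an
#'   `m6a_model_set`).
#' @param acc_min,prec_min,auc_min Strict lower bounds
#'   (defaults 0.7, 0.85, 0.67).
#' @return Character vector of qualifying motifs, sorted.
#' @export
select_qualifying_motifs <- function(metrics, acc_min = 0.7,
                                     prec_min = 0.85, auc_min = 0.67) {
  if (inherits(metrics, "m6a_model_set")) metrics <- metrics$metrics
  ok <- !is.na(metrics$clip_detection_rate) & !is.na(metrics$precision) &
    !is.na(metrics$roc_auc) &
    metrics$clip_detection_rate > acc_min &
    metrics$precision > prec_min &
    metrics$roc_auc > auc_min
  sort(metrics$motif[ok])
}

#' ROC AUC of predictions against a fixture's ground truth
#'
#' Matches predicted probabilities to the synthetic manifest by site identity
#' and computes the AUC against the *true* methylation status — including
#' truly methylated sites the training labels omitted. By default the sites
#' that entered any model's training set are excluded, so the value measures
#' generalization rather than memorization of training labels.
#'
#' @param predictions An `m6a_predictions` data frame.
#' @param manifest Manifest data frame from [manifest_truth()] /
#'   [generate_fixture()].
#' @param models Optionally the `m6a_model_set` whose training sites should
#'   be excluded.
#' @return AUC in `[0, 1]`.
#' @export
manifest_auc <- function(predictions, manifest, models = NULL) {
  key_p <- paste(predictions$ref, predictions$a_pos, sep = "\r")
  key_m <- paste(manifest$ref, manifest$a_pos, sep = "\r")
  idx <- match(key_p, key_m)
  keep <- !is.na(idx)
  if (!is.null(models)) {
    stopifnot(inherits(models, "m6a_model_set"))
    train <- unlist(lapply(models$models, `[[`, "train_keys"),
                    use.names = FALSE)
    full_key <- paste(predictions$ref, predictions$a_pos,
                      predictions$strand, sep = "\r")
    keep <- keep & !(full_key %in% train)
  }
  truth <- manifest$methylated[idx[keep]]
  prob <- predictions$probability[keep]
  roc_auc(prob[truth], prob[!truth])
}

#' Persist a model set
#'
#' Serializes the model set — forests, hyperparameters, metrics, flank and a
#' format-version tag — so that loading reproduces identical predictions.
#'
#' @param models An `m6a_model_set`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
save_models <- function(models, path) {
  stopifnot(inherits(models, "m6a_model_set"))
  saveRDS(models, path)
  invisible(path)
}

#' Load a persisted model set
#'
#' @param path File written by [save_models()].
#' @return The `m6a_model_set`.
#' @export
load_models <- function(path) {
  models <- readRDS(path)
  if (!inherits(models, "m6a_model_set") ||
      !identical(models$format_version, .MODEL_FORMAT_VERSION))
    stop("not a compatible model file (format version mismatch): ", path)
  models
}

#' @export
print.m6a_model_set <- function(x, ...) {
  cat("<m6a_model_set> ", length(x$models), " per-motif forest(s), flank ",
      x$flank, "\n", sep = "")
  cat("  motifs:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted model set
#'
#' Prints the per-motif evaluation metrics and the qualifying-motif set.
#'
#' @param object An `m6a_model_set`.
#' @param ... Unused.
#' @return The metrics table, invisibly.
#' @method summary m6a_model_set
#' @export
summary.m6a_model_set <- function(object, ...) {
  cat("Per-motif random-forest classifiers (flank ", object$flank, ", ",
      2L * object$flank + 1L, " features)\n\n", sep = "")
  m <- object$metrics
  m[c("clip_detection_rate", "precision", "roc_auc",
      "training_accuracy")] <-
    lapply(m[c("clip_detection_rate", "precision", "roc_auc",
               "training_accuracy")], round, 3)
  print(m, row.names = FALSE)
  q <- select_qualifying_motifs(object)
  cat("\nQualifying motifs (detection > 0.7, precision > 0.85, AUC > 0.67): ",
      if (length(q)) paste(q, collapse = ", ") else "none", "\n", sep = "")
  invisible(object$metrics)
}

#' Mean feature importance by window offset
#'
#' Averages each forest's variable importance (mean decrease in Gini) across
#' motifs and plots it against the window offset, highlighting where the
#' discriminative signal sits relative to the central A.
#'
#' @param x An `m6a_model_set`.
#' @param ... Passed to [graphics::barplot()].
#' @return The offset-indexed mean importance vector, invisibly.
#' @method plot m6a_model_set
#' @export
plot.m6a_model_set <- function(x, ...) {
  imp <- sapply(x$models, function(m)
    randomForest::importance(m$classifier)[, 1L])
  mean_imp <- rowMeans(as.matrix(imp))
  names(mean_imp) <- as.character(seq.int(-x$flank, x$flank))
  graphics::barplot(mean_imp, names.arg = names(mean_imp),
                    xlab = "offset from central A",
                    ylab = "mean decrease in Gini", ...)
  invisible(mean_imp)
}
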