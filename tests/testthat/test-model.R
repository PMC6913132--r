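test_that("split partitions positives 70/30 and balances training negatives", {
  w <- make_windows(n_pos = 10, n_neg = 100)
  sp <- make_split(w, train_frac = 0.7, seed = 3)
  expect_length(sp$train_pos, 7L)
  expect_length(sp$train_neg, 7L)
  expect_length(sp$test_pos, 3L)
  expect_length(sp$test_neg, 93L)
  # positives partition, negatives split without replacement
  expect_setequal(c(sp$train_pos, sp$test_pos), which(w$label == "positive"))
  expect_length(intersect(sp$train_neg, sp$test_neg), 0L)
  expect_setequal(c(sp$train_neg, sp$test_neg), which(w$label == "negative"))
})

test_that("split is reproducible from its seed and rejects degenerate inputs", {
  w <- make_windows(n_pos = 10, n_neg = 100)
  expect_identical(make_split(w, seed = 9), make_split(w, seed = 9))
  expect_false(identical(make_split(w, seed = 9)$train_neg,
                         make_split(w, seed = 10)$train_neg))
  expect_error(make_split(w, train_frac = 1.0), "no test positives")
  expect_error(make_split(make_windows(n_pos = 1, n_neg = 50)),
               "at least 2 positive")
  expect_error(make_split(make_windows(n_pos = 10, n_neg = 3)),
               "negatives to balance")
})

test_that("best-of-n keeps the run with the highest training accuracy", {
  w <- make_windows(n_pos = 30, n_neg = 120, peak = 0.15, noise = 0.12,
                    seed = 4)
  fit <- train_motif_model(w, n_runs = 10, n_trees = 60, seed = 5)
  expect_length(fit$run_accuracies, 10L)
  expect_equal(fit$training_accuracy, max(fit$run_accuracies))
  expect_equal(fit$hyperparameters$best_run,
               which.max(fit$run_accuracies))
  # n_runs = 1 is the identity case
  one <- train_motif_model(w, n_runs = 1, n_trees = 60, seed = 5)
  expect_equal(one$training_accuracy, one$run_accuracies[1])
})

test_that("training is seed-reproducible end to end", {
  w <- make_windows(n_pos = 20, n_neg = 80, seed = 6)
  a <- train_motif_model(w, n_runs = 3, n_trees = 40, seed = 21)
  b <- train_motif_model(w, n_runs = 3, n_trees = 40, seed = 21)
  expect_identical(a$run_accuracies, b$run_accuracies)
  expect_identical(a$split, b$split)
  probe <- make_windows(n_pos = 5, n_neg = 5, seed = 99)
  expect_identical(predict_sites(probe, structure(
                     list(models = list(GGACT = a), flank = 10L,
                          format_version = "1"),
                     class = "m6a_model_set"),
                     motifs = "GGACT")$probability,
                   predict_sites(probe, structure(
                     list(models = list(GGACT = b), flank = 10L,
                          format_version = "1"),
                     class = "m6a_model_set"),
                     motifs = "GGACT")$probability)
})

test_that("linearly separable classes train to perfect accuracy", {
  w <- make_windows(n_pos = 25, n_neg = 25, baseline = 0.3, peak = 0.5,
                    noise = 0.02, seed = 8)
  fit <- train_motif_model(w, n_runs = 2, seed = 2)
  expect_equal(fit$training_accuracy, 1.0)
  m <- evaluate_model(fit, w)
  expect_equal(m$clip_detection_rate, 1.0)
  expect_equal(m$roc_auc, 1.0)
})

test_that("evaluation metrics follow their counting definitions", {
  # hand-built scores: clip detection = called test positives / test positives
  w <- make_windows(n_pos = 20, n_neg = 100, seed = 31)
  fit <- train_motif_model(w, n_runs = 2, seed = 31)
  m <- evaluate_model(fit, w)
  pool <- c(fit$split$test_pos, fit$split$test_neg)
  prob <- m6Aforest:::.forest_prob(fit$classifier, w$values[pool, ])
  np <- length(fit$split$test_pos)
  truth <- rep(c(TRUE, FALSE), c(np, length(fit$split$test_neg)))
  expect_equal(m$clip_detection_rate, mean(prob[truth] >= 0.5))
  tp <- sum(prob >= 0.5 & truth); fp <- sum(prob >= 0.5 & !truth)
  expect_equal(m$precision, tp / (tp + fp))
  expect_equal(m$roc_auc, auc_pairs(prob[truth], prob[!truth]),
               tolerance = 1e-12)
  expect_equal(m$n_test_neg, length(fit$split$test_neg))
})

test_that("AUC matches the closed-form pairwise statistic", {
  # perfectly separated scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.7), c(0.3, 0.2, 0.1)), 1.0)
  # label-independent constant scores
  expect_equal(roc_auc(rep(0.4, 5), rep(0.4, 7)), 0.5)
  # random score lists against the independent pairwise oracle
  set.seed(14)
  for (i in 1:10) {
    pos <- round(runif(20), 2)   # rounding forces ties
    neg <- round(runif(30), 2)
    expect_equal(roc_auc(pos, neg), auc_pairs(pos, neg), tolerance = 1e-12)
  }
})

test_that("clip detection rate is monotone non-increasing in threshold", {
  w <- make_windows(n_pos = 30, n_neg = 90, seed = 15)
  fit <- train_motif_model(w, n_runs = 2, seed = 15)
  rates <- sapply(seq(0, 1, by = 0.1), function(t)
    evaluate_model(fit, w, threshold = t)$clip_detection_rate)
  expect_true(all(diff(rates) <= 0))
})

test_that("motif qualification applies strict inequalities on all three metrics", {
  metrics <- data.frame(
    motif = c("GGACT", "AGACT", "GGACA", "GGACC", "TGACT", "GAACT"),
    clip_detection_rate = c(0.79, 0.65, 0.70, 0.71, 0.71, NA),
    precision          = c(0.90, 0.95, 0.90, 0.85, 0.86, 0.9),
    roc_auc            = c(0.70, 0.80, 0.70, 0.70, 0.67, 0.7))
  q <- select_qualifying_motifs(metrics)
  expect_equal(q, "GGACT")            # all three strictly exceeded
  # boundary triple (0.70, 0.90, 0.70) fails the strict accuracy bound
  expect_false("GGACA" %in% q)
  # precision exactly at 0.85 fails
  expect_false("GGACC" %in% q)
  # AUC exactly at 0.67 fails
  expect_false("TGACT" %in% q)
  # NA metrics never qualify
  expect_false("GAACT" %in% q)
})

test_that("model persistence round-trips predictions exactly", {
  w <- make_windows(n_pos = 20, n_neg = 60, seed = 16)
  w$sites$motif <- "GGACT"
  fit <- m6a_train(w, n_runs = 2, seed = 16)
  path <- tempfile(fileext = ".rds")
  save_models(fit, path)
  back <- load_models(path)
  probe <- make_windows(n_pos = 10, n_neg = 10, seed = 17)
  expect_identical(predict_sites(probe, fit, motifs = "GGACT"),
                   predict_sites(probe, back, motifs = "GGACT"))
  # incompatible files are refused
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format_version = "0"), bad)
  expect_error(load_models(bad), "format version")
})

test_that("m6a_train trains per motif and refuses infeasible explicit requests", {
  w1 <- make_windows(n_pos = 15, n_neg = 60, motif = "GGACT", seed = 18)
  w2 <- make_windows(n_pos = 12, n_neg = 50, motif = "AGACT", seed = 19)
  w <- w1
  w$sites <- rbind(w1$sites, w2$sites)
  w$sites$a_pos <- seq(10L, by = 25L, length.out = nrow(w$sites))
  w$values <- rbind(w1$values, w2$values)
  w$coverage <- c(w1$coverage, w2$coverage)
  w$label <- c(w1$label, w2$label)
  fit <- m6a_train(w, n_runs = 2, seed = 20)
  expect_named(fit$models, c("AGACT", "GGACT"))
  expect_equal(nrow(motif_metrics(fit)), 2L)
  expect_error(m6a_train(w, motifs = c("GGACT", "TGACT"), n_runs = 2),
               "TGACT")
})
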