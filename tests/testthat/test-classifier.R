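test_that("holdout splits keep whole wells out of training", {
  d <- make_blobs(n_per_class = 40, n_wells = 8, seed = 2)
  sp <- split_holdout(d, 2, seed = 7)
  expect_length(unique(sp$train$well_id), 6)
  expect_length(intersect(sp$train$well_id, sp$test$well_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(d))
  sp2 <- split_holdout(d, 2, seed = 7)
  expect_identical(sp$test_wells, sp2$test_wells)
  expect_error(split_holdout(d[d$well_id %in% unique(d$well_id)[1:2], ], 2),
               "at least 3 wells")
})

test_that("the boosted ensemble separates blobs and respects its contracts", {
  d <- make_blobs(n_per_class = 50, seed = 3)
  m <- train_rusboost(d, n_rounds = 20, max_depth = 2, seed = 4)
  expect_true(all(m$history$weighted_error < 0.5))
  pred <- predict(m, d, type = "class")
  expect_equal(mean(pred == d$label), 1.0)
  scores <- predict(m, d, type = "prob")
  expect_true(all(scores >= 0 & scores <= 1))
  imp <- rusboost_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  # broom-style accessors
  expect_equal(nrow(tidy(m)), length(m$trees))
  expect_equal(glance(m)$n_trees, length(m$trees))
})

test_that("each boosting round trains on a class-balanced resample", {
  # 5% minority: with ratio 1 each round's resample holds equal class
  # counts, visible as the fitted tree's root-node size
  d <- make_blobs(n_per_class = 100, seed = 5)
  d$label <- c(rep("non-nociceptor", 190), rep("nociceptor", 10))
  m <- train_rusboost(d, n_rounds = 5, max_depth = 1, seed = 6)
  for (tree in m$trees) {
    # the fitted tree saw n_min + n_min = 20 rows
    expect_equal(sum(tree$frame$n[1]), 20)
  }
})

test_that("a single depth-1 round finds the impurity-optimal stump", {
  toy <- tibble::tibble(
    mfr_hz = c(0.2, 1.1, 2.3, 3.0, 4.2, 5.1),
    isicv = c(1.2, 0.4, 0.9, 1.5, 0.3, 0.8),
    sync_median = c(0.1, 0.2, 0.15, 0.3, 0.25, 0.05),
    sync_skewness = c(0, 0.5, -0.2, 0.1, 0.4, 0.3),
    label = c("non-nociceptor", "non-nociceptor", "nociceptor",
              "non-nociceptor", "nociceptor", "nociceptor"))
  m <- train_rusboost(toy, n_rounds = 1, max_depth = 1, seed = 5)
  splits <- m$trees[[1]]$splits
  got_feature <- rownames(splits)[1]
  got_improve <- splits[1, "improve"]
  # exhaustive search over all feature-threshold splits, weighted Gini
  y <- toy$label == "nociceptor"
  best <- -Inf
  best_features <- character(0)
  gini_dec <- function(v, cut) {
    part <- function(idx) {
      if (!sum(idx)) return(0)
      p <- mean(y[idx])
      sum(idx) / length(y) * 2 * p * (1 - p)
    }
    2 * mean(y) * (1 - mean(y)) - part(v < cut) - part(v >= cut)
  }
  for (f in c("mfr_hz", "isicv", "sync_median", "sync_skewness")) {
    v <- toy[[f]]
    cuts <- sort(unique(v))
    cuts <- (head(cuts, -1) + tail(cuts, -1)) / 2
    for (cc in cuts) {
      dec <- gini_dec(v, cc)
      if (dec > best + 1e-12) {
        best <- dec
        best_features <- f
      } else if (abs(dec - best) <= 1e-12) {
        best_features <- union(best_features, f)
      }
    }
  }
  expect_equal(got_improve, best, tolerance = 1e-10)
  expect_true(got_feature %in% best_features)
})

test_that("degenerate classifier inputs are rejected", {
  d <- make_blobs(20, seed = 9)
  one_class <- dplyr::mutate(d, label = "nociceptor")
  expect_error(train_rusboost(one_class), "both classes")
  bad <- d
  bad$mfr_hz[1] <- NaN
  expect_error(train_rusboost(bad), "non-finite")
})

test_that("reference models emit calibrated scores and separate blobs", {
  d <- make_blobs(n_per_class = 50, seed = 10)
  sp <- split_holdout(d, 2, seed = 10)
  models <- train_reference_models(sp$train, seed = 10)
  models$tree <- train_rusboost(sp$train, n_rounds = 30, seed = 10)
  for (nm in names(models)) {
    s <- score_units(models[[nm]], sp$test)
    expect_true(all(s >= 0 & s <= 1), info = nm)
    expect_equal(roc_auc(s, sp$test$label == "nociceptor")$auc, 1,
                 tolerance = 0.02, info = nm)
  }
  # inverse-prevalence weights: ratio equals majority/minority count ratio
  imb <- d[c(1:80, 91:100), ]
  m <- train_reference_models(imb, models = "log", seed = 1)$log
  counts <- table(label_vector(imb))
  expect_equal(m$class_weights[["pos"]] / m$class_weights[["neg"]],
               unname(counts["neg"] / counts["pos"]), tolerance = 1e-12)
})

test_that("hyperparameter search is seeded, bounded and dominant-point-consistent", {
  d <- make_blobs(n_per_class = 30, seed = 12)
  t1 <- tune_hyperparameters("knn", d, budget = 1, inner_k = 3, seed = 3)
  expect_equal(nrow(t1$history), 1)
  expect_equal(t1$best, as.list(t1$history[1, setdiff(
    names(t1$history), "mean_auc")]))
  t2 <- tune_hyperparameters("knn", d, budget = 4, inner_k = 3, seed = 3)
  t3 <- tune_hyperparameters("knn", d, budget = 4, inner_k = 3, seed = 3)
  expect_identical(t2$best, t3$best)
  expect_identical(t2$method, "random_search")
  # the returned point attains the maximum of its own history
  expect_equal(t2$best_auc, max(t2$history$mean_auc))
  expect_error(tune_hyperparameters("knn", d, budget = 0), "budget")
})

test_that("cross-validation is stratified, partitioning and separable-exact", {
  d <- make_blobs(n_per_class = 40, seed = 13)
  cv <- crossval_auc(d, models = c("tree", "lda"), k = 5, seed = 13)
  folds <- attr(cv, "folds")
  expect_length(folds, nrow(d))
  expect_setequal(unique(folds), 1:5)
  y <- d$label == "nociceptor"
  per_fold <- table(folds, y)
  expect_lte(diff(range(per_fold[, "TRUE"])), 1)
  expect_lte(diff(range(per_fold[, "FALSE"])), 1)
  expect_true(all(cv$auc > 0.95))
  expect_equal(nrow(cv), 2 * 5)
  expect_error(crossval_auc(d[1:12, ], k = 10), "at least k")
})

test_that("model comparison reproduces the rank-test oracle", {
  cv_same <- tibble::tibble(model = rep(c("a", "b", "c", "d", "e"),
                                        each = 10),
                            auc = rep(0.9, 50))
  out <- compare_models(cv_same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$decision, "no model outperforms")

  g <- list(a = c(1, 2, 3), b = c(10, 11, 12))
  cv2 <- tibble::tibble(model = rep(names(g), lengths(g)), auc = unlist(g))
  out2 <- compare_models(cv2)
  expect_equal(out2$statistic, kw_oracle(g), tolerance = 1e-12)
  # exchangeability: permuting group order leaves H unchanged
  cv2r <- cv2[rev(seq_len(nrow(cv2))), ]
  expect_equal(compare_models(cv2r)$statistic, out2$statistic,
               tolerance = 1e-12)
  expect_error(compare_models(cv2[c(1, 4), ]), ">= 2 AUC values")
})

test_that("ROC/AUC equals pairwise concordance with ties at one half", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c(FALSE, FALSE, TRUE, TRUE))$auc, 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.9, 0.95),
                       c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both classes")
  set.seed(14)
  for (r in 1:20) {
    n <- sample(5:60, 1)
    s <- round(runif(n), 2) # deliberate ties
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(roc_auc(s, l)$auc, auc_oracle(s, l), tolerance = 1e-12)
    roc <- roc_auc(s, l)$roc
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  s <- runif(80)
  l <- runif(80) < 0.45
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("holdout reports compute the confusion-derived metrics", {
  # TP 3, FN 1, FP 1, TN 5 at the 0.5 threshold
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.4, 0.45)
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE)
  rep <- nocilabel:::score_report(scores, truth)
  expect_equal(rep$accuracy, 0.8)
  expect_equal(unname(rep$f1["nociceptor"]), 0.75)
  expect_equal(unname(rep$confusion["nociceptor", "nociceptor"]), 3)
  # an all-majority predictor has zero minority F1
  rep0 <- nocilabel:::score_report(rep(0.1, 10), truth)
  expect_equal(unname(rep0$f1["nociceptor"]), 0)
})

test_that("evaluate_holdout reports natural and balanced metrics", {
  d <- make_blobs(n_per_class = 50, seed = 16)
  sp <- split_holdout(d, 2, seed = 16)
  m <- train_rusboost(sp$train, n_rounds = 30, seed = 16)
  rep <- evaluate_holdout(m, sp$test, seed = 16)
  expect_s3_class(rep, "classifier_report")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_true(all(rep$f1 >= 0 & rep$f1 <= 1))
  expect_equal(sum(rep$confusion), nrow(sp$test))
  expect_equal(rep$balanced$n_test,
               2 * min(table(sp$test$label)))
  td <- tidy(rep)
  expect_equal(td$natural[td$metric == "accuracy"], rep$accuracy)
  expect_error(evaluate_holdout(m, sp$test[0, ]), "empty test")
})

test_that("the confidence-retention curve trades retention for accuracy", {
  # confidences {0.6, 0.9, 0.95}, correctness {0, 1, 1}
  scores <- c(0.4, 0.9, 0.95)
  truth <- c(TRUE, TRUE, TRUE)
  curve <- confidence_retention_curve(scores, truth, cutoffs = c(0.5, 0.8, 1))
  expect_equal(curve$retention[curve$confidence == 0.5], 1)
  expect_equal(curve$accuracy[curve$confidence == 0.8], 1)
  expect_equal(curve$retention[curve$confidence == 0.8], 2 / 3,
               tolerance = 1e-12)
  expect_true(all(diff(curve$retention) <= 0))
  expect_error(confidence_retention_curve(scores, truth, cutoffs = 0.3),
               "\\[0.5, 1\\]")
})

test_that("PCA projects with training loadings and recovers planted planes", {
  d <- make_blobs(n_per_class = 60, seed = 17)
  pp <- pca_projection(d[1:90, ], d[91:120, ])
  expect_true(all(diff(pp$explained_variance) <= 1e-12))
  # the training mean row projects to the origin
  mu <- dplyr::summarise(d[1:90, ], dplyr::across(
    c(mfr_hz, isicv, sync_median, sync_skewness), mean))
  origin <- pca_projection(d[1:90, ], mu)$test
  expect_equal(unname(unlist(origin[c("PC1", "PC2")])), c(0, 0),
               tolerance = 1e-10)
  # 2-D data embedded in 4-D by rotation: the PC plane recovers it
  set.seed(18)
  rot <- qr.Q(qr(matrix(rnorm(16), 4)))
  z <- cbind(rnorm(200, sd = 3), rnorm(200, sd = 1))
  x4 <- z %*% t(rot[, 1:2])
  emb <- tibble::tibble(mfr_hz = x4[, 1], isicv = x4[, 2],
                        sync_median = x4[, 3], sync_skewness = x4[, 4])
  pp2 <- pca_projection(emb)
  sds <- vapply(emb, sd, numeric(1))
  true_plane <- qr.Q(qr(diag(1 / sds) %*% rot[, 1:2]))
  fitted_plane <- qr.Q(qr(pp2$loadings))
  angles <- acos(pmin(1, svd(t(true_plane) %*% fitted_plane)$d))
  expect_lt(max(angles), 1e-6)
  # zero-variance features are named in the error
  dz <- dplyr::mutate(d, isicv = 1)
  expect_error(pca_projection(dz), "isicv")
})
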