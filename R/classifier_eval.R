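# Stratified fold ids: within each class, fold labels are dealt out in
# shuffled order, so class proportions match across folds to within 1 unit.
stratified_folds <- function(y, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(table(y) < k)) {
    stop("each class needs at least k = ", k, " members for stratification",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' ROC curve and AUC from scores
#'
#' The AUC is the concordance probability that a random positive scores
#' above a random negative, with tied scores counted one half (midrank
#' formula). The ROC curve is traced over every score threshold.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical (or coercible) positive-class indicators.
#' @return A list with `auc` and `roc` (tibble `threshold`, `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be complete and equal length", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an ROC", call. = FALSE)
  }
  r <- rank(scores) # midranks: ties count one half in the concordance
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  keep <- c(s_sorted[-length(s_sorted)] != s_sorted[-1], TRUE)
  tpr <- cumsum(l_sorted)[keep] / n_pos
  fpr <- cumsum(!l_sorted)[keep] / n_neg
  roc <- tibble::tibble(threshold = c(Inf, s_sorted[keep]),
                        fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}

#' Cross-validated AUC of a model panel
#'
#' Stratified k-fold cross-validation: each model family is refitted on
#' k-1 folds and scored by AUC on the held-out fold, giving k AUC values
#' per model for group-wise comparison.
#'
#' @param data Labeled feature table (the training partition).
#' @param models Character vector of families (subset of
#'   `c("tree", "log", "lda", "knn", "fnn")`).
#' @param k Number of folds (default 10).
#' @param hyperparameters Optional named list of per-family parameter lists.
#' @param seed Integer seed (fold assignment and per-fold fits).
#' @return An object of class `cv_result`: tibble (`model`, `fold`, `auc`)
#'   with the fold assignment in attribute `folds`.
#' @export
crossval_auc <- function(data, models = c("tree", "log", "lda", "knn",
                                          "fnn"),
                         k = 10, hyperparameters = list(), seed = 1L) {
  data <- tibble::as_tibble(data)
  y <- label_vector(data)
  folds <- stratified_folds(y, k, derive_seed(seed, 53L))
  res <- list()
  for (m in models) {
    hp <- hyperparameters[[m]] %||% list()
    for (f in seq_len(k)) {
      tr <- data[folds != f, ]
      te <- data[folds == f, ]
      fit <- train_single_model(m, tr, hp, seed = derive_seed(seed, 59L + f))
      s <- score_units(fit, te)
      res[[length(res) + 1]] <- tibble::tibble(
        model = m, fold = f,
        auc = roc_auc(s, te$label == POSITIVE_CLASS)$auc)
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "folds") <- folds
  class(out) <- c("cv_result", class(out))
  out
}

#' Compare cross-validated models by Kruskal-Wallis rank test
#'
#' Group-wise comparison of the per-fold AUC values across model families
#' (Kruskal-Wallis H with tie correction). When `p >= alpha` the decision
#' is that no model statistically outperforms the others.
#'
#' @param cv A [crossval_auc()] result (or any tibble with `model` and
#'   `auc`).
#' @param alpha Significance level (default 0.05).
#' @return A list with `statistic` (H), `df`, `p_value`, `alpha`, and
#'   `decision` (`"no model outperforms"` or
#'   `"at least one model differs"`).
#' @export
compare_models <- function(cv, alpha = 0.05) {
  cv <- tibble::as_tibble(cv)
  groups <- split(cv$auc, cv$model)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups of >= 2 AUC values", call. = FALSE)
  }
  if (stats::var(unlist(groups)) == 0) {
    # all values identical: H = 0, p = 1 (kruskal.test errors here)
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1,
                alpha = alpha, decision = "no model outperforms"))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, alpha = alpha,
       decision = if (kt$p.value >= alpha) "no model outperforms"
       else "at least one model differs")
}

#' Evaluate a fitted classifier on the held-out wells
#'
#' Scores the test set and reports: the confusion matrix at the 0.5 score
#' threshold, accuracy, per-class F1, AUC with the full ROC curve, feature
#' importances (boosted-tree models), and the confidence-retention curve.
#' Because natural test prevalence and a class-balanced test set answer
#' different questions, the report also carries the same metrics on a
#' seeded class-balanced subsample (`$balanced`).
#'
#' @param model A `rusboost` or `noci_model` object.
#' @param test Labeled feature table of the held-out wells.
#' @param threshold Score threshold for the confusion matrix (default 0.5).
#' @param include_balanced Also evaluate a class-balanced subsample
#'   (default TRUE).
#' @param seed Seed for the balanced subsample draw.
#' @return An object of class `classifier_report`.
#' @export
evaluate_holdout <- function(model, test, threshold = 0.5,
                             include_balanced = TRUE, seed = 1L) {
  test <- tibble::as_tibble(test)
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  truth <- test$label == POSITIVE_CLASS
  if (!any(truth) || all(truth)) {
    stop("test set must contain both classes", call. = FALSE)
  }
  scores <- score_units(model, test)
  report <- score_report(scores, truth, threshold)
  report$importance <- if (inherits(model, "rusboost")) {
    rusboost_importance(model)
  } else NULL
  report$confidence_curve <- confidence_retention_curve(scores, truth,
                                                        threshold = threshold)
  report$n_test <- nrow(test)
  if (include_balanced) {
    set.seed(derive_seed(seed, 61L))
    n_bal <- min(sum(truth), sum(!truth))
    idx <- c(sample(which(truth), n_bal), sample(which(!truth), n_bal))
    report$balanced <- score_report(scores[idx], truth[idx], threshold)
    report$balanced$n_test <- 2L * n_bal
  }
  class(report) <- "classifier_report"
  report
}

score_report <- function(scores, truth, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & truth)
  fn <- sum(!pred & truth)
  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = FALSE,
                      dimnames = list(predicted = c("nociceptor",
                                                    "non-nociceptor"),
                                      truth = c("nociceptor",
                                                "non-nociceptor")))
  f1 <- function(tp, fp, fn) {
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }
  ra <- roc_auc(scores, truth)
  list(confusion = confusion,
       accuracy = (tp + tn) / length(truth),
       f1 = c(`non-nociceptor` = f1(tn, fn, fp),
              nociceptor = f1(tp, fp, fn)),
       auc = ra$auc, roc = ra$roc, scores = scores, truth = truth,
       threshold = threshold)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> n =", x$n_test, "\n")
  cat("  accuracy", format(x$accuracy, digits = 3),
      "| AUC", format(x$auc, digits = 3),
      "| F1(noci)", format(x$f1[["nociceptor"]], digits = 3),
      "| F1(non)", format(x$f1[["non-nociceptor"]], digits = 3), "\n")
  if (!is.null(x$balanced)) {
    cat("  balanced subsample: accuracy",
        format(x$balanced$accuracy, digits = 3),
        "| AUC", format(x$balanced$auc, digits = 3), "\n")
  }
  invisible(x)
}

#' Confidence-retention trade-off curve
#'
#' A prediction's confidence is `max(score, 1 - score)`. For each
#' confidence cutoff `c`, the curve reports the accuracy among predictions
#' with confidence at least `c` and the fraction of the test set retained
#' (monotonically non-increasing in `c`) — the trade between keeping cells
#' and trusting their predicted subtype.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param truth Logical positive-class indicators.
#' @param cutoffs Confidence cutoffs in `[0.5, 1]`.
#' @param threshold Class-decision threshold (default 0.5).
#' @return A tibble with `confidence`, `accuracy` (NA when nothing is
#'   retained), and `retention`.
#' @export
confidence_retention_curve <- function(scores, truth,
                                       cutoffs = seq(0.5, 1, by = 0.025),
                                       threshold = 0.5) {
  if (any(cutoffs < 0.5 | cutoffs > 1)) {
    stop("confidence cutoffs must lie in [0.5, 1]", call. = FALSE)
  }
  conf <- pmax(scores, 1 - scores)
  correct <- (scores >= threshold) == truth
  purrr::map_dfr(cutoffs, function(cc) {
    keep <- conf >= cc
    tibble::tibble(
      confidence = cc,
      accuracy = if (any(keep)) mean(correct[keep]) else NA_real_,
      retention = mean(keep))
  })
}

#' Two-component PCA projection of train and test features
#'
#' Standardises the features on the training set, extracts the loadings
#' from the training covariance, and projects both sets onto the first two
#' principal components — the test set never influences the projection.
#'
#' @param train,test Feature tables (the four baseline feature columns;
#'   `label` carried through if present).
#' @return An object of class `pca_projection`: list with `train`, `test`
#'   (tibbles with `PC1`, `PC2` and any carried columns), `loadings`,
#'   `explained_variance`.
#' @export
pca_projection <- function(train, test = NULL) {
  train <- tibble::as_tibble(train)
  feats <- feature_columns(train)
  if (nrow(train) < 3 || length(feats) < 2) {
    stop("need >= 3 rows and >= 2 feature columns", call. = FALSE)
  }
  xs <- as.matrix(train[feats])
  sds <- apply(xs, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(feats[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- prcomp(xs, center = TRUE, scale. = TRUE)
  project <- function(d) {
    coords <- predict(pc, as.matrix(tibble::as_tibble(d)[feats]))[, 1:2,
                                                                  drop = FALSE]
    out <- tibble::as_tibble(coords)
    if ("label" %in% names(d)) out$label <- d$label
    if ("well_id" %in% names(d)) out$well_id <- d$well_id
    out
  }
  structure(
    list(train = project(train),
         test = if (!is.null(test)) project(test) else NULL,
         loadings = pc$rotation[, 1:2],
         explained_variance = pc$sdev^2 / sum(pc$sdev^2)),
    class = "pca_projection"
  )
}

#' @rdname tidy-nocilabel
#' @export
tidy.classifier_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "f1_non_nociceptor", "f1_nociceptor", "auc"),
    natural = c(x$accuracy, x$f1[["non-nociceptor"]],
                x$f1[["nociceptor"]], x$auc),
    balanced = if (!is.null(x$balanced)) {
      c(x$balanced$accuracy, x$balanced$f1[["non-nociceptor"]],
        x$balanced$f1[["nociceptor"]], x$balanced$auc)
    } else NA_real_
  )
}

#' @rdname tidy-nocilabel
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(n_test = x$n_test, accuracy = x$accuracy, auc = x$auc,
                 f1_nociceptor = x$f1[["nociceptor"]],
                 f1_non_nociceptor = x$f1[["non-nociceptor"]])
}

#' Broom-style tidiers for nocilabel objects
#'
#' @description
#' `tidy()` methods return per-component tibbles (boosting rounds for
#' `rusboost`, metric rows for `classifier_report`); `glance()` methods
#' return one-row model summaries.
#'
#' @param x A `rusboost` model or `classifier_report`.
#' @param ... Unused.
#' @name tidy-nocilabel
NULL
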