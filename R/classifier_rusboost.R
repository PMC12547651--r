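#' Well-level holdout split
#'
#' Assigns `n_holdout_wells` whole wells to the test set so that no unit of
#' a test well ever appears in training (leave-wells-out, the guard against
#' within-well leakage).
#'
#' @param data A labeled feature table (needs a `well_id` column).
#' @param n_holdout_wells Number of wells to hold out (default 2).
#' @param seed Integer seed for the well draw.
#' @return A list with `train` and `test` tibbles and `test_wells`.
#' @export
split_holdout <- function(data, n_holdout_wells = 2, seed = 1L) {
  data <- tibble::as_tibble(data)
  wells <- unique(data$well_id)
  if (length(wells) < n_holdout_wells + 1) {
    stop("need at least ", n_holdout_wells + 1, " wells to hold ",
         n_holdout_wells, " out", call. = FALSE)
  }
  set.seed(derive_seed(seed, 11L))
  test_wells <- sample(wells, n_holdout_wells)
  list(train = data[!data$well_id %in% test_wells, ],
       test = data[data$well_id %in% test_wells, ],
       test_wells = test_wells)
}

POSITIVE_CLASS <- "nociceptor"

feature_columns <- function(data) {
  intersect(c("mfr_hz", "isicv", "sync_median", "sync_skewness"),
            names(data))
}

label_vector <- function(data) {
  if (!"label" %in% names(data)) stop("data has no label column",
                                      call. = FALSE)
  factor(ifelse(data$label == POSITIVE_CLASS, "pos", "neg"),
         levels = c("neg", "pos"))
}

#' Train a random-undersampling boosted decision-tree ensemble
#'
#' The imbalance-aware core learner. Each boosting round (i) randomly
#' undersamples the majority class down to `undersample_ratio` times the
#' minority count, (ii) fits a depth-limited CART tree on the resample using
#' the current boosting weights, (iii) computes the weighted error on the
#' *full* training set, (iv) derives the learner weight
#' `alpha = learning_rate * log((1 - err)/err)` (the adaptive-boosting
#' rule), and (v) upweights misclassified examples and renormalises. Rounds
#' whose weighted error reaches 0.5 are discarded and resampled a bounded
#' number of times; boosting stops early when retries are exhausted or a
#' round is perfect.
#'
#' @param data Labeled feature table (columns `mfr_hz`, `isicv`,
#'   `sync_median`, `sync_skewness`, `label`; the positive class is
#'   `"nociceptor"`).
#' @param n_rounds Number of boosting rounds (default 200).
#' @param max_depth Tree depth limit (default 3).
#' @param learning_rate Shrinkage on the learner weights (default 0.5).
#' @param undersample_ratio Majority:minority ratio of each resample
#'   (default 1, i.e. balanced).
#' @param seed Integer seed driving all undersampling draws.
#' @param max_retries Resampling attempts per round before stopping early.
#' @return An object of class `rusboost`: trees, per-learner weights
#'   (`alphas`), per-round diagnostics, and the training configuration.
#' @export
train_rusboost <- function(data, n_rounds = 200, max_depth = 3,
                           learning_rate = 0.5, undersample_ratio = 1,
                           seed = 1L, max_retries = 5) {
  data <- tibble::as_tibble(data)
  feats <- feature_columns(data)
  if (length(feats) == 0) stop("no feature columns found", call. = FALSE)
  x <- data[feats]
  if (!all(purrr::map_lgl(x, ~ all(is.finite(.x))))) {
    stop("non-finite feature values", call. = FALSE)
  }
  y <- label_vector(data)
  if (nlevels(droplevels(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(x)
  minority <- names(which.min(table(y)))
  majority <- setdiff(levels(y), minority)
  idx_min <- which(y == minority)
  idx_maj <- which(y == majority)
  n_take <- min(length(idx_maj),
                max(1L, round(undersample_ratio * length(idx_min))))

  set.seed(derive_seed(seed, 23L))
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  history <- list()
  df <- cbind(x, .y = y)

  for (m in seq_len(n_rounds)) {
    accepted <- FALSE
    for (try in seq_len(max_retries)) {
      idx <- c(idx_min, sample(idx_maj, n_take))
      fit <- rpart::rpart(
        .y ~ ., data = df[idx, , drop = FALSE],
        weights = w[idx] / sum(w[idx]),
        method = "class",
        control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                       minsplit = 4, minbucket = 2,
                                       xval = 0, maxsurrogate = 0,
                                       maxcompete = 0)
      )
      pred <- predict(fit, df, type = "class")
      err <- sum(w[pred != y])
      if (err < 0.5) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    err_c <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * log((1 - err_c) / err_c)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    history[[length(history) + 1]] <- tibble::tibble(
      round = m, weighted_error = err, alpha = alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 0) break
  }
  if (length(trees) == 0) {
    stop("boosting failed: no round achieved weighted error < 0.5",
         call. = FALSE)
  }
  structure(
    list(trees = trees, alphas = alphas, features = feats,
         positive_class = POSITIVE_CLASS,
         history = dplyr::bind_rows(history),
         config = list(n_rounds = n_rounds, max_depth = max_depth,
                       learning_rate = learning_rate,
                       undersample_ratio = undersample_ratio, seed = seed)),
    class = "rusboost"
  )
}

#' @export
print.rusboost <- function(x, ...) {
  cat("<rusboost> ", length(x$trees), " trees (depth <= ",
      x$config$max_depth, "), learning rate ", x$config$learning_rate,
      "\n", sep = "")
  invisible(x)
}

#' Predict from a RUSBoost ensemble
#'
#' @param object A [train_rusboost()] model.
#' @param newdata Feature table.
#' @param type `"prob"` for positive-class scores in `[0, 1]` or `"class"`
#'   for labels at the 0.5 threshold. Scores are the logistic transform of
#'   the additive ensemble margin `F(x) = sum_m alpha_m (2 p_m(x) - 1)`
#'   (the standard probability calibration for adaptive boosting), so
#'   `score >= 0.5` coincides with a positive weighted vote.
#' @param ... Unused.
#' @return Numeric scores or a character label vector.
#' @export
predict.rusboost <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)[object$features]
  p <- matrix(0, nrow(newdata), length(object$trees))
  for (m in seq_along(object$trees)) {
    pr <- predict(object$trees[[m]], newdata, type = "prob")
    p[, m] <- pr[, "pos"]
  }
  margin <- as.numeric((2 * p - 1) %*% object$alphas)
  score <- stats::plogis(margin)
  if (type == "prob") return(score)
  ifelse(score >= 0.5, object$positive_class, "non-nociceptor")
}

#' Feature importances of a RUSBoost ensemble
#'
#' Mean impurity-decrease importance of each feature, aggregated over the
#' ensemble's trees weighted by their learner weights, and normalised to
#' sum to 1.
#'
#' @param model A [train_rusboost()] model.
#' @return A tibble with `feature` and `importance` (sums to 1), sorted
#'   decreasing.
#' @export
rusboost_importance <- function(model) {
  stopifnot(inherits(model, "rusboost"))
  imp <- setNames(numeric(length(model$features)), model$features)
  for (m in seq_along(model$trees)) {
    vi <- model$trees[[m]]$variable.importance
    if (is.null(vi)) next
    vi <- vi / sum(vi)
    imp[names(vi)] <- imp[names(vi)] + model$alphas[m] * vi
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy-nocilabel
#' @export
tidy.rusboost <- function(x, ...) {
  x$history
}

#' @rdname tidy-nocilabel
#' @export
glance.rusboost <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees),
    max_depth = x$config$max_depth,
    learning_rate = x$config$learning_rate,
    undersample_ratio = x$config$undersample_ratio,
    mean_weighted_error = mean(x$history$weighted_error)
  )
}
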