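#' Train the reference classifier panel
#'
#' Fits the four comparison models alongside the boosted-tree ensemble:
#' logistic regression (`log`), linear discriminant analysis (`lda`), a
#' k-nearest-neighbour random-feature-subspace ensemble (`knn`), and a small
#' feed-forward neural-network ensemble (`fnn`). All four upweight the
#' minority class in proportion to inverse prevalence (the boosted tree
#' handles imbalance by undersampling instead). Fits delegate to the
#' standard engines (`glm`, `MASS::lda`, `class::knn`, `nnet::nnet`) behind
#' a uniform scoring interface.
#'
#' @param data Labeled feature table.
#' @param models Character subset of `c("log", "lda", "knn", "fnn")`.
#' @param hyperparameters Optional named list of per-family parameter lists
#'   (as returned by [tune_hyperparameters()]); missing families use
#'   defaults.
#' @param seed Integer seed (subspace draws, net initialisations).
#' @return A named list of `noci_model` objects; score with
#'   [score_units()].
#' @export
train_reference_models <- function(data,
                                   models = c("log", "lda", "knn", "fnn"),
                                   hyperparameters = list(), seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  out <- list()
  for (m in models) {
    hp <- hyperparameters[[m]] %||% list()
    out[[m]] <- train_single_model(m, data, hp, seed)
  }
  out
}

default_hyperparameters <- function(family) {
  switch(family,
    tree = list(n_rounds = 200, max_depth = 3, learning_rate = 0.5,
                undersample_ratio = 1),
    log = list(),
    lda = list(),
    knn = list(k = 7, n_subspaces = 15, subspace_dim = 2),
    fnn = list(size = 8, decay = 0.1, n_nets = 5, maxit = 200),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

train_single_model <- function(family, data, hp = list(), seed = 1L) {
  if (family == "tree") {
    hp <- utils::modifyList(default_hyperparameters("tree"), hp)
    return(train_rusboost(data, n_rounds = hp$n_rounds,
                          max_depth = hp$max_depth,
                          learning_rate = hp$learning_rate,
                          undersample_ratio = hp$undersample_ratio,
                          seed = seed))
  }
  hp <- utils::modifyList(default_hyperparameters(family), hp)
  data <- tibble::as_tibble(data)
  feats <- feature_columns(data)
  x <- as.data.frame(data[feats])
  y <- label_vector(data)
  if (nlevels(droplevels(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  tab <- table(y)
  # inverse-prevalence class weights: weight ratio = majority/minority count
  cw <- as.numeric(sum(tab) / (2 * tab))
  names(cw) <- names(tab)
  wts <- cw[as.character(y)]
  set.seed(derive_seed(seed, 31L))

  fit <- switch(family,
    log = {
      df <- cbind(x, .y = as.integer(y == "pos"))
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           weights = wts))
    },
    lda = MASS::lda(x, grouping = y, prior = c(0.5, 0.5)),
    knn = {
      p <- length(feats)
      dim_s <- min(hp$subspace_dim, p)
      subspaces <- purrr::map(seq_len(hp$n_subspaces),
                              ~ sort(sample(p, dim_s)))
      mu <- vapply(x, mean, numeric(1))
      sigma <- vapply(x, sd, numeric(1))
      sigma[sigma == 0] <- 1
      list(train_x = scale(as.matrix(x), mu, sigma), train_y = y,
           k = hp$k, subspaces = subspaces, mu = mu, sigma = sigma,
           class_weights = cw)
    },
    fnn = {
      mu <- vapply(x, mean, numeric(1))
      sigma <- vapply(x, sd, numeric(1))
      sigma[sigma == 0] <- 1
      xs <- scale(as.matrix(x), mu, sigma)
      nets <- purrr::map(seq_len(hp$n_nets), function(i) {
        nnet::nnet(xs, class.ind2(y), size = hp$size, decay = hp$decay,
                   maxit = hp$maxit, weights = wts, softmax = TRUE,
                   trace = FALSE)
      })
      list(nets = nets, mu = mu, sigma = sigma)
    }
  )
  structure(list(family = family, fit = fit, features = feats,
                 hyperparameters = hp, class_weights = cw),
            class = "noci_model")
}

class.ind2 <- function(y) {
  m <- matrix(0, length(y), 2, dimnames = list(NULL, c("neg", "pos")))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' @export
print.noci_model <- function(x, ...) {
  cat("<noci_model> family:", x$family, "\n")
  invisible(x)
}

#' Positive-class scores from any fitted subtype classifier
#'
#' Uniform scoring interface over the boosted-tree ensemble and the
#' reference panel: every model emits a score in `[0, 1]`, interpreted as
#' the (class-weighted) probability that the unit is a nociceptor.
#'
#' @param model A `rusboost` or `noci_model` object.
#' @param newdata Feature table.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
score_units <- function(model, newdata) {
  UseMethod("score_units")
}

#' @export
score_units.rusboost <- function(model, newdata) {
  predict(model, newdata, type = "prob")
}

#' @export
score_units.noci_model <- function(model, newdata) {
  newdata <- tibble::as_tibble(newdata)
  x <- as.data.frame(newdata[model$features])
  fit <- model$fit
  switch(model$family,
    log = as.numeric(predict(fit, x, type = "response")),
    lda = as.numeric(predict(fit, x)$posterior[, "pos"]),
    knn = {
      xs <- scale(as.matrix(x), fit$mu, fit$sigma)
      votes <- matrix(0, nrow(xs), length(fit$subspaces))
      for (s in seq_along(fit$subspaces)) {
        cols <- fit$subspaces[[s]]
        pred <- class::knn(fit$train_x[, cols, drop = FALSE],
                           xs[, cols, drop = FALSE],
                           fit$train_y, k = fit$k, prob = TRUE)
        f_win <- attr(pred, "prob")
        f_pos <- ifelse(pred == "pos", f_win, 1 - f_win)
        votes[, s] <- f_pos
      }
      f_pos <- rowMeans(votes)
      # apply minority upweighting to the vote fractions
      w_pos <- fit$class_weights[["pos"]]
      w_neg <- fit$class_weights[["neg"]]
      w_pos * f_pos / (w_pos * f_pos + w_neg * (1 - f_pos))
    },
    fnn = {
      xs <- scale(as.matrix(x), fit$mu, fit$sigma)
      preds <- vapply(fit$nets, function(nn) predict(nn, xs)[, "pos"],
                      numeric(nrow(xs)))
      rowMeans(matrix(preds, nrow = nrow(xs)))
    }
  )
}

#' Hyperparameter search for one model family
#'
#' Sequential random search over the documented per-family space,
#' maximising inner cross-validated AUC; deterministic under a fixed seed.
#' The `method` field of the result is flagged `"random_search"`. Spaces:
#' tree depth 1-8, rounds 50-500, learning rate 0.01-1 (log scale),
#' undersample ratio 1; k 1-25; subspace dimension 2-3; hidden sizes 4-64
#' (log scale).
#'
#' @param family One of `"tree"`, `"log"`, `"lda"`, `"knn"`, `"fnn"`.
#' @param data Labeled feature table (the training partition).
#' @param budget Number of candidate evaluations (>= 1; default 30).
#' @param inner_k Inner CV folds for scoring candidates (default 5).
#' @param seed Integer seed.
#' @return A list with `best` (parameter list), `best_auc`, `method`,
#'   `nested` (FALSE: tuned once on the training partition, then
#'   cross-validated), and `history` (tibble of evaluated candidates).
#' @export
tune_hyperparameters <- function(family, data, budget = 30, inner_k = 5,
                                 seed = 1L) {
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  sampler <- hyperparameter_space(family)
  if (is.null(sampler)) {
    # families without tunable parameters (log, lda)
    return(list(best = list(), best_auc = NA_real_,
                method = "random_search", nested = FALSE,
                history = tibble::tibble()))
  }
  set.seed(derive_seed(seed, 41L))
  candidates <- purrr::map(seq_len(budget), ~ sampler())
  history <- list()
  for (i in seq_along(candidates)) {
    auc_i <- inner_cv_auc(family, data, candidates[[i]], inner_k,
                          seed = derive_seed(seed, 43L + i))
    history[[i]] <- tibble::as_tibble(c(candidates[[i]],
                                        list(mean_auc = auc_i)))
  }
  history <- dplyr::bind_rows(history)
  best_i <- which.max(history$mean_auc)
  list(best = candidates[[best_i]], best_auc = history$mean_auc[best_i],
       method = "random_search", nested = FALSE, history = history)
}

hyperparameter_space <- function(family) {
  switch(family,
    tree = function() list(
      max_depth = sample(1:8, 1),
      n_rounds = sample(seq(50, 500, by = 50), 1),
      learning_rate = 10^runif(1, -2, 0),
      undersample_ratio = 1),
    knn = function() list(
      k = sample(1:25, 1),
      subspace_dim = sample(2:3, 1),
      n_subspaces = sample(c(10, 15, 20), 1)),
    fnn = function() list(
      size = round(2^runif(1, 2, 6)),
      decay = 10^runif(1, -3, 0),
      n_nets = 5, maxit = 200),
    NULL
  )
}

inner_cv_auc <- function(family, data, hp, k, seed) {
  data <- tibble::as_tibble(data)
  y <- label_vector(data)
  folds <- stratified_folds(y, k, seed)
  aucs <- purrr::map_dbl(seq_len(k), function(f) {
    tr <- data[folds != f, ]
    te <- data[folds == f, ]
    fit <- train_single_model(family, tr, hp, seed = seed)
    s <- score_units(fit, te)
    roc_auc(s, te$label == POSITIVE_CLASS)$auc
  })
  mean(aucs)
}
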