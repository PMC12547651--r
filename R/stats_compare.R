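#' Mann-Whitney U comparison of two samples
#'
#' U is computed from midrank sums; the p-value uses the exact null
#' distribution when both samples are small (`min(n1, n2) <= 8`) and tie
#' free, and the normal approximation with tie and continuity correction
#' otherwise. Significance stars follow the usual convention
#' (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact path;
#'   `NULL` (default) selects it automatically as above.
#' @return A one-row tibble: `n_a`, `n_b`, `u` (U of sample `a`),
#'   `p_value`, `stars`, `rank_biserial` (effect size, positive when `a`
#'   tends larger).
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less",
                                                 "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- exact %||% (min(n1, n2) <= 8 && !has_ties)
  if (length(unique(c(a, b))) == 1) {
    # completely tied data: no evidence against the null
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = alternative, exact = use_exact,
                  correct = TRUE)$p.value
    )
  }
  tibble::tibble(
    n_a = n1, n_b = n2, u = u, p_value = p,
    stars = p_stars(p),
    rank_biserial = 2 * u / (n1 * n2) - 1
  )
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare every baseline feature between the two labeled subtypes
#'
#' Runs one Mann-Whitney U comparison per feature column between
#' nociceptor-labeled and non-nociceptor-labeled units, reporting which
#' group has the larger median. No multiple-testing correction is applied
#' by default (each feature is presented as its own contrast); Holm
#' adjustment is available via `adjust`.
#'
#' @param features A labeled feature table (from [build_feature_table()]
#'   with labels, or [read_features()]).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble with one row per feature: `feature`, `n_nociceptor`,
#'   `n_non_nociceptor`, `u`, `p_value`, `stars`, `higher_in`.
#' @export
compare_feature_by_label <- function(features, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  features <- tibble::as_tibble(features)
  if (!"label" %in% names(features)) {
    stop("feature table has no label column", call. = FALSE)
  }
  feats <- feature_columns(features)
  if (length(feats) == 0) stop("no feature columns found", call. = FALSE)
  pos <- features[features$label == POSITIVE_CLASS, ]
  neg <- features[features$label != POSITIVE_CLASS, ]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    stop("both labels must be present", call. = FALSE)
  }
  out <- purrr::map_dfr(feats, function(fc) {
    res <- mann_whitney_u(pos[[fc]], neg[[fc]])
    tibble::tibble(
      feature = fc,
      n_nociceptor = res$n_a, n_non_nociceptor = res$n_b,
      u = res$u, p_value = res$p_value,
      higher_in = dplyr::case_when(
        median(pos[[fc]]) > median(neg[[fc]]) ~ "nociceptor",
        median(pos[[fc]]) < median(neg[[fc]]) ~ "non-nociceptor",
        TRUE ~ "tie"))
  })
  if (adjust == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  }
  out$stars <- p_stars(out$p_value)
  out
}
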