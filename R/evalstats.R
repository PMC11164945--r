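#' Bundle predicted probabilities with labels and patient grouping
#'
#' The common currency of all evaluation statistics: per-image predicted
#' probabilities, true binary labels (1 = S1plus) and the patient id of
#' each image, which is the resampling unit for the jackknife (images of a
#' patient are correlated and must leave the sample together).
#'
#' @param scores predicted probabilities in \[0, 1\].
#' @param labels binary labels in \{0, 1\}.
#' @param group_ids patient id per image; defaults to one group per image.
#' @export
score_set <- function(scores, labels, group_ids = NULL) {
  if (is.null(group_ids)) group_ids <- as.character(seq_along(scores))
  stopifnot(length(scores) == length(labels),
            length(scores) == length(group_ids))
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(scores < 0 | scores > 1)) stop("scores must be in [0, 1]")
  structure(list(scores = as.numeric(scores), labels = as.numeric(labels),
                 group_ids = as.character(group_ids)),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("score_set:", length(x$scores), "scores,",
      sum(x$labels == 1), "positive /", sum(x$labels == 0), "negative,",
      length(unique(x$group_ids)), "patients\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a random positive scores
#' above a random negative, counting ties as 1/2. Computed from midranks,
#' equivalent to exhaustive pair counting.
#'
#' @param scoreset a [score_set()].
#' @export
roc_auc <- function(scoreset) {
  y <- scoreset$labels
  s <- scoreset$scores
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes present")
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Thresholded confusion-matrix metrics
#'
#' Binarizes at `threshold` (score >= threshold predicts S1plus) and
#' reports accuracy, sensitivity, specificity, PPV and NPV. Ratios with a
#' zero denominator are reported as `NA` with a warning, never as 0.
#'
#' @param scoreset a [score_set()].
#' @param threshold decision threshold (default 0.5).
#' @return list of class `"metric_report"`.
#' @export
confusion_metrics <- function(scoreset, threshold = 0.5) {
  y <- scoreset$labels
  pred <- as.numeric(scoreset$scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  out <- list(accuracy = (tp + tn) / length(y),
              sensitivity = safe_div(tp, tp + fn, "sensitivity"),
              specificity = safe_div(tn, tn + fp, "specificity"),
              ppv = safe_div(tp, tp + fp, "PPV"),
              npv = safe_div(tn, tn + fn, "NPV"),
              n_pos = tp + fn, n_neg = tn + fp, threshold = threshold)
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.3f | sensitivity %s | specificity %s | ",
                     "PPV %s | NPV %s (threshold %.2f, %d pos / %d neg)\n"),
              x$accuracy, fmt_na(x$sensitivity), fmt_na(x$specificity),
              fmt_na(x$ppv), fmt_na(x$npv), x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(metric,
         auc = roc_auc,
         accuracy = function(ss) mean((ss$scores >= 0.5) == (ss$labels == 1)),
         sensitivity = function(ss) confusion_metrics(ss)$sensitivity,
         specificity = function(ss) confusion_metrics(ss)$specificity,
         ppv = function(ss) confusion_metrics(ss)$ppv,
         npv = function(ss) confusion_metrics(ss)$npv,
         stop("unknown metric '", metric, "'"))
}

#' Leave-one-patient-out jackknife confidence interval
#'
#' Recomputes the metric on every leave-one-group-out subset (groups are
#' patients), forms the jackknife standard error
#' `sqrt((g - 1) / g * sum((theta_i - mean(theta))^2))` and returns the
#' full-sample point estimate with a normal-quantile interval clipped to
#' \[0, 1\]. Replicates on which the metric is not computable (a subset
#' losing a whole class) are skipped with a warning.
#'
#' @param scoreset a [score_set()].
#' @param metric `"auc"`, `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"ppv"`, `"npv"`, or a function of a score_set.
#' @param level confidence level (default 0.95).
#' @return list: `estimate`, `ci_low`, `ci_high`, `se`, `n_groups`.
#' @export
jackknife_ci <- function(scoreset, metric = "auc", level = 0.95) {
  f <- metric_fun(metric)
  groups <- unique(scoreset$group_ids)
  if (length(groups) < 2) stop("jackknife requires at least 2 groups")
  est <- f(scoreset)
  reps <- numeric(0)
  skipped <- 0L
  for (g in groups) {
    keep <- scoreset$group_ids != g
    sub <- score_set(scoreset$scores[keep], scoreset$labels[keep],
                     scoreset$group_ids[keep])
    val <- tryCatch(suppressWarnings(f(sub)), error = function(e) NA_real_)
    if (is.na(val)) skipped <- skipped + 1L else reps <- c(reps, val)
  }
  if (skipped > 0)
    warning(skipped, " jackknife replicate(s) skipped ",
            "(metric not computable on the subset)")
  gn <- length(reps)
  if (gn < 2) stop("fewer than 2 usable jackknife replicates")
  se <- sqrt((gn - 1) / gn * sum((reps - mean(reps))^2))
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = est,
       ci_low = max(0, est - z * se),
       ci_high = min(1, est + z * se),
       se = se, n_groups = gn)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two classifiers scored on the same cases. Uses the
#' placement-value (structural-component) decomposition: per-case
#' components of each AUC, their 2 x 2 empirical covariances over positives
#' and negatives, the variance of the AUC difference, and a two-sided
#' normal p-value for `z = diff / sqrt(var)`.
#'
#' @param scoreset_a,scoreset_b [score_set()]s with identical labels in
#'   identical order.
#' @return list of class `"delong_result"`: `auc_a`, `auc_b`, `difference`,
#'   `variance`, `z`, `p_value`.
#' @export
delong_test <- function(scoreset_a, scoreset_b) {
  if (!identical(scoreset_a$labels, scoreset_b$labels))
    stop("paired DeLong test requires identical labels in identical order")
  y <- scoreset_a$labels
  pos <- which(y == 1)
  neg <- which(y == 0)
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  comp <- function(s) {
    x <- s[pos]
    yv <- s[neg]
    # placement values via midranks (O(N log N))
    r_all <- rank(c(x, yv), ties.method = "average")
    rx <- rank(x, ties.method = "average")
    ry <- rank(yv, ties.method = "average")
    v10 <- (r_all[seq_len(m)] - rx) / n          # per-positive components
    v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m  # per-negative components
    list(auc = sum(v10) / m, v10 = v10, v01 = v01)
  }
  a <- comp(scoreset_a$scores)
  b <- comp(scoreset_b$scores)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  if (var_diff <= 0) {
    if (abs(diff) > 1e-12)
      stop("non-positive variance of the AUC difference with nonzero ",
           "difference")
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, difference = diff,
                 variance = var_diff, z = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(paste0("DeLong test: AUC_a %.4f vs AUC_b %.4f, ",
                     "difference %+.4f, z = %.3f, p = %.4g\n"),
              x$auc_a, x$auc_b, x$difference, x$z, x$p_value))
  invisible(x)
}
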