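#' ROC area under the curve (Mann-Whitney form)
#'
#' The AUC is the fraction of (positive, negative) score pairs ranked
#' correctly, with ties counted one half — the Mann-Whitney U statistic
#' scaled to \[0, 1\].
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary 0/1 (or logical) class labels; both classes present.
#' @return The AUC.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    stop("roc_auc: both classes must be present", call. = FALSE)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Youden-optimal threshold
#'
#' Scans the midpoints between adjacent distinct scores (plus outer
#' sentinels) and returns the threshold maximizing sensitivity +
#' specificity, calling a sample positive when `score >= threshold`. Ties
#' return the lowest maximizing threshold.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(unique(labels)) < 2L)
    stop("youden_threshold: both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  best <- -Inf; bt <- cand[1]; bsens <- NA; bspec <- NA
  for (th in cand) {
    sens <- sum(scores >= th & labels == 1) / npos
    spec <- sum(scores < th & labels == 0) / nneg
    if (sens + spec > best + 1e-12) {
      best <- sens + spec; bt <- th; bsens <- sens; bspec <- spec
    }
  }
  list(threshold = bt, sensitivity = bsens, specificity = bspec)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile 95% interval over stratified bootstrap resamples (positives
#' and negatives resampled separately, so every resample keeps both
#' classes). Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of resamples (default 2000).
#' @param seed Integer seed.
#' @return List with `ci_low`, `ci_high`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    stop("auc_ci: both classes must be present", call. = FALSE)
  rng <- local_rng(seed)
  aucs <- numeric(n_boot)
  np <- length(pos); nn <- length(neg)
  for (b in seq_len(n_boot)) {
    ip <- floor(rng$runif(np) * np) + 1
    in_ <- floor(rng$runif(nn) * nn) + 1
    aucs[b] <- roc_auc(c(pos[ip], neg[in_]), rep(c(1L, 0L), c(np, nn)))
  }
  q <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = q[1], ci_high = q[2])
}

#' Evaluate a laterality model on a feature table
#'
#' Scores every row of the design's ROI (affected side = positive,
#' all other rows = negative, mirroring the training contrast) and reports
#' AUC with a bootstrap CI, the Youden threshold with its sensitivity and
#' specificity, and per-patient laterality calls.
#'
#' @param model A [laterality_model()].
#' @param table Feature table of the evaluation cohort.
#' @param n_boot,seed Bootstrap settings for the CI.
#' @return List of class `laterality_eval`: `auc`, `ci_low`, `ci_high`,
#'   `threshold`, `sensitivity`, `specificity`, `scores` (per-row
#'   data.frame) and `calls` (per-patient data.frame with `correct`).
#' @export
evaluate_model <- function(model, table, n_boot = 2000L, seed = 1L) {
  tb <- table[table$roi == model$design, , drop = FALSE]
  if (!nrow(tb)) stop("evaluate_model: no rows for roi '", model$design, "'",
                      call. = FALSE)
  sc <- predict(model, tb)
  y <- as.integer(tb$affected)
  a <- roc_auc(sc, y)
  ci <- auc_ci(sc, y, n_boot = n_boot, seed = seed)
  yo <- youden_threshold(sc, y)
  scores <- data.frame(tb[, meta_columns(), drop = FALSE], score = sc,
                       row.names = NULL)
  pat <- unique(tb$subject_id[tb$group == "patient"])
  calls <- lapply(pat, function(id) {
    sub <- scores[scores$subject_id == id, ]
    l <- sub$score[sub$side == "left"]; r <- sub$score[sub$side == "right"]
    if (!length(l) || !length(r)) return(NULL)
    side <- if (l > r) "left" else if (r > l) "right" else "indeterminate"
    truth <- sub$side[sub$affected == 1][1]
    data.frame(subject_id = id, call = side, truth = truth,
               correct = identical(side, truth), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  structure(list(auc = a, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 threshold = yo$threshold, sensitivity = yo$sensitivity,
                 specificity = yo$specificity, scores = scores,
                 calls = calls),
            class = "laterality_eval")
}

#' @exportS3Method print laterality_eval
print.laterality_eval <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci_low, x$ci_high))
  cat(sprintf("Youden threshold %.3f: sensitivity %.3f, specificity %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  if (!is.null(x$calls) && nrow(x$calls))
    cat(sprintf("Laterality calls: %d/%d correct\n",
                sum(x$calls$correct), nrow(x$calls)))
  invisible(x)
}

#' Per-patient laterality call from hemisphere scores
#'
#' Scores each hemisphere's feature vector with the model and returns the
#' side with the larger score; exact ties are `"indeterminate"`.
#'
#' @param model A [laterality_model()].
#' @param left_features,right_features Named feature vectors (or single-row
#'   tables) for the left and right ROI.
#' @return `"left"`, `"right"` or `"indeterminate"`.
#' @export
laterality_call <- function(model, left_features, right_features) {
  l <- predict(model, left_features)
  r <- predict(model, right_features)
  if (l > r) "left" else if (r > l) "right" else "indeterminate"
}
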