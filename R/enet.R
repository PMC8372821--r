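#' Elastic-net configuration
#'
#' Hyperparameter search space for the penalized logistic laterality score:
#' the mixing parameter alpha runs over a grid in \[0, 1\] (0 = ridge,
#' 1 = LASSO) and, for each alpha, lambda runs down a log-spaced path of
#' `n_lambda` values spanning `lambda_decades` decades below the smallest
#' lambda that zeroes every coefficient. Tuning is 10-fold stratified
#' cross-validation on mean squared error between the predicted probability
#' and the 0/1 label.
#'
#' @param alpha_grid Numeric vector in \[0, 1\] (default `seq(0, 1, 0.05)`).
#' @param n_lambda Path length per alpha (default 100).
#' @param lambda_decades Decades spanned by the path (default 4).
#' @param k_folds Number of CV folds (default 10).
#' @param fold_seed Integer seed for the stratified fold assignment.
#' @param selection_rule `"1se"` (default) selects, among all grid points
#'   whose mean CV MSE lies within one standard error of the minimum, the
#'   most parsimonious one (largest lambda, then largest alpha); `"min"`
#'   takes the raw minimizer. The 1-SE band keeps noise-only fits from
#'   winning on CV jitter at small sample sizes.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha_grid = seq(0, 1, by = 0.05), n_lambda = 100L,
                        lambda_decades = 4, k_folds = 10L, fold_seed = 1L,
                        selection_rule = c("1se", "min")) {
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop("enet_config: alpha_grid must lie in [0, 1]", call. = FALSE)
  if (k_folds < 2L) stop("enet_config: k_folds must be >= 2", call. = FALSE)
  structure(list(alpha_grid = sort(alpha_grid), n_lambda = as.integer(n_lambda),
                 lambda_decades = lambda_decades, k_folds = as.integer(k_folds),
                 fold_seed = as.integer(fold_seed),
                 selection_rule = match.arg(selection_rule)),
            class = "enet_config")
}

# lambda path: glmnet's entry criterion lambda_max = max|X'(y - ybar)| / (n a)
# with a = max(alpha, 1e-3) so the ridge end still gets a finite path.
lambda_path <- function(Z, y, alpha, n_lambda, decades) {
  n <- nrow(Z)
  ybar <- mean(y)
  g <- abs(crossprod(Z, y - ybar)) / n
  lmax <- max(g) / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Fit a penalized logistic model at fixed hyperparameters
#'
#' Minimizes the penalized negative log-likelihood
#' `-(1/n) sum[y log p + (1-y) log(1-p)] + lambda ((1-alpha)||b||^2/2 +
#' alpha ||b||_1)` with unpenalized intercept, via coordinate descent
#' (glmnet). Columns are assumed pre-standardized.
#'
#' @param Z Standardized numeric matrix.
#' @param y Binary 0/1 response with both classes present.
#' @param alpha Elastic-net mixing in \[0, 1\].
#' @param lambda Penalty strength (>= 0).
#' @return List with `intercept`, `beta` (named vector), `alpha`, `lambda`.
#' @export
fit_enet <- function(Z, y, alpha, lambda) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("fit_enet: response has a single class", call. = FALSE)
  path <- sort(unique(c(lambda_path(Z, y, alpha, 50L, 4), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                       x = Z, y = y))
  list(intercept = cf[1],
       beta = stats::setNames(cf[-1], colnames(Z)),
       alpha = alpha, lambda = lambda)
}

# stratified fold ids, deterministic under seed
stratified_folds <- function(y, k, seed) {
  rng <- local_rng(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    perm <- order(rng$runif(length(idx)))
    fold[idx[perm]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated hyperparameter tuning
#'
#' For every alpha on the grid and every lambda on that alpha's path,
#' computes the mean held-out squared error between predicted probability
#' and label over stratified k-folds, then selects per
#' `cfg$selection_rule`: the sparsest pair within one standard error of the
#' minimum (default), or the raw minimizer. Exact ties always prefer the
#' larger lambda (sparser model), then the larger alpha.
#'
#' @param Z Standardized matrix.
#' @param y Binary response.
#' @param cfg An [enet_config()].
#' @return List with `alpha`, `lambda`, `cv_mse` (the winning mean MSE), and
#'   `curve` (data.frame alpha/lambda/mse over the whole grid).
#' @export
cv_tune <- function(Z, y, cfg = enet_config()) {
  y <- as.integer(y)
  n <- nrow(Z)
  if (n < cfg$k_folds) stop("cv_tune: fewer rows than folds", call. = FALSE)
  fold <- stratified_folds(y, cfg$k_folds, cfg$fold_seed)
  curves <- list()
  for (alpha in cfg$alpha_grid) {
    path <- lambda_path(Z, y, alpha, cfg$n_lambda, cfg$lambda_decades)
    mse <- matrix(NA_real_, cfg$k_folds, length(path))
    for (k in seq_len(cfg$k_folds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L)
        stop("cv_tune: training split lost a class", call. = FALSE)
      fit <- glmnet::glmnet(Z[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = alpha,
                            lambda = path, standardize = FALSE, maxit = 1e5)
      p <- stats::predict(fit, Z[!tr, , drop = FALSE], s = path,
                          type = "response")
      mse[k, ] <- colMeans((p - y[!tr])^2)
    }
    curves[[length(curves) + 1L]] <-
      data.frame(alpha = alpha, lambda = path, rank = seq_along(path),
                 mse = colMeans(mse),
                 se = apply(mse, 2, stats::sd) / sqrt(cfg$k_folds))
  }
  curve <- do.call(rbind, curves)
  best_i <- which.min(curve$mse)
  band <- if (identical(cfg$selection_rule, "1se"))
    curve$mse[best_i] + curve$se[best_i] else curve$mse[best_i] + 1e-12
  cand <- curve[curve$mse <= band, ]
  # parsimony: most penalized point of its own path first (lambda scales
  # differ across alpha, so raw lambda is not comparable), then the more
  # lasso-like alpha, then raw lambda for determinism
  cand <- cand[order(cand$rank, -cand$alpha, -cand$lambda), ]
  list(alpha = cand$alpha[1], lambda = cand$lambda[1],
       cv_mse = cand$mse[1], cv_mse_min = curve$mse[best_i], curve = curve)
}

#' Fit the radiomic laterality model
#'
#' The package's central estimator. From a per-ROI feature table it
#' (1) builds the requested contrast design — affected-side rows of
#' patients against unaffected-side rows plus one hemisphere per control;
#' (2) filters features by pooled t-tests with Benjamini-Hochberg FDR
#' control at `q_threshold`; (3) standardizes the surviving features; and
#' (4) fits an elastic-net penalized logistic regression whose alpha and
#' lambda are tuned by stratified 10-fold cross-validation on
#' probability-scale MSE. The fitted linear score is the laterality score.
#' If fewer than two features survive the filter (as expected under a null
#' cohort), the filter is bypassed and the penalty alone performs selection.
#'
#' @param table Feature table from [extract_cohort()] (or
#'   [read_feature_table()]).
#' @param design `"hippocampal"` (H+) or `"temporal"` (H-, extrahippocampal).
#' @param q_threshold BH FDR level for the univariate filter (default 0.05).
#' @param enet An [enet_config()].
#' @param seed Integer seed controlling the control-hemisphere draw and CV
#'   folds.
#' @return An object of class `laterality_model`; see
#'   [predict.laterality_model()].
#' @examples
#' \donttest{
#' ph <- make_cohort(phantom_spec(n_patients = 4, n_controls = 4,
#'                                grid = c(32, 32, 24), seed = 7))
#' tab <- extract_cohort(ph, rois = "hippocampal")
#' fit <- laterality_model(tab, design = "hippocampal", seed = 7)
#' print(fit)
#' }
#' @export
laterality_model <- function(table, design = c("hippocampal", "temporal"),
                             q_threshold = 0.05, enet = enet_config(),
                             seed = 1L) {
  design <- match.arg(design)
  enet$fold_seed <- as.integer(seed)
  dz <- build_design(table, design, seed = seed)
  sel <- select_features(dz$X, dz$y, q_threshold)
  keep <- sel$feature[sel$pass]
  filtered <- TRUE
  if (length(keep) < 2L) {
    keep <- sel$feature
    filtered <- FALSE
  }
  std <- standardize_features(dz$X[, keep, drop = FALSE])
  tune <- cv_tune(std$Z, dz$y, enet)
  fit <- fit_enet(std$Z, dz$y, tune$alpha, tune$lambda)
  structure(list(design = design, selection = sel,
                 filter_active = filtered, q_threshold = q_threshold,
                 features = colnames(std$Z),
                 center = std$center, scale = std$scale,
                 dropped = std$dropped,
                 alpha = fit$alpha, lambda = fit$lambda,
                 intercept = fit$intercept, beta = fit$beta,
                 cv = tune$curve, cv_mse = tune$cv_mse,
                 n = nrow(std$Z), seed = as.integer(seed),
                 call = match.call()),
            class = "laterality_model")
}

#' @exportS3Method print laterality_model
print.laterality_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("Radiomic laterality model (%s design)\n", x$design))
  cat(sprintf("  n = %d samples, %d candidate features (%d passed the %s filter)\n",
              x$n, length(x$features),
              sum(x$selection$pass),
              if (x$filter_active) sprintf("BH q<%.2g", x$q_threshold)
              else "bypassed"))
  cat(sprintf("  elastic net: alpha = %.3g, lambda = %.4g, %d nonzero coefficients\n",
              x$alpha, x$lambda, nz))
  cat(sprintf("  cross-validated MSE = %.4f\n", x$cv_mse))
  invisible(x)
}

#' @exportS3Method summary laterality_model
summary.laterality_model <- function(object, ...) {
  nz <- object$beta[object$beta != 0]
  res <- list(design = object$design, alpha = object$alpha,
              lambda = object$lambda, cv_mse = object$cv_mse,
              n_filtered = sum(object$selection$pass),
              selected = sort(abs(nz), decreasing = TRUE),
              intercept = object$intercept)
  class(res) <- "summary.laterality_model"
  res
}

#' @exportS3Method print summary.laterality_model
print.summary.laterality_model <- function(x, ...) {
  cat(sprintf("Laterality model (%s): alpha %.3g, lambda %.4g, cv-MSE %.4f\n",
              x$design, x$alpha, x$lambda, x$cv_mse))
  cat(sprintf("%d features passed filtering; %d carry nonzero weight:\n",
              x$n_filtered, length(x$selected)))
  print(utils::head(x$selected, 20))
  invisible(x)
}

#' @export
coef.laterality_model <- function(object, all = FALSE, ...) {
  cf <- c("(Intercept)" = object$intercept, object$beta)
  if (all) cf else cf[c(TRUE, object$beta != 0)]
}

#' Predict laterality scores
#'
#' Applies the stored standardization and the logistic score
#' `plogis(b0 + b'z)` to new ROI feature rows.
#'
#' @param object A [laterality_model()].
#' @param newdata A feature table (rows of any ROI/side), a numeric matrix
#'   with named columns, or a single named feature vector.
#' @param type `"response"` (probability) or `"link"` (linear score).
#' @param ... Unused.
#' @return Numeric vector of scores, one per row.
#' @export
predict.laterality_model <- function(object, newdata,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) {
    miss <- setdiff(object$features, names(newdata))
    if (length(miss))
      stop("predict: missing feature(s): ", paste(utils::head(miss, 3),
           collapse = ", "), call. = FALSE)
    as.matrix(newdata[, object$features, drop = FALSE])
  } else if (is.matrix(newdata)) {
    miss <- setdiff(object$features, colnames(newdata))
    if (length(miss))
      stop("predict: missing feature(s): ", paste(utils::head(miss, 3),
           collapse = ", "), call. = FALSE)
    newdata[, object$features, drop = FALSE]
  } else {
    if (is.null(names(newdata)))
      stop("predict: newdata must be named", call. = FALSE)
    miss <- setdiff(object$features, names(newdata))
    if (length(miss))
      stop("predict: missing feature(s): ", paste(utils::head(miss, 3),
           collapse = ", "), call. = FALSE)
    matrix(newdata[object$features], 1,
           dimnames = list(NULL, object$features))
  }
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  eta <- drop(object$intercept + Z %*% object$beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' Serialize / restore a laterality model as JSON
#'
#' The artifact stores feature names, standardization statistics,
#' coefficients, hyperparameters and the seed, so a model can be applied to
#' new data without R serialization formats.
#'
#' @param model A [laterality_model()].
#' @param path JSON output path.
#' @return `path` (write); a `laterality_model` (read).
#' @export
write_model_json <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_model_json requires the 'jsonlite' package", call. = FALSE)
  obj <- model[c("design", "features", "center", "scale", "dropped",
                 "alpha", "lambda", "intercept", "beta", "q_threshold",
                 "filter_active", "n", "seed")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("read_model_json requires the 'jsonlite' package", call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta <- stats::setNames(as.numeric(obj$beta), obj$features)
  obj$center <- stats::setNames(as.numeric(obj$center), obj$features)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$features)
  structure(obj, class = "laterality_model")
}
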