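#' Build a laterality contrast design from a feature table
#'
#' Mirrors the clinical contrast construction: positives are the
#' affected-side ROI rows of patients; negatives pool the patients'
#' unaffected-side rows with one hemisphere per control (chosen uniformly at
#' random under `seed`, since controls have no affected side). The
#' hippocampal design uses the hippocampal ROI rows, the temporal
#' (extrahippocampal) design the temporal ROI rows.
#'
#' @param table Feature table from [extract_cohort()].
#' @param design `"hippocampal"` (H+) or `"temporal"` (H-).
#' @param seed Integer seed for the control-hemisphere draw.
#' @return List with `X` (numeric feature matrix), `y` (1 = affected,
#'   0 = unaffected/control) and `meta` (the selected rows' metadata).
#' @export
build_design <- function(table, design = c("hippocampal", "temporal"),
                         seed = 1L) {
  design <- match.arg(design)
  tb <- table[table$roi == design, , drop = FALSE]
  if (!nrow(tb)) stop("build_design: no rows for roi '", design, "'",
                      call. = FALSE)
  pat <- tb[tb$group == "patient", , drop = FALSE]
  if (nrow(pat) && !any(pat$affected == 1))
    stop("build_design: patients lack affected-side annotation", call. = FALSE)
  ctl <- tb[tb$group == "control", , drop = FALSE]
  keep_ctl <- integer(0)
  if (nrow(ctl)) {
    rng <- local_rng(seed)
    for (id in unique(ctl$subject_id)) {
      ridx <- which(ctl$subject_id == id)
      keep_ctl <- c(keep_ctl, if (length(ridx) == 1L) ridx
                    else ridx[floor(rng$runif(1) * length(ridx)) + 1L])
    }
  }
  sel <- rbind(pat, ctl[keep_ctl, , drop = FALSE])
  fc <- feature_columns(table)
  X <- as.matrix(sel[, fc, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(sel$affected),
       meta = sel[, meta_columns(), drop = FALSE])
}

# Local RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env$runif <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
  env
}

#' Pooled two-sample Student t-test
#'
#' Classic equal-variance two-sided t-test with `n1 + n0 - 2` degrees of
#' freedom. When the pooled variance is exactly zero the p-value is defined
#' as 1 if the group means agree and 0 otherwise, so constant features never
#' yield NaN.
#'
#' @param x1,x0 Numeric vectors (each length >= 2).
#' @return List with `t`, `df`, `p`.
#' @examples
#' student_t(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < 2L || n0 < 2L)
    stop("student_t: both groups need at least 2 values", call. = FALSE)
  df <- n1 + n0 - 2L
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / df
  if (sp2 <= 0) {
    eq <- isTRUE(all.equal(mean(x1), mean(x0)))
    return(list(t = 0, df = df, p = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Univariate filtering with Benjamini-Hochberg FDR control
#'
#' Applies [student_t()] to every feature column of `X` (group 1 vs group 0)
#' and adjusts the p-values with the Benjamini-Hochberg step-up procedure;
#' a feature passes when its adjusted q-value falls below `q_threshold`.
#'
#' @param X Numeric matrix, rows = samples, columns = features.
#' @param y Binary labels (1 = positive group).
#' @param q_threshold FDR level (default 0.05).
#' @return A data.frame of class `rad_selection` with columns `feature`,
#'   `t`, `p`, `q`, `pass`.
#' @export
select_features <- function(X, y, q_threshold = 0.05) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  y <- as.integer(y)
  res <- apply(X, 2, function(col) {
    r <- student_t(col[y == 1], col[y == 0])
    c(r$t, r$p)
  })
  p <- res[2, ]
  q <- bh_adjust(p)
  out <- data.frame(feature = colnames(X), t = res[1, ], p = p, q = q,
                    pass = q < q_threshold, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("rad_selection", class(out))
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1.
#' Delegates to [stats::p.adjust()] (method `"BH"`), which implements
#' exactly this rule.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Column standardization with stored statistics
#'
#' Centers and scales feature columns using statistics computed on the fit
#' rows only, so validation data is transformed with the training
#' statistics. Zero-variance columns (on the fit rows) are dropped and
#' recorded.
#'
#' @param X Numeric matrix.
#' @param fit_rows Row indices used to compute means/SDs (default: all).
#' @return List with `Z` (standardized matrix over all rows), `center`,
#'   `scale` (named vectors for the kept columns) and `dropped` (names of
#'   zero-variance columns).
#' @export
standardize_features <- function(X, fit_rows = seq_len(nrow(X))) {
  stopifnot(is.matrix(X))
  mu <- colMeans(X[fit_rows, , drop = FALSE])
  sd_ <- apply(X[fit_rows, , drop = FALSE], 2, stats::sd)
  keep <- which(sd_ > 0)
  dropped <- colnames(X)[sd_ <= 0 | !is.finite(sd_)]
  if (length(dropped))
    keep <- which(sd_ > 0 & is.finite(sd_))
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], `/`)
  list(Z = Z, center = mu[keep], scale = sd_[keep], dropped = dropped)
}
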