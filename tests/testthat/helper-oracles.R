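# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive loops and first-principles formulas.

# symmetric co-occurrence probabilities by exhaustive pair enumeration
oracle_glcm <- function(levels, ng, offset) {
  d <- dim(levels)
  M <- matrix(0, ng, ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    a <- levels[x, y, z]
    if (a == 0) next
    x2 <- x + offset[1]; y2 <- y + offset[2]; z2 <- z + offset[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    b <- levels[x2, y2, z2]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  tot <- sum(M)
  P <- if (tot > 0) M / tot else M
  attr(P, "n_pairs") <- tot
  P
}

# run-length counts by walking every maximal run
oracle_glrlm <- function(levels, ng, dir) {
  d <- dim(levels)
  runs <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    g <- levels[x, y, z]
    if (g == 0) next
    px <- x - dir[1]; py <- y - dir[2]; pz <- z - dir[3]
    if (px >= 1 && px <= d[1] && py >= 1 && py <= d[2] && pz >= 1 &&
        pz <= d[3] && levels[px, py, pz] == g) next  # not a run start
    len <- 1
    cx <- x + dir[1]; cy <- y + dir[2]; cz <- z + dir[3]
    while (cx >= 1 && cx <= d[1] && cy >= 1 && cy <= d[2] && cz >= 1 &&
           cz <= d[3] && levels[cx, cy, cz] == g) {
      len <- len + 1
      cx <- cx + dir[1]; cy <- cy + dir[2]; cz <- cz + dir[3]
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  if (!length(runs)) return(matrix(0, ng, 1))
  rr <- do.call(rbind, runs)
  M <- matrix(0, ng, max(rr[, 2]))
  for (i in seq_len(nrow(rr))) M[rr[i, 1], rr[i, 2]] <- M[rr[i, 1], rr[i, 2]] + 1
  attr(M, "n_voxels") <- sum(levels > 0)
  M
}

# periodic correlation-filtering of a 1D signal: y[i] = sum_k h[k] x[(i+k-1) mod n]
oracle_filter1 <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    sum(h * x[((i - 1 + seq_along(h) - 1) %% n) + 1]), numeric(1))
}

# sequential axis-by-axis application of the 1D oracle
oracle_dwt3_band <- function(arr, lo, hi, band) {
  d <- dim(arr)
  letters3 <- strsplit(band, "")[[1]]  # (z, y, x)
  hx <- if (letters3[3] == "L") lo else hi
  hy <- if (letters3[2] == "L") lo else hi
  hz <- if (letters3[1] == "L") lo else hi
  out <- arr
  for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    out[, y, z] <- oracle_filter1(out[, y, z], hx)
  for (x in seq_len(d[1])) for (z in seq_len(d[3]))
    out[x, , z] <- oracle_filter1(out[x, , z], hy)
  for (x in seq_len(d[1])) for (y in seq_len(d[2]))
    out[x, y, ] <- oracle_filter1(out[x, y, ], hz)
  out
}

# unpenalized logistic regression by Newton-Raphson (IRLS)
oracle_logistic <- function(X, y, tol = 1e-10, maxit = 100) {
  X1 <- cbind(1, X)
  b <- rep(0, ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- crossprod(X1, y - p)
    H <- crossprod(X1 * W, X1)
    step <- solve(H, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# exhaustive Youden scan over every real cut (all midpoints and sentinels)
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  vals <- vapply(cand, function(th) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    sens + spec
  }, numeric(1))
  list(threshold = cand[which.max(vals)], value = max(vals))
}

# small helper: synthetic feature table with metadata, for design tests
toy_feature_table <- function(n_patients, n_controls, n_feat = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  add_row <- function(id, group, side, roi, affected) {
    f <- as.list(stats::setNames(rnorm(n_feat), paste0("f", seq_len(n_feat))))
    c(list(subject_id = id, group = group, side = side, roi = roi,
           affected = affected), f)
  }
  for (i in seq_len(n_patients)) {
    aff <- if (i %% 2 == 0) "left" else "right"
    for (side in c("left", "right")) for (roi in c("hippocampal", "temporal"))
      rows[[length(rows) + 1]] <- add_row(sprintf("P%02d", i), "patient",
                                          side, roi, as.integer(side == aff))
  }
  for (i in seq_len(n_controls))
    for (side in c("left", "right")) for (roi in c("hippocampal", "temporal"))
      rows[[length(rows) + 1]] <- add_row(sprintf("C%02d", i), "control",
                                          side, roi, 0L)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  class(df) <- c("rad_features", class(df))
  df
}

# direct access to the internal per-matrix GLCM feature computation
glcm_feature_vec_test <- function(P) radlat:::glcm_feature_vec(P)

# loop-based first-principles implementations of the 23 co-occurrence
# features, independent of the package's vectorized version
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P)
  mux <- sum(seq_len(ng) * px)
  sx2 <- sum((seq_len(ng) - mux)^2 * px)
  auto <- clusP <- clusS <- clusT <- ctr <- id <- idn <- idm <- idmn <- 0
  iv <- jent <- jen <- 0
  hxy1 <- hxy2 <- hx <- 0
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in seq_len(ng)) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    for (j in seq_len(ng)) {
      p <- P[i, j]
      auto <- auto + i * j * p
      clusP <- clusP + (i + j - 2 * mux)^4 * p
      clusS <- clusS + (i + j - 2 * mux)^3 * p
      clusT <- clusT + (i + j - 2 * mux)^2 * p
      ctr <- ctr + (i - j)^2 * p
      id <- id + p / (1 + abs(i - j))
      idn <- idn + p / (1 + abs(i - j) / ng)
      idm <- idm + p / (1 + (i - j)^2)
      idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
      if (i != j) iv <- iv + p / (i - j)^2
      jen <- jen + p^2
      if (p > 0) jent <- jent - p * log2(p)
      pp <- px[i] * px[j]
      if (p > 0 && pp > 0) hxy1 <- hxy1 - p * log2(pp)
      if (pp > 0) hxy2 <- hxy2 - pp * log2(pp)
      psum[i + j] <- psum[i + j] + p
      pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
    }
  }
  sav <- sum((1:(2 * ng)) * psum)
  sent <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  da <- sum((0:(ng - 1)) * pdif)
  dent <- -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  dvar <- sum(((0:(ng - 1)) - da)^2 * pdif)
  corr <- if (sx2 > 0) (auto - mux^2) / sx2 else 1
  imc1 <- if (hx > 0) (jent - hxy1) / hx else 0
  imc2 <- if (hxy2 >= jent) sqrt(1 - exp(-2 * (hxy2 - jent))) else 0
  c(Autocorrelation = auto, ClusterProminence = clusP, ClusterShade = clusS,
    ClusterTendency = clusT, Contrast = ctr, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, JointAverage = mux, JointEnergy = jen,
    JointEntropy = jent, Imc1 = imc1, Imc2 = imc2, Id = id, Idn = idn,
    Idm = idm, Idmn = idmn, InverseVariance = iv,
    MaximumProbability = max(P), SumAverage = sav, SumEntropy = sent,
    SumOfSquares = sx2)
}

# loop-based 12 run-length features
oracle_glrlm_features <- function(M, np) {
  nr <- sum(M)
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (g in seq_len(nrow(M))) for (l in seq_len(ncol(M))) {
    r <- M[g, l]
    sre <- sre + r / l^2; lre <- lre + r * l^2
    lgl <- lgl + r / g^2; hgl <- hgl + r * g^2
    srl <- srl + r / (g^2 * l^2); srh <- srh + r * g^2 / l^2
    lrl <- lrl + r * l^2 / g^2; lrh <- lrh + r * g^2 * l^2
  }
  pg <- rowSums(M) / nr
  mug <- sum(seq_len(nrow(M)) * pg)
  c(ShortRunEmphasis = sre / nr, LongRunEmphasis = lre / nr,
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nr,
    RunLengthNonUniformity = sum(colSums(M)^2) / nr,
    RunPercentage = nr / np,
    LowGrayLevelRunEmphasis = lgl / nr, HighGrayLevelRunEmphasis = hgl / nr,
    ShortRunLowGrayLevelEmphasis = srl / nr,
    ShortRunHighGrayLevelEmphasis = srh / nr,
    LongRunLowGrayLevelEmphasis = lrl / nr,
    LongRunHighGrayLevelEmphasis = lrh / nr,
    GrayLevelVariance = sum(pg * (seq_len(nrow(M)) - mug)^2))
}
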