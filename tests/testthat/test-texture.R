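disc_from_levels <- function(lv, ng) {
  # wrap a ready-made level array as a disc_roi (levels 0 = outside)
  structure(list(levels = lv, mask = lv > 0L, n_levels = ng),
            class = "disc_roi")
}

test_that("GLCM of simple constructed patterns matches hand enumeration", {
  # constant 2x2x2 ROI: single entry P(1,1) = 1 at any direction
  d <- disc_from_levels(array(1L, c(2, 2, 2)), 4)
  P <- compute_glcm(d, 1, c(1, 0, 0))
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  expect_equal(attr(P, "n_pairs"), 8)  # 4 pairs, symmetrized

  # 1D strip 1,2,1,2 along x: 3 pairs, all cross-level
  d2 <- disc_from_levels(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), 2)
  P2 <- compute_glcm(d2, 1, c(1, 0, 0))
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1] + P2[2, 2], 0)

  # mask thinner than the offset: flagged empty
  P3 <- compute_glcm(d2, 1, c(0, 0, 1))
  expect_equal(attr(P3, "n_pairs"), 0)
})

test_that("GLCM matrices equal the brute-force pair-enumeration oracle", {
  set.seed(31)
  fx <- make_toy_fixtures()
  lv <- fx$random
  lv[sample(125, 30)] <- 0L  # irregular mask
  d <- disc_from_levels(lv, 4)
  dirs <- directions_3d()
  for (dist in 1:3) for (k in seq_len(nrow(dirs))) {
    P <- compute_glcm(d, dist, dirs[k, ])
    O <- oracle_glcm(lv, 4, dist * dirs[k, ])
    expect_equal(unclass(P), unclass(O), ignore_attr = TRUE)
    expect_equal(attr(P, "n_pairs"), attr(O, "n_pairs"))
    expect_equal(P, t(P), ignore_attr = TRUE)   # symmetry
    if (attr(P, "n_pairs") > 0) expect_equal(sum(P), 1)
  }
})

test_that("GLCM features: point-mass matrix, checkerboard contrast, aggregation consistency", {
  d <- disc_from_levels(array(1L, c(3, 3, 3)), 8)
  dirs <- directions_3d()
  glcms <- lapply(seq_len(nrow(dirs)), function(k) compute_glcm(d, 1, dirs[k, ]))
  f <- glcm_features(glcms)
  expect_length(f, 46L)
  for (agg in c("avg", "mrg")) {
    expect_equal(unname(f[paste0(agg, "_JointEnergy")]), 1)
    expect_equal(unname(f[paste0(agg, "_JointEntropy")]), 0)
    expect_equal(unname(f[paste0(agg, "_Contrast")]), 0)
    expect_equal(unname(f[paste0(agg, "_MaximumProbability")]), 1)
  }

  # checkerboard: every distance-1 axis neighbour differs by exactly 1 level
  fx <- make_toy_fixtures()
  dchk <- disc_from_levels(fx$checkerboard, 2)
  for (ax in 1:3) {
    dir <- c(0L, 0L, 0L); dir[ax] <- 1L
    P <- compute_glcm(dchk, 1, dir)
    feats <- glcm_feature_vec_test(P)
    expect_equal(unname(feats["Contrast"]), 1)
  }

  # when all 13 directional matrices are identical, avg and mrg agree
  same <- lapply(1:13, function(k) compute_glcm(dchk, 1, c(1L, 0L, 0L)))
  fs <- glcm_features(same)
  expect_equal(unname(fs[paste0("avg_", sub("avg_", "", names(fs)[1:23]))]),
               unname(fs[24:46]), tolerance = 1e-12)
})

test_that("merged-aggregation GLCM features match an explicit merged-matrix oracle", {
  set.seed(32)
  lv <- array(sample(0:3, 216, TRUE), c(6, 6, 6))
  d <- disc_from_levels(lv, 3)
  dirs <- directions_3d()
  glcms <- lapply(seq_len(nrow(dirs)), function(k) compute_glcm(d, 1, dirs[k, ]))
  f <- glcm_features(glcms)
  counts <- Reduce(`+`, lapply(seq_len(nrow(dirs)), function(k)
    oracle_glcm(lv, 3, dirs[k, ]) * attr(oracle_glcm(lv, 3, dirs[k, ]), "n_pairs")))
  M <- counts / sum(counts)
  attr(M, "n_pairs") <- sum(counts)
  of <- glcm_feature_vec_test(M)
  expect_equal(unname(f[paste0("mrg_", names(of))]), unname(of),
               tolerance = 1e-10)
})

test_that("GLRLM matrices and features follow run enumeration", {
  fx <- make_toy_fixtures()
  d <- disc_from_levels(fx$strip, 2)   # 1,1,1,2,2 along x
  M <- compute_glrlm(d, c(1, 0, 0))
  expect_equal(M[1, 3], 1)  # one run of level 1, length 3
  expect_equal(M[2, 2], 1)  # one run of level 2, length 2
  expect_equal(sum(M), 2)
  f <- glrlm_features(rep(list(M), 13))
  expect_equal(unname(f["avg_RunPercentage"]), 2 / 5)

  # constant line: one maximal run of length n
  dl <- disc_from_levels(array(1L, c(7, 1, 1)), 2)
  Ml <- compute_glrlm(dl, c(1, 0, 0))
  expect_equal(Ml[1, 7], 1)
  expect_equal(sum(Ml), 1)

  # single run of length 4: run percentage 1/4
  d4 <- disc_from_levels(array(1L, c(4, 1, 1)), 2)
  f4 <- glrlm_features(rep(list(compute_glrlm(d4, c(1, 0, 0))), 13))
  expect_equal(unname(f4["avg_RunPercentage"]), 1 / 4)

  # all runs length 1: both emphases are 1
  da <- disc_from_levels(array(c(1L, 2L, 1L, 2L, 1L), c(5, 1, 1)), 2)
  fa <- glrlm_features(rep(list(compute_glrlm(da, c(1, 0, 0))), 13))
  expect_equal(unname(fa["avg_ShortRunEmphasis"]), 1)
  expect_equal(unname(fa["avg_LongRunEmphasis"]), 1)
})

test_that("GLRLM matrices and all 12 features match the brute-force oracle", {
  set.seed(33)
  lv <- make_toy_fixtures()$random
  lv[sample(125, 25)] <- 0L
  d <- disc_from_levels(lv, 4)
  dirs <- directions_3d()
  for (k in seq_len(nrow(dirs))) {
    M <- compute_glrlm(d, dirs[k, ])
    O <- oracle_glrlm(lv, 4, dirs[k, ])
    expect_equal(unclass(M)[, seq_len(ncol(O))], unclass(O),
                 ignore_attr = TRUE)
    # total voxels covered by runs along a direction = mask size
    expect_equal(sum(M %*% seq_len(ncol(M))), sum(lv > 0))
    # 12 features from first-principles formulas on the oracle matrix
    np <- sum(lv > 0); nr <- sum(O)
    g <- seq_len(nrow(O)); l <- seq_len(ncol(O))
    fo <- glrlm_features(rep(list(M), 13))
    expect_equal(unname(fo["avg_ShortRunEmphasis"]),
                 sum(sweep(O, 2, l^2, `/`)) / nr)
    expect_equal(unname(fo["avg_LongRunEmphasis"]),
                 sum(sweep(O, 2, l^2, `*`)) / nr)
    expect_equal(unname(fo["avg_GrayLevelNonUniformity"]),
                 sum(rowSums(O)^2) / nr)
    expect_equal(unname(fo["avg_RunLengthNonUniformity"]),
                 sum(colSums(O)^2) / nr)
    expect_equal(unname(fo["avg_RunPercentage"]), nr / np)
    expect_equal(unname(fo["avg_LowGrayLevelRunEmphasis"]),
                 sum(sweep(O, 1, g^2, `/`)) / nr)
    expect_equal(unname(fo["avg_HighGrayLevelRunEmphasis"]),
                 sum(sweep(O, 1, g^2, `*`)) / nr)
    mug <- sum(g * rowSums(O) / nr)
    expect_equal(unname(fo["avg_GrayLevelVariance"]),
                 sum(rowSums(O) / nr * (g - mug)^2))
  }
})

test_that("texture family totals 162 and direction-averaged features are flip-invariant", {
  set.seed(34)
  vals <- array(rnorm(7^3), c(7, 7, 7))
  mask <- array(runif(7^3) < 0.8, c(7, 7, 7))
  tf <- texture_features(vals, mask)
  expect_length(tf, 162L)
  expect_equal(sum(grepl("^glcm_", names(tf))), 138L)
  expect_equal(sum(grepl("^glrlm_", names(tf))), 24L)
  expect_true(all(is.finite(tf)))

  # axis flip: direction set closed under negation + symmetrized GLCM
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  tf2 <- texture_features(flip(vals), flip(mask))
  avg <- grepl("_avg_|_mrg_", names(tf))
  expect_equal(tf[avg], tf2[avg], tolerance = 1e-10)
})

test_that("level permutation moves contrast but not joint energy/entropy", {
  lv <- array(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L), c(8, 1, 1))
  d1 <- disc_from_levels(lv, 4)
  perm <- c(1L, 4L, 2L, 3L)    # level 2 -> 4: adjacent pairs now differ by 3
  d2 <- disc_from_levels(array(perm[lv], dim(lv)), 4)
  P1 <- compute_glcm(d1, 1, c(1, 0, 0))
  P2 <- compute_glcm(d2, 1, c(1, 0, 0))
  f1 <- glcm_feature_vec_test(P1); f2 <- glcm_feature_vec_test(P2)
  expect_equal(unname(f1["JointEnergy"]), unname(f2["JointEnergy"]))
  expect_equal(unname(f1["JointEntropy"]), unname(f2["JointEntropy"]))
  expect_false(isTRUE(all.equal(unname(f1["Contrast"]),
                                unname(f2["Contrast"]))))
})
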