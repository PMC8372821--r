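fo_of <- function(x, ng = 32) {
  vals <- array(x, c(length(x), 1, 1))
  mask <- array(TRUE, dim(vals))
  firstorder_features(x, discretize(vals, mask, disc_config(ng)))
}

test_that("hand-computed values on {1,2,3,4} and degenerate constants", {
  f <- fo_of(c(1, 2, 3, 4))
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Variance"]), 1.25)      # population variance
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["RootMeanSquare"]), sqrt(30 / 4))

  fc <- fo_of(rep(7, 20))
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Entropy"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
  expect_equal(unname(fc["Range"]), 0)
  expect_equal(unname(fc["Skewness"]), 0)
  expect_equal(unname(fc["Kurtosis"]), 0)
  expect_equal(unname(fc["Mean"]), 7)
  expect_equal(unname(fc["Median"]), 7)
})

test_that("two equal-mass levels give 1 bit of entropy and uniformity 1/2", {
  f <- fo_of(rep(c(0, 10), each = 25), ng = 2)
  expect_equal(unname(f["Entropy"]), 1)
  expect_equal(unname(f["Uniformity"]), 0.5)
})

test_that("all 17 features agree with a first-principles oracle on random multisets", {
  set.seed(21)
  for (rep in 1:5) {
    x <- round(rnorm(50, sd = 4), 2)
    ng <- 8
    f <- fo_of(x, ng)
    expect_equal(length(f), 17L)
    m <- mean(x); n <- length(x)
    v <- sum((x - m)^2) / n
    lv <- pmin(ng, floor(ng * (x - min(x)) / (max(x) - min(x))) + 1)
    p <- as.vector(table(lv)) / n
    expect_equal(unname(f["Mean"]), m)
    expect_equal(unname(f["Variance"]), v)
    expect_equal(unname(f["StandardDeviation"]), sqrt(v))
    expect_equal(unname(f["Skewness"]), sum((x - m)^3) / n / v^1.5)
    expect_equal(unname(f["Kurtosis"]), sum((x - m)^4) / n / v^2)
    expect_equal(unname(f["MeanAbsoluteDeviation"]), mean(abs(x - m)))
    expect_equal(unname(f["Entropy"]), -sum(p * log2(p)))
    expect_equal(unname(f["Uniformity"]), sum(p^2))
    expect_equal(unname(f["Median"]), median(x))
    expect_equal(unname(f["P10"]), unname(quantile(x, 0.1)))
    expect_equal(unname(f["P90"]), unname(quantile(x, 0.9)))
    expect_equal(unname(f["InterquartileRange"]),
                 unname(diff(quantile(x, c(0.25, 0.75)))))
    expect_equal(unname(f["Minimum"]), min(x))
    expect_equal(unname(f["Maximum"]), max(x))
  }
})

test_that("adding a constant shifts location features and fixes dispersion features", {
  set.seed(22)
  x <- rnorm(80)
  f0 <- fo_of(x); f1 <- fo_of(x + 11)
  for (nm in c("Mean", "Median", "Minimum", "Maximum", "P10", "P90"))
    expect_equal(unname(f1[nm] - f0[nm]), 11, tolerance = 1e-12)
  for (nm in c("Variance", "StandardDeviation", "Entropy", "Uniformity",
               "Range", "InterquartileRange", "Skewness", "Kurtosis"))
    expect_equal(unname(f1[nm]), unname(f0[nm]), tolerance = 1e-9)
  expect_true(f0["Entropy"] >= 0 && f0["Entropy"] <= log2(32))
  expect_true(f0["Uniformity"] > 0 && f0["Uniformity"] <= 1)
})

test_that("shape features match direct geometry on voxel solids", {
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  s1 <- shape_features(m1, c(1, 1, 1))
  expect_equal(unname(s1["VoxelVolume"]), 1)
  expect_equal(unname(s1["SurfaceArea"]), 6)
  expect_equal(unname(s1["Maximum3DDiameter"]), 0)

  m2 <- array(FALSE, c(4, 4, 4)); m2[2:3, 2:3, 2:3] <- TRUE
  s2 <- shape_features(m2, c(1, 1, 1))
  expect_equal(unname(s2["VoxelVolume"]), 8)
  expect_equal(unname(s2["SurfaceArea"]), 24)
  expect_equal(unname(s2["Maximum3DDiameter"]), sqrt(3))
  expect_equal(unname(s2["SurfaceVolumeRatio"]), 3)

  # anisotropic spacing scales volume and faces correctly
  s3 <- shape_features(m1, c(2, 1, 1))
  expect_equal(unname(s3["VoxelVolume"]), 2)
  expect_equal(unname(s3["SurfaceArea"]), 2 * 1 + 4 * 2)
  expect_error(shape_features(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("digital-ball sphericity is maximal among tested solids and approaches the staircase limit", {
  ball_at <- function(r) {
    g <- seq_len(2 * r + 3); c0 <- r + 2
    dist2 <- outer(outer((g - c0)^2, (g - c0)^2, `+`), (g - c0)^2, `+`)
    dist2 <= r^2
  }
  # with face-count (staircase) surface area the ball's surface is 3/2 the
  # smooth sphere's, so sphericity tends to 2/3 from below as r grows
  s10 <- shape_features(ball_at(10), c(1, 1, 1))
  s20 <- shape_features(ball_at(20), c(1, 1, 1))
  expect_lt(unname(s20["Sphericity"]), 1)
  expect_gt(unname(s20["Sphericity"]), 0.6)
  expect_lt(abs(unname(s20["Sphericity"]) - 2 / 3), 0.05)
  # a thin slab is far less spherical than the ball
  sm <- shape_features(array(TRUE, c(2, 20, 20)), c(1, 1, 1))
  expect_lt(unname(sm["Sphericity"]), unname(s20["Sphericity"]))
  # spherical disproportion mirrors sphericity on the same solids
  expect_gt(unname(sm["SphericalDisproportion"]),
            unname(s20["SphericalDisproportion"]))
})
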