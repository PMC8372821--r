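std_mat <- function(X) {
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  Z
}

test_that("the fully penalized limit is the intercept-only model", {
  set.seed(61)
  Z <- std_mat(matrix(rnorm(40 * 5), 40, 5,
                      dimnames = list(NULL, paste0("f", 1:5))))
  y <- rep(c(1, 0), c(15, 25))
  fit <- fit_enet(Z, y, alpha = 0.5, lambda = 1e3)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("the unpenalized limit matches an independent Newton solver", {
  set.seed(62)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  eta <- 0.5 + X %*% c(1, -0.8, 0)
  y <- rbinom(n, 1, plogis(eta))
  Z <- std_mat(X)
  fit <- fit_enet(Z, y, alpha = 0.5, lambda = 0)
  b_or <- oracle_logistic(Z, y)
  expect_equal(fit$intercept, b_or[1], tolerance = 1e-4)
  expect_equal(unname(fit$beta), b_or[-1], tolerance = 1e-4)
})

test_that("LASSO zeroes coefficients at finite lambda while ridge never does", {
  set.seed(63)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(n, 1, plogis(X %*% c(1.2, 0.8)))
  Z <- std_mat(X)
  lam <- 0.05
  f1 <- fit_enet(Z, y, alpha = 1, lambda = 2)     # far beyond entry point
  f0 <- fit_enet(Z, y, alpha = 0, lambda = 2)
  expect_true(all(f1$beta == 0))
  expect_true(all(abs(f0$beta) > 1e-8))           # ridge shrinks, never kills
  # shrinkage ordering along the path at alpha = 1
  fs <- fit_enet(Z, y, alpha = 1, lambda = lam)
  fl <- fit_enet(Z, y, alpha = 1, lambda = lam / 10)
  expect_true(all(abs(fs$beta) <= abs(fl$beta) + 1e-8))
})

test_that("nonzero-coefficient count is non-increasing in lambda at fixed alpha", {
  set.seed(64)
  n <- 120; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(X %*% c(rep(1, 4), rep(0, p - 4))))
  Z <- std_mat(X)
  path <- exp(seq(log(0.5), log(1e-4), length.out = 12))
  nz <- vapply(path, function(l) sum(fit_enet(Z, y, 1, l)$beta != 0),
               numeric(1))
  expect_true(all(diff(nz) >= -1e-9))  # path ordered large -> small lambda
})

test_that("cross-validated tuning prefers informative models and is reproducible", {
  set.seed(65)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.5) > 0)
  Z <- std_mat(X)
  cfg <- enet_config(alpha_grid = c(0, 0.5, 1), n_lambda = 40, fold_seed = 9)
  tune <- cv_tune(Z, y, cfg)
  null_mse <- max(tune$curve$mse[tune$curve$lambda ==
                                   max(tune$curve$lambda)])
  expect_lt(tune$cv_mse, null_mse)
  tune2 <- cv_tune(Z, y, cfg)
  expect_equal(tune$alpha, tune2$alpha)
  expect_equal(tune$lambda, tune2$lambda)
})

test_that("pure-noise features give a near-null tuned model", {
  set.seed(66)
  n <- 200; p <- 50
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c(0L, 1L), n / 2)
  Z <- std_mat(X)
  tune <- cv_tune(Z, y, enet_config(alpha_grid = c(0.1, 0.5, 1),
                                    n_lambda = 30, fold_seed = 2))
  fit <- fit_enet(Z, y, tune$alpha, tune$lambda)
  expect_lte(sum(fit$beta != 0), 5)
  expect_equal(tune$cv_mse, 0.25, tolerance = 0.03)  # Bernoulli variance
})

test_that("prediction applies stored standardization and is monotone and consistent", {
  set.seed(67)
  tab <- toy_feature_table(6, 6, n_feat = 4)
  # plant signal into f1 for affected hippocampal rows
  hot <- tab$affected == 1
  tab$f1[hot] <- tab$f1[hot] + 3
  fit <- laterality_model(tab, "hippocampal",
                          enet = enet_config(alpha_grid = 0.5, n_lambda = 30,
                                             k_folds = 4), seed = 5)
  # at the training feature means the score is plogis(intercept)
  mu <- fit$center
  expect_equal(unname(predict(fit, mu)), plogis(fit$intercept),
               tolerance = 1e-12)
  # monotone in a positive-weight feature
  if (any(fit$beta > 0)) {
    nm <- names(which.max(fit$beta))
    lo <- mu; hi <- mu; hi[nm] <- hi[nm] + 1
    expect_gt(predict(fit, hi), predict(fit, lo))
  }
  # batch and single-row prediction agree
  rows <- tab[1:4, ]
  batch <- predict(fit, rows)
  single <- vapply(1:4, function(i)
    predict(fit, unlist(rows[i, feature_columns(tab)])), numeric(1))
  expect_equal(unname(batch), unname(single), tolerance = 1e-12)
  expect_true(all(batch > 0 & batch < 1))
  expect_error(predict(fit, mu[-1]), "missing feature")
})

test_that("model JSON round trip reproduces predictions", {
  set.seed(68)
  tab <- toy_feature_table(5, 5, n_feat = 3)
  tab$f2[tab$affected == 1] <- tab$f2[tab$affected == 1] + 2
  fit <- laterality_model(tab, "temporal",
                          enet = enet_config(alpha_grid = c(0.2, 0.9),
                                             n_lambda = 25, k_folds = 4), seed = 3)
  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  fit2 <- read_model_json(f)
  expect_equal(predict(fit2, tab[1:6, ]), predict(fit, tab[1:6, ]),
               tolerance = 1e-9)
  expect_equal(fit2$alpha, fit$alpha)
})

test_that("single-class responses are rejected", {
  Z <- std_mat(matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(fit_enet(Z, rep(1, 10), 0.5, 0.1), "single class")
})
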