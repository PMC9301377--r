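test_that("feature assembly emits the 13 predictors in canonical order", {
  su <- setup_config(400, 100, 10, 100)
  kin <- data.frame(stroke = 1:3, contact = c(-20, -10, 0),
                    release = c(70, 80, 90))
  f <- assemble_features(su, kin)
  expect_length(f, 13)
  expect_equal(names(f), feature_names())
  expect_equal(unname(f), c(400, 100, 10, 100, -20, -10, 0, 70, 80, 90,
                            90, 90, 90))
  # order of kinematic rows does not matter
  f2 <- assemble_features(su, kin[c(3, 1, 2), ])
  expect_equal(f2, f)
  # contact = release collapses the push entries
  kin0 <- data.frame(stroke = 1:3, contact = c(1, 2, 3), release = c(1, 2, 3))
  expect_equal(unname(assemble_features(su, kin0)[11:13]), c(0, 0, 0))
  expect_error(assemble_features(su, kin[1:2, ]), "incomplete features")
})

test_that("PLS fits exactly when the response is linear in full-rank predictors", {
  set.seed(21)
  X <- matrix(rnorm(30 * 5), 30, 5)
  beta <- c(0.5, -1, 2, 0.2, -0.7)
  y <- 2 + drop(X %*% beta)
  m <- train_pls(X, y, n_components = 5)
  resid <- y - predict_time(m, X)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("one-component PLS on a single predictor is simple least squares", {
  set.seed(22)
  x <- rnorm(40, 10, 3)
  y <- 1.5 + 0.08 * x + rnorm(40, 0, 0.1)
  m <- train_pls(matrix(x, ncol = 1), y, n_components = 1)
  fit <- lm(y ~ x)
  expect_equal(predict_time(m, matrix(x, ncol = 1)),
               unname(fitted(fit)), tolerance = 1e-10)
})

test_that("full-rank PLS training predictions coincide with OLS", {
  set.seed(23)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(25, 0, 0.3)
  m <- train_pls(X, y, n_components = 6)
  ols <- lm(y ~ X)
  expect_equal(predict_time(m, X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("explained variance in the response accumulates monotonically", {
  set.seed(24)
  co <- generate_cohort(1, seed = 77)
  feat <- wheelsprint:::measured_features(
    co$trials[co$trials$athlete_id == "P1", ],
    co$times[co$times$athlete_id == "P1", ], co$plans[["P1"]])
  m <- train_pls(as.matrix(feat[feature_names()]), feat$time_s,
                 n_components = 8)
  expect_true(all(m$explvar_y > -1e-10))
  expect_true(all(diff(cumsum(m$explvar_y)) > -1e-10))
  expect_lte(sum(m$explvar_y), 100 + 1e-8)
})

test_that("predictions are invariant to predictor rescaling when scaling is on", {
  set.seed(25)
  X <- matrix(rnorm(20 * 4, 10), 20, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(20, 0, 0.2)
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000  # e.g. metres -> millimetres
  m1 <- train_pls(X, y, n_components = 3, scale = TRUE)
  m2 <- train_pls(X2, y, n_components = 3, scale = TRUE)
  Xnew <- matrix(rnorm(8 * 4, 10), 8, 4)
  Xnew2 <- Xnew
  Xnew2[, 2] <- Xnew2[, 2] * 1000
  expect_equal(predict_time(m1, Xnew), predict_time(m2, Xnew2),
               tolerance = 1e-8)
})

test_that("degenerate training inputs are refused", {
  X <- matrix(1, 10, 3)
  expect_error(train_pls(X, rnorm(10), 2), "identical")
  expect_error(train_pls(matrix(rnorm(20), 10, 2), rep(1, 10), 2), "constant")
  expect_error(train_pls(matrix(rnorm(20), 10, 2), rnorm(3), 2), "differ")
  expect_error(train_pls(matrix(rnorm(4), 2, 2), rnorm(2), 2), "training rows")
})

test_that("component selection stops at the explained-variance plateau", {
  expect_equal(select_components(c(60, 20, 10, 1, 0.5)), 3)
  expect_equal(select_components(rep(10, 8)), 5)     # cap when no plateau
  expect_equal(select_components(45), 1)             # single component
  expect_equal(select_components(c(1, 50, 30)), 1)   # floor at one component
  expect_equal(select_components(c(60, 20, 10, 1), plateau = 0.5), 4)
  expect_equal(select_components(rep(10, 8), cap = 7), 7)
})

test_that("the train/test split holds out the final two set-ups intact", {
  trials <- expand.grid(trial = 1:2, setup_id = 1:9)
  sp <- split_train_test(trials)
  expect_equal(nrow(sp$train), 14)
  expect_equal(nrow(sp$test), 4)
  expect_equal(sort(unique(sp$train$setup_id)), 1:7)
  expect_equal(sort(unique(sp$test$setup_id)), 8:9)
  expect_length(intersect(sp$train$setup_id, sp$test$setup_id), 0)
  # 7/9 sits inside the conventional 70-30 and 80-20 training bands
  expect_gte(7 / 9, 0.7)
  expect_lte(7 / 9, 0.8)
  # fallback for incomplete designs
  expect_warning(sp6 <- split_train_test(expand.grid(trial = 1:2,
                                                     setup_id = 1:6)),
                 "expected 9 set-ups")
  expect_equal(sort(unique(sp6$test$setup_id)), 5:6)
})

test_that("prediction applies centering and checks dimensions", {
  set.seed(26)
  X <- matrix(rnorm(20 * 3, 5), 20, 3)
  y <- rnorm(20, 2.4, 0.2)
  m <- train_pls(X, y, n_components = 2)
  expect_equal(predict_time(m, colMeans(X)), mean(y))
  expect_error(predict_time(m, rnorm(5)), "feature dimension")
})

test_that("a linear cohort with small time noise is predicted within 0.05 s", {
  co <- generate_cohort(4, seed = 404, angle_sd = 0, time_sd = 0.02)
  res <- run_pipeline(co)
  expect_lte(mean(abs(res$time_predictions$diff_s)), 0.05)
})
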