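test_that("stratified splitting is proportional, disjoint and seeded", {
  strata <- rep("a", 1000)
  lab <- split_stratified(strata, 0.2, seed = 3)
  expect_identical(sum(lab == "test"), 200L)
  expect_identical(sum(lab == "train"), 800L)
  expect_identical(lab, split_stratified(strata, 0.2, seed = 3))
  expect_false(identical(lab, split_stratified(strata, 0.2, seed = 4)))

  set.seed(9)
  strata <- sample(paste0("s", 1:6), 3000, replace = TRUE,
                   prob = c(0.4, 0.25, 0.15, 0.1, 0.07, 0.03))
  lab <- split_stratified(strata, 0.2, seed = 1)
  for (s in unique(strata)) {
    n_s <- sum(strata == s)
    n_t <- sum(strata == s & lab == "test")
    expect_lte(abs(n_t - 0.2 * n_s), 1)
  }
  expect_warning(split_stratified(c("a", "a", "b"), 0.2, seed = 1),
                 "best-effort")

  folds <- assign_folds(strata, 5, seed = 2)
  expect_setequal(unique(folds), 1:5)
  for (s in unique(strata)) {
    tab <- table(folds[strata == s])
    expect_lte(diff(range(tab)), 1)
  }
})

test_that("learning-rate schedule halves on stagnation down to the floor", {
  set.seed(1)
  x <- matrix(runif(60 * 30), 60, 30)
  y <- rnorm(60)
  # min_delta larger than any achievable improvement: every epoch counts as
  # stagnant, so the LR must halve every lr_patience epochs
  cfg <- model_config(max_epochs = 25, lr_patience = 10, es_patience = 100,
                      min_delta = 1e9, seed = 2)
  m <- train_model(x, y, x, y, cfg)
  # epoch 1 always improves on the infinite initial best, so the stagnation
  # clock starts at epoch 2: halvings take effect at epochs 12 and 22
  expect_equal(m$history$lr[1:11], rep(0.01, 11))
  expect_equal(m$history$lr[12:21], rep(0.005, 10))
  expect_equal(m$history$lr[22:25], rep(0.0025, 4))
  # floor at 1e-4
  cfg2 <- model_config(max_epochs = 12, lr = 2e-4, lr_patience = 2,
                       es_patience = 100, min_delta = 1e9, seed = 2)
  m2 <- train_model(x, y, x, y, cfg2)
  expect_equal(min(m2$history$lr), 1e-4)
  expect_true(all(m2$history$lr >= 1e-4))
})

test_that("early stopping restores the best-validation weights", {
  set.seed(4)
  x <- matrix(runif(400 * 30), 400, 30)
  y <- rowSums(x[, 1:3]) + rnorm(400, sd = 0.01)
  cfg <- model_config(max_epochs = 300, es_patience = 10, seed = 3)
  m <- train_model(x[1:300, ], y[1:300], x[301:400, ], y[301:400], cfg)
  expect_lt(nrow(m$history), 300)
  # the restored epoch is optimal up to the min_delta improvement slack
  expect_lte(m$history$val_rmse[m$best_epoch],
             min(m$history$val_rmse) + cfg$min_delta)
})

test_that("prediction is deterministic, order-independent and width-checked", {
  model <- get_tiny_model()
  set.seed(6)
  poses <- generate_random(random_spec(n = 20, seed = 2), "I")
  dt <- generate_dataset(poses, noiseless_params())
  x <- as.matrix(as.data.frame(dt)[, feature_names()])
  p1 <- predict(model, x)
  expect_identical(p1, predict(model, x))
  ord <- sample(nrow(x))
  expect_equal(predict(model, x[ord, ]), p1[ord], tolerance = 1e-12)
  expect_error(predict(model, x[, 1:10]), "width")

  # zero-weight network outputs its output-layer bias
  z <- model
  z$W <- lapply(z$W, function(w) w * 0)
  z$b <- lapply(z$b, function(b) b * 0)
  z$b[[length(z$b)]] <- 0.25
  expect_equal(unique(predict(z, x)),
               0.25 * z$y_scale + z$y_center, tolerance = 1e-12)
})

test_that("evaluation metrics and histogram follow their definitions", {
  r <- evaluate_predictions(c(0, 1, 2), c(0, 1, 5))
  expect_equal(r$rmse, sqrt(3))
  expect_equal(r$mae, 1)
  r2 <- evaluate_predictions(c(-23.77, 1), c(-14.66, 1))
  expect_equal(r2$dde[1], -9.11)
  perf <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perf$r2, 1)
  expect_equal(perf$rmse, 0)
  expect_equal(perf$mae, 0)
  set.seed(8)
  dde <- c(rnorm(100), -7, 9, 4, -4)  # includes out-of-range and edge values
  r3 <- evaluate_predictions(dde, rep(0, length(dde)))
  expect_identical(sum(r3$histogram$count), length(dde))
  expect_identical(nrow(r3$histogram), 16L)
  expect_warning(evaluate_predictions(c(1, 1), c(1, 2)), "zero-variance")
})

test_that("checkpoints round-trip bit-identically", {
  model <- get_tiny_model()
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path1)
  back <- load_checkpoint(path1)
  set.seed(12)
  probe <- generate_dataset(generate_random(random_spec(n = 10, seed = 3), "Br"),
                            noiseless_params())
  x <- as.matrix(as.data.frame(probe)[, feature_names()])
  expect_identical(predict(back, x), predict(model, x))
  save_checkpoint(back, path2)
  expect_identical(readLines(path1), readLines(path2))
  writeLines("{\"format\": \"other\"}", path2)
  expect_error(load_checkpoint(path2), "unsupported checkpoint format")
})
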