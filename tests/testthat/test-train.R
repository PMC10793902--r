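test_that("metrics match hand-computed values on toy batches", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rp, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  m2 <- compute_metrics(c(1, 2, 3), c(3, 2, 1))
  expect_equal(m2$rp, -1)
  expect_equal(m2$rmse, sqrt(8 / 3), tolerance = 1e-9)
  expect_equal(m2$mae, 4 / 3, tolerance = 1e-9)
  expect_error(compute_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(compute_metrics(1, 1), "two observations")
})

test_that("metrics agree with a naive two-pass reference on random batches", {
  naive <- function(p, y) {
    n <- length(p)
    pb <- sum(p) / n; yb <- sum(y) / n
    num <- 0; dp <- 0; dy <- 0; se <- 0; ae <- 0
    for (i in seq_len(n)) {
      num <- num + (p[i] - pb) * (y[i] - yb)
      dp <- dp + (p[i] - pb)^2
      dy <- dy + (y[i] - yb)^2
      se <- se + (y[i] - p[i])^2
      ae <- ae + abs(y[i] - p[i])
    }
    list(rp = num / sqrt(dp * dy), rmse = sqrt(se / n), mae = ae / n)
  }
  set.seed(10)
  for (rep in 1:20) {
    p <- stats::rnorm(50); y <- stats::rnorm(50)
    m <- compute_metrics(p, y)
    r <- naive(p, y)
    expect_equal(m$rp, r$rp, tolerance = 1e-12)
    expect_equal(m$rmse, r$rmse, tolerance = 1e-12)
    expect_equal(m$mae, r$mae, tolerance = 1e-12)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("losses match their piecewise definitions", {
  expect_equal(loss_mse(c(1, 2), c(1, 2)), 0)
  expect_equal(loss_smooth_l1(c(1, 2), c(1, 2)), 0)
  expect_equal(loss_smooth_l1(0.5, 0), 0.125)
  expect_equal(loss_smooth_l1(2, 0), 1.5)
  expect_equal(loss_mse(2, 0), 4)
  # continuity at |residual| = 1: both pieces give 0.5
  expect_equal(loss_smooth_l1(1, 0), 0.5)
  expect_equal(loss_smooth_l1(1 - 1e-9, 0), 0.5, tolerance = 1e-6)
  set.seed(11)
  for (rep in 1:10) {
    p <- stats::rnorm(30); y <- stats::rnorm(30)
    # algebraic identity with RMSE
    expect_equal(loss_mse(p, y), compute_metrics(p, y)$rmse^2, tolerance = 1e-12)
    # smooth L1 bounded by the quadratic everywhere
    expect_lte(loss_smooth_l1(p, y), loss_mse(p, y) / 2 + 0.5)
  }
})

test_that("the custom loss interpolates correlation and error", {
  p <- c(1, 2, 3); y <- c(3, 2, 1)
  expect_equal(loss_custom(p, y, 0), compute_metrics(p, y)$rmse)
  expect_equal(loss_custom(c(1, 2, 3), c(1, 2, 3), 1), 0)
  expect_equal(loss_custom(p, y, 0.5), 0.5 * 2 + 0.5 * sqrt(8 / 3),
               tolerance = 1e-9)
  expect_equal(loss_custom_printed(p, y, 0.5), 0.5 * (-1) + 0.5 * sqrt(8 / 3),
               tolerance = 1e-9)
  expect_error(loss_custom(p, y, 1.2), "alpha")
  expect_error(loss_config("custom", alpha = -0.1), "alpha")
})

test_that("loss gradients match finite differences", {
  set.seed(12)
  p <- stats::rnorm(12); y <- stats::rnorm(12)
  for (lc in list(loss_config("mse"), loss_config("smooth_l1"),
                  loss_config("custom", alpha = 0.4))) {
    lg <- loss_and_grad(p, y, lc)
    num <- vapply(seq_along(p), function(i) {
      e <- 1e-6
      p1 <- p; p1[i] <- p[i] + e
      p0 <- p; p0[i] <- p[i] - e
      (loss_and_grad(p1, y, lc)$value - loss_and_grad(p0, y, lc)$value) / (2 * e)
    }, numeric(1))
    expect_equal(lg$grad, num, tolerance = 1e-5)
  }
})

train_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_dataset(24, seed = 91, lig = c(8, 14), poc = c(4, 7))
      cfg <- tiny_model_config()
      samples <- featurize_dataset(ds, cfg)
      lab <- attr(samples, "labels")
      tr <- samples[1:18]; attr(tr, "labels") <- lab[1:18]
      va <- samples[19:24]; attr(va, "labels") <- lab[19:24]
      cache <<- list(cfg = cfg, tr = tr, va = va)
    }
    cache
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  fx <- train_fixture()
  tc <- train_config(max_epochs = 6, seed = 3, batch_size = 18, lr = 5e-4)
  fit1 <- train_model(fx$tr, fx$va, fx$cfg, tc, loss_config("mse"))
  expect_equal(nrow(fit1$history), 6)
  # strict decrease over the first epochs of full-batch descent
  expect_true(all(diff(fit1$history$train_loss[1:5]) < 0))
  fit2 <- train_model(fx$tr, fx$va, fx$cfg, tc, loss_config("mse"))
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("a zero learning rate freezes the validation metrics", {
  fx <- train_fixture()
  tc <- train_config(max_epochs = 4, seed = 3, batch_size = 18, lr = 0)
  fit <- train_model(fx$tr, fx$va, fx$cfg, tc, loss_config("mse"))
  expect_equal(length(unique(fit$history$val_rmse)), 1)
  expect_equal(length(unique(fit$history$val_mae)), 1)
})

test_that("fold assignment partitions the data with balanced sizes", {
  for (k in c(2, 3, 10)) {
    f <- make_folds(50, k, seed = 7)
    expect_length(f, 50)
    expect_setequal(unique(f), seq_len(k))
    sizes <- table(f)
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # leave-one-out: every fold has exactly one element
  f <- make_folds(12, 12, seed = 1)
  expect_true(all(table(f) == 1))
  expect_identical(make_folds(30, 5, seed = 2), make_folds(30, 5, seed = 2))
  expect_error(make_folds(10, 1), "at least 2")
  expect_error(make_folds(5, 6), "exceeds")
})

test_that("k-fold cross-validation trains one model per fold", {
  ds <- small_dataset(12, seed = 92, lig = c(8, 12), poc = c(4, 6))
  cv <- kfold_cv(ds, k = 3, config = tiny_model_config(),
                 tc = train_config(max_epochs = 2, seed = 1, batch_size = 8),
                 lc = loss_config("mse"), seed = 5)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(sum(cv$per_fold$n_val), 12)
  expect_true(all(is.finite(cv$per_fold$rmse)))
  expect_named(cv$mean, c("rp", "rmse", "mae"))
})
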