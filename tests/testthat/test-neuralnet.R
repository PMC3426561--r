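toy_inputs <- function(n = 30L, d = 4L, seed = 1L) {
  withr::with_seed(seed, matrix(runif(n * d, 0, 10), ncol = d))
}

test_that("initialization is seeded and fits min-max scaling exactly", {
  x <- toy_inputs()
  m1 <- init_model(c(4, 6, 1), x, seed = 7)
  m2 <- init_model(c(4, 6, 1), x, seed = 7)
  m3 <- init_model(c(4, 6, 1), x, seed = 8)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)
  expect_false(identical(m1$weights, m3$weights))

  # scaling maps per-feature min to -1 and max to +1
  scaled_min <- vironet:::scale_inputs(m1, matrix(apply(x, 2, min), 1))
  scaled_max <- vironet:::scale_inputs(m1, matrix(apply(x, 2, max), 1))
  expect_equal(as.numeric(scaled_min), rep(-1, 4), tolerance = 1e-12)
  expect_equal(as.numeric(scaled_max), rep(1, 4), tolerance = 1e-12)

  xc <- cbind(x, 5)  # constant feature
  expect_warning(mc <- init_model(c(5, 3, 1), xc, seed = 1), "constant")
  expect_equal(vironet:::scale_inputs(mc, matrix(c(0, 0, 0, 0, 5), 1))[5], 5)
})

test_that("forward pass matches the closed forms and the loop oracle", {
  # all-zero parameters: output 0 everywhere
  x <- toy_inputs()
  m <- init_model(c(4, 6, 1), x, seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  m$biases <- lapply(m$biases, function(b) b * 0)
  expect_equal(forward(m, x), rep(0, nrow(x)))

  # 1-1-1 net with unit weights, zero biases, identity scaling
  m1 <- init_model(c(1, 1, 1), matrix(c(-1, 1), ncol = 1), seed = 1)
  m1$weights <- list(matrix(1), matrix(1))
  m1$biases <- list(0, 0)
  for (v in c(-0.7, 0, 0.3)) {
    expect_equal(forward(m1, v), tanh(tanh(v)), tolerance = 1e-15)
  }

  # random nets against an independently coded matrix/tanh oracle
  withr::with_seed(13, {
    for (sizes in list(c(4, 6, 1), c(4, 5, 3, 1))) {
      mm <- init_model(sizes, x, seed = sample.int(1000, 1))
      xt <- matrix(runif(10 * 4, 0, 10), ncol = 4)
      expect_equal(forward(mm, xt), oracle_forward(mm, xt),
                   tolerance = 1e-12)
      expect_true(all(abs(forward(mm, xt)) < 1))
    }
  })
  expect_error(forward(m, matrix(1, 2, 3)), "expects")
})

test_that("analytic Jacobian matches central finite differences", {
  x <- toy_inputs(n = 12)
  for (sizes in list(c(4, 3, 1), c(4, 3, 2, 1), c(1, 1, 1))) {
    xx <- if (sizes[1] == 1) matrix(seq(-1, 1, length.out = 8), ncol = 1)
          else x
    m <- init_model(sizes, xx, seed = 3)
    J <- vironet:::output_jacobian(m, xx)
    Jfd <- fd_jacobian(m, xx)
    expect_equal(dim(J), c(nrow(xx), vironet:::n_params(m)))
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-6)
  }
})

test_that("one near-Gauss-Newton step solves a linear-regime problem", {
  withr::with_seed(21, {
    x <- matrix(runif(60, -1, 1), ncol = 2)
    y <- runif(30, -0.1, 0.1)  # targets well inside the linear regime
  })
  m <- init_model(c(2, 3, 1), x, seed = 4)
  # moderate weights keep the Jacobian well conditioned while the small
  # targets keep the residual problem nearly linear
  theta0 <- vironet:::get_params(m) * 0.3
  m <- vironet:::set_params(m, theta0)

  # in the linear regime the layer-scaling symmetry makes the Jacobian
  # rank-deficient, so the damped problem is the well-posed one: the oracle
  # solves min ||e - J d||^2 + mu ||d||^2 by QR on the augmented system,
  # with a finite-difference Jacobian, independent of the analytic path
  mu <- 0.01
  step <- lm_step(m, x, y, mu)
  e <- y - forward(m, x)
  Jfd <- fd_jacobian(m, x)
  aug <- rbind(Jfd, sqrt(mu) * diag(ncol(Jfd)))
  delta_ls <- qr.solve(aug, c(e, numeric(ncol(Jfd))))
  expect_equal(vironet:::get_params(step$model), theta0 + delta_ls,
               tolerance = 1e-6)
  expect_lt(step$mse, mean(e^2))
})

test_that("early stopping counts equality as failure and keeps the best epoch", {
  scan <- vironet:::early_stop_scan(c(5, 4, 3, 3, 3, 3, 3, 3, 3),
                                    max_fail = 6)
  expect_equal(scan$stop_epoch, 9)  # 6th consecutive non-improvement
  expect_equal(scan$best_epoch, 3)

  # strict improvement resets the counter
  scan2 <- vironet:::early_stop_scan(c(5, 4, 4, 4, 3, 3, 3), max_fail = 3)
  expect_equal(scan2$stop_epoch, 7)
  expect_equal(scan2$best_epoch, 5)

  scan3 <- vironet:::early_stop_scan(c(3, 2, 1), max_fail = 6)
  expect_equal(scan3$stop_epoch, 3)
  expect_equal(scan3$best_epoch, 3)
})

test_that("training decreases MSE monotonically and returns best-val weights", {
  ds <- make_benchmark(separation = 0.4, n_per_class = 40, seed = 31)
  x <- ds$features; y <- ds$labels
  tr <- 1:60; va <- 61:80
  m <- init_model(c(20, 4, 1), x[tr, ], seed = 5)
  fit <- train_mlp(m, x[tr, ], y[tr], x[va, ], y[va], test_config())

  expect_true(all(diff(fit$trace$train_mse) < 0))
  expect_equal(length(fit$trace$train_mse), length(fit$trace$val_mse))
  # returned model is at least as good on validation as every recorded
  # epoch (the epoch-0 initial weights are eligible too)
  val_mse <- mean((y[va] - forward(fit$model, x[va, ]))^2)
  expect_lte(val_mse, min(fit$trace$val_mse) + 1e-12)
  if (fit$trace$best_epoch > 0) {
    expect_equal(val_mse, min(fit$trace$val_mse), tolerance = 1e-12)
  }
  if (fit$trace$stop_reason == "max_fail") {
    expect_equal(length(fit$trace$val_mse) - fit$trace$best_epoch, 6)
  }

  # determinism: identical data, seed, and config give an identical trace
  fit2 <- train_mlp(init_model(c(20, 4, 1), x[tr, ], seed = 5),
                    x[tr, ], y[tr], x[va, ], y[va], test_config())
  expect_identical(fit$trace$train_mse, fit2$trace$train_mse)
  expect_identical(fit$trace$val_mse, fit2$trace$val_mse)

  expect_error(train_mlp(m, x[tr, ], y[tr], x[0, , drop = FALSE],
                         numeric(0)),
               "validation")
})

test_that("a separable 20-sample toy set is fit to 100% training accuracy", {
  ds <- make_benchmark(separation = 0.8, n_per_class = 14, seed = 17)
  x <- ds$features; y <- ds$labels
  tr <- c(1:10, 15:24); va <- c(11:14, 25:28)
  m <- init_model(c(20, 4, 1), x[tr, ], seed = 2)
  fit <- train_mlp(m, x[tr, ], y[tr], x[va, ], y[va],
                   test_config(max_epochs = 200))
  pred <- ifelse(forward(fit$model, x[tr, ]) > 0, 1, -1)
  expect_equal(mean(pred == y[tr]), 1)
})

test_that("a small net separates a single zero-overlap feature (>=99%)", {
  accs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 200
      x <- matrix(runif(n * 20, 0, 10), ncol = 20)
      colnames(x) <- AA_CODES
      y <- rep(c(1, -1), each = n / 2)
      x[, 3] <- ifelse(y > 0, runif(n, 6, 9), runif(n, 1, 4))  # no overlap
      test_idx <- sample(n, 40)
    })
    rest <- setdiff(1:n, test_idx)
    va <- rest[1:30]; tr <- setdiff(rest, va)
    m <- init_model(c(20, 5, 1), x[tr, ], seed = s)
    fit <- train_mlp(m, x[tr, ], y[tr], x[va, ], y[va],
                     test_config(max_epochs = 60))
    mean(ifelse(forward(fit$model, x[test_idx, ]) > 0, 1, -1) == y[test_idx])
  }, numeric(1))
  expect_gte(mean(accs), 0.99)
})

test_that("models round-trip through JSON exactly and validate on load", {
  ds <- make_benchmark(separation = 0.3, n_per_class = 25, seed = 3,
                       include_pi = TRUE)
  x <- ds$features
  m <- init_model(c(21, 4, 1), x, seed = 11)
  fit <- train_mlp(m, x[1:35, ], ds$labels[1:35], x[36:50, ],
                   ds$labels[36:50], test_config(max_epochs = 10))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  probe <- x[sample(nrow(x), 30, replace = TRUE), ]
  expect_identical(forward(back, probe), forward(fit$model, probe))

  # tampering with a stored parameter is caught by the checksum
  txt <- readLines(path)
  tampered <- sub("\"checksum\":", "\"checksum\":1e9, \"x\":", txt)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(tampered, bad)
  expect_error(load_model(bad), "checksum|corrupted")

  # a 21-input (pI) model refuses 20-dimensional input
  expect_error(forward(back, x[, 1:20]), "expects 21")

  # wrong format refused
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), other)
  expect_error(load_model(other), "version|format|model file")
})
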