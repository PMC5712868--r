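# VPC rule and APC perceptron.

make_features <- function(qrs, rr_prev, rr_mean) {
  n <- length(qrs)
  data.frame(pr_interval = rep(0.16, n), qrs_duration = qrs,
             rr_prev = rr_prev, rr_next = rep(1, n),
             rr_mean_20 = rr_mean, rr_sd_20 = rep(0.02, n),
             r_amplitude = rep(1, n))
}

test_that("a wide premature beat among narrow beats is labeled V", {
  n <- 21
  qrs <- rep(0.08, n); qrs[11] <- 0.16
  rrp <- rep(1, n); rrp[11] <- 0.6
  f <- make_features(qrs, rrp, rep(1, n))
  f$rr_prev[1] <- NA
  beats <- beat_series(seq(0, by = 200, length.out = n), fs = 200)
  out <- classify_vpc(f, beats)
  expect_equal(out$labels[11], "V")
  expect_true(all(out$labels[-11] == "N"))
})

test_that("metronomic narrow beats yield zero V labels", {
  n <- 30
  f <- make_features(rep(0.08, n), rep(1, n), rep(1, n))
  beats <- beat_series(seq(0, by = 200, length.out = n), fs = 200)
  expect_false(any(classify_vpc(f, beats)$labels == "V"))
})

test_that("beats with undefined features are never labeled V", {
  n <- 11
  qrs <- rep(0.08, n); qrs[c(1, 6)] <- 0.2
  rrp <- rep(0.5, n); rrp[1] <- NA
  f <- make_features(qrs, rrp, rep(1, n))
  f$rr_mean_20[6] <- NA
  beats <- beat_series(seq(0, by = 200, length.out = n), fs = 200)
  out <- classify_vpc(f, beats)
  expect_equal(out$labels[1], "N")   # first beat, rr_prev undefined
  expect_equal(out$labels[6], "N")   # undefined neighborhood mean
})

test_that("VPC labeling is invariant to a uniform time shift", {
  n <- 15
  qrs <- rep(0.08, n); qrs[8] <- 0.17
  rrp <- rep(1, n); rrp[8] <- 0.5
  f <- make_features(qrs, rrp, rep(1, n))
  b1 <- beat_series(seq(0, by = 200, length.out = n), fs = 200)
  b2 <- beat_series(seq(5000, by = 200, length.out = n), fs = 200)
  expect_identical(classify_vpc(f, b1)$labels, classify_vpc(f, b2)$labels)
})

test_that("forward pass saturates and zeroes as the sigmoid dictates", {
  m0 <- mlp_model(W1 = matrix(0, 3, 4), b1 = rep(0, 4),
                  W2 = matrix(0, 4, 1), b2 = 0)
  expect_equal(mlp_forward(m0, c(1, 2, 3)), 0.5)
  m1 <- mlp_model(W1 = matrix(0, 3, 4), b1 = rep(0, 4),
                  W2 = matrix(0, 4, 1), b2 = 50)
  expect_gt(mlp_forward(m1, c(0, 0, 0)), 1 - 1e-9)
  expect_error(mlp_forward(m0, c(1, 2)), "features")
})

test_that("analytic gradients match central finite differences everywhere", {
  set.seed(31)
  m <- mlp_model(W1 = matrix(rnorm(3 * 5, sd = 0.5), 3, 5),
                 b1 = rnorm(5, sd = 0.2),
                 W2 = matrix(rnorm(5, sd = 0.5), 5, 1), b2 = 0.1)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c(0, 1), 4)
  w <- runif(8, 0.5, 2)
  g <- mlp_gradients(m, X, y, w)
  eps <- 1e-6
  rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
  worst <- 0
  perturb <- function(field, i, j = NULL) {
    up <- m; dn <- m
    if (is.null(j)) { up[[field]][i] <- up[[field]][i] + eps
                      dn[[field]][i] <- dn[[field]][i] - eps }
    else { up[[field]][i, j] <- up[[field]][i, j] + eps
           dn[[field]][i, j] <- dn[[field]][i, j] - eps }
    (mlp_gradients(up, X, y, w)$loss - mlp_gradients(dn, X, y, w)$loss) /
      (2 * eps)
  }
  for (i in 1:3) for (j in 1:5)
    worst <- max(worst, rel_err(g$gW1[i, j], perturb("W1", i, j)))
  for (i in 1:5) {
    worst <- max(worst, rel_err(g$gb1[i], perturb("b1", i)))
    worst <- max(worst, rel_err(g$gW2[i, 1], perturb("W2", i, 1)))
  }
  worst <- max(worst, rel_err(g$gb2, perturb("b2", 1)))
  expect_lt(worst, 1e-4)
})

gaussian_clouds <- function(n_per, sep_sd = 4, p = 7, seed = 42) {
  set.seed(seed)
  shift <- sep_sd / sqrt(p)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = shift), n_per, p))
  list(X = X, y = rep(c("N", "S"), each = n_per))
}

test_that("training separates 4-SD Gaussian clouds at 95%+ held-out accuracy", {
  d <- gaussian_clouds(300)
  fit <- train_apc_mlp(d$X, d$y, seed = 9)
  expect_gte(fit$report$test_accuracy, 0.95)
  # independent cross-check: an off-the-shelf single-hidden-layer net
  # separates the same data comparably
  skip_if_not_installed("nnet")
  nn <- nnet::nnet(d$X, as.numeric(d$y == "S"), size = 10, trace = FALSE,
                   maxit = 200)
  expect_gte(mean((predict(nn, d$X) >= 0.5) == (d$y == "S")), 0.95)
})

test_that("permuted labels give chance-level held-out accuracy", {
  d <- gaussian_clouds(300)
  set.seed(7)
  fit <- train_apc_mlp(d$X, sample(d$y), seed = 9)
  expect_gt(fit$report$test_accuracy, 0.40)
  expect_lt(fit$report$test_accuracy, 0.60)
})

test_that("training is bitwise reproducible for a fixed seed", {
  d <- gaussian_clouds(60)
  f1 <- train_apc_mlp(d$X, d$y, seed = 5)
  f2 <- train_apc_mlp(d$X, d$y, seed = 5)
  expect_identical(f1$model$W1, f2$model$W1)
  expect_identical(f1$model$W2, f2$model$W2)
  expect_identical(f1$report$epochs_run, f2$report$epochs_run)
})

test_that("training loss is non-increasing under plain gradient descent", {
  d <- gaussian_clouds(100)
  cfg <- mlp_config()
  cfg$momentum <- 0; cfg$lr <- 0.05; cfg$max_epochs <- 100L
  fit <- train_apc_mlp(d$X, d$y, config = cfg, seed = 3)
  hist <- fit$report$loss_history
  expect_gt(length(hist), 5L)
  expect_true(all(diff(hist) <= 1e-10))
})

test_that("single-class training is refused", {
  d <- gaussian_clouds(30)
  expect_error(train_apc_mlp(d$X, rep("N", nrow(d$X)), seed = 1),
               "one class")
})

test_that("APC labeling respects the V-precedence and tie rules", {
  d <- gaussian_clouds(60)
  fit <- train_apc_mlp(d$X, d$y, seed = 5)
  # force known probabilities via a degenerate model
  m <- mlp_model(W1 = matrix(0, 7, 2), b1 = c(0, 0),
                 W2 = matrix(0, 2, 1), b2 = 0)  # prob exactly 0.5
  f <- as.data.frame(matrix(0, 3, 7))
  beats <- beat_series(c(0, 200, 400), fs = 200,
                       labels = c("V", "N", "unknown"))
  out <- classify_apc(m, f, beats)
  expect_equal(out$labels, c("V", "S", "S"))  # V kept; 0.5 ties to S
  m_lo <- mlp_model(W1 = matrix(0, 7, 2), b1 = c(0, 0),
                    W2 = matrix(0, 2, 1), b2 = -0.1)  # prob < 0.5
  out2 <- classify_apc(m_lo, f, beats)
  expect_equal(out2$labels, c("V", "N", "N"))
  expect_true(inherits(fit$model, "mlp_model"))
})

test_that("model JSON persistence round trips exactly", {
  td <- withr::local_tempdir()
  d <- gaussian_clouds(60)
  fit <- train_apc_mlp(d$X, d$y, seed = 5)
  p <- file.path(td, "m.json")
  save_mlp_json(fit$model, p)
  back <- load_mlp_json(p)
  x <- rnorm(7)
  expect_equal(back$n_in, fit$model$n_in)
  expect_equal(mlp_forward(back, x), mlp_forward(fit$model, x),
               tolerance = 1e-12)
})
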