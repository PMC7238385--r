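test_that("feature scaling maps the training range onto [-1, 1]", {
  sc <- fit_feature_scaler(matrix(c(0, 5, 10), ncol = 1))
  expect_equal(as.numeric(apply_feature_scaler(sc, matrix(c(0, 5, 10)))),
               c(-1, 0, 1))
  # out-of-range values extrapolate linearly
  expect_equal(as.numeric(apply_feature_scaler(sc, matrix(12))), 1.4)
  # constant columns collapse to zero with a warning
  sc2 <- fit_feature_scaler(matrix(c(3, 3, 3), ncol = 1))
  expect_warning(out <- apply_feature_scaler(sc2, matrix(c(3, 4))), "constant")
  expect_equal(as.numeric(out), c(0, 0))
})

test_that("weight initialization is seeded and correctly shaped", {
  w1 <- init_mlp(1)
  w2 <- init_mlp(1)
  expect_identical(w1, w2)
  expect_false(identical(w1, init_mlp(2)))
  expect_equal(dim(w1$W1), c(10L, 10L))
  expect_length(w1$Bias1, 10L)
  expect_equal(dim(w1$W2), c(1L, 10L))
  expect_length(w1$Bias2, 1L)
  expect_true(all(abs(unlist(w1)) <= 0.5))
})

test_that("prediction applies the 0.5 decision threshold", {
  w <- init_mlp(1)
  w$W1[] <- 0; w$Bias1[] <- 0; w$W2[] <- 0; w$Bias2 <- 0
  fit <- structure(list(weights = w, scaler = NULL, n_in = 10L),
                   class = "pcg_mlp")
  x <- matrix(rnorm(10), 1)
  expect_equal(predict(fit, x, type = "score"), 0)
  expect_equal(predict(fit, x), 0)           # score 0 -> class 0
  fit$weights$Bias2 <- 0.5
  expect_equal(predict(fit, x), 0)           # exactly 0.5 -> class 0
  fit$weights$Bias2 <- 0.7
  expect_equal(predict(fit, x), 1)           # bias-only forward pass
  expect_error(predict(fit, matrix(c(NA, rnorm(9)), 1)), "non-finite")
})

test_that("Levenberg-Marquardt reaches a separable toy set's floor", {
  toy <- make_toy_clusters(n_per = 10, sep = 4, seed = 5)
  fit <- pcg_mlp(toy$x, toy$y, control = mlp_control(seed = 2))
  expect_lte(fit$mse, 1e-3)
  expect_lte(fit$iterations, 1000L)
  # the training trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 1e-12))
  # independent-optimizer oracle: BFGS from the same start must not beat the
  # damped Gauss-Newton fit on this convex-enough problem
  sc <- fit_feature_scaler(toy$x)
  xs <- apply_feature_scaler(sc, toy$x)
  w0 <- init_mlp(2)
  theta0 <- c(as.numeric(w0$W1), w0$Bias1, as.numeric(w0$W2), w0$Bias2)
  obj <- function(th) {
    W1 <- matrix(th[1:100], 10, 10); b1 <- th[101:110]
    W2 <- th[111:120]; b2 <- th[121]
    pred <- as.numeric(tanh(sweep(xs %*% t(W1), 2, b1, `+`)) %*% W2) + b2
    mean((pred - toy$y)^2)
  }
  bfgs <- stats::optim(theta0, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-12))
  expect_lte(fit$mse, max(bfgs$value, 1e-3))
})

test_that("degenerate targets and fixed seeds behave deterministically", {
  set.seed(30)
  x <- matrix(rnorm(200), 20)
  y1 <- rep(1, 20)
  # constant targets: the network converges to the constant
  fit <- suppressWarnings(pcg_mlp(x, y1, control = mlp_control(seed = 4)))
  expect_lt(fit$mse, 1e-6 + 1e-9)
  expect_true(all(abs(fit$fitted_scores - 1) < 0.01))
  # identical seed and data reproduce the exact training trace
  y2 <- rep(c(0, 1), 10)
  f1 <- pcg_mlp(x, y2, control = mlp_control(seed = 6, max_iter = 60))
  f2 <- pcg_mlp(x, y2, control = mlp_control(seed = 6, max_iter = 60))
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
})

test_that("confusion metrics follow their defining ratios", {
  m <- classification_metrics(tp = 58, fp = 2, tn = 22, fn = 4)
  expect_equal(round(unname(m), 1), c(93.0, 93.5, 91.7))
  expect_equal(unname(classification_metrics(5, 5, 5, 5)),
               c(50, 50, 50))
  expect_equal(unname(classification_metrics(10, 0, 10, 0)),
               c(100, 100, 100))
  expect_warning(m0 <- classification_metrics(0, 0, 5, 0), "sensitivity")
  expect_true(is.na(m0["sensitivity"]))
  expect_error(classification_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("jack-knife trains one network per sample and recovers labels", {
  toy <- make_toy_clusters(n_per = 8, sep = 7, seed = 21)
  jk <- pcg_jackknife(toy$x, toy$y, control = mlp_control(seed = 9))
  expect_equal(jk$n_models, 16L)
  expect_length(jk$score, 16L)
  expect_equal(sum(jk$confusion), 16)
  # strong separation: every held-out sample classified correctly
  expect_gte(jk$metrics[["accuracy"]], 95)
  # metrics agree with a brute-force count over the per-sample predictions
  expect_equal(unname(jk$confusion["tp"]), sum(jk$label == 1 & jk$truth == 1))
  expect_equal(unname(jk$confusion["tn"]), sum(jk$label == 0 & jk$truth == 0))
  # bit-for-bit reproducibility at the label level
  jk2 <- pcg_jackknife(toy$x, toy$y, control = mlp_control(seed = 9))
  expect_identical(jk$label, jk2$label)
  expect_error(pcg_jackknife(toy$x, rep(1, 16)), "both classes")
})

test_that("folds that lose a class are trained anyway and flagged", {
  set.seed(77)
  x <- matrix(rnorm(90), 9)
  x[1, ] <- x[1, ] + 5
  y <- c(1, rep(0, 8))  # leaving out sample 1 leaves a single class
  jk <- suppressWarnings(pcg_jackknife(x, y, control = mlp_control(seed = 3,
                                                                  max_iter = 50)))
  expect_equal(jk$single_class_folds, 1L)
  expect_equal(jk$n_models, 9L)
})
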