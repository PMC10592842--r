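test_that("model builds with seeded, reproducible parameters", {
  m1 <- tiny_model(seed = 3L)
  m2 <- tiny_model(seed = 3L)
  expect_identical(fibertrace:::net_get_params(m1$ptr),
                   fibertrace:::net_get_params(m2$ptr))
  m3 <- tiny_model(seed = 4L)
  expect_false(identical(fibertrace:::net_get_params(m1$ptr),
                         fibertrace:::net_get_params(m3$ptr)))
})

test_that("segmentation output is a probability map of the input shape", {
  m <- tiny_model()
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- forward_seg(m, x)
  expect_equal(dim(p), c(64, 64, 2))
  expect_true(all(p >= 0 & p <= 1))
  # two-class softmax: background + fiber channels sum to one
  # (engine computes in single precision)
  raw <- fibertrace:::net_forward_seg(m$ptr, x, FALSE)
  expect_lt(max(abs(raw[, , 1, ] + raw[, , 2, ] - 1)), 1e-6)
  # eval mode is deterministic
  expect_identical(p, forward_seg(m, x))
  # config errors
  expect_error(forward_seg(m, array(0.5, c(30, 30, 3, 1))),
               class = "ft_validation_error")
  expect_error(model_config(depth = 3, patch_size = 100),
               class = "ft_validation_error")
})

test_that("classification arm yields 2 logits and the fc embedding", {
  m <- tiny_model(patch = 64L)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  fc <- forward_class(m, x)
  expect_equal(dim(fc$logits), c(3, 2))
  expect_equal(dim(fc$embedding), c(3, 32))  # configured fc2 size
  expect_identical(fc, forward_class(m, x))
  expect_error(forward_class(m, array(0.5, c(32, 32, 3, 1))),
               class = "ft_validation_error")
})

test_that("a tiny model overfits one repeated patch quickly", {
  m <- tiny_model(seed = 1L)
  set.seed(10)
  x1 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  x <- array(rep(x1, 4), c(64, 64, 3, 4))
  y <- array(0, c(64, 64, 4)); y[20:44, 20:44, ] <- 1
  loss <- NA
  for (s in 1:200) {
    r <- fibertrace:::net_train_step(m$ptr, x, y, 0.25, 2, TRUE, NULL, 0.5,
                                     1, NULL, NULL, 0, 1e-3, TRUE)
    loss <- r$loss_seg
    if (loss < 0.01) break
  }
  expect_lt(loss, 0.01)
})

test_that("losses through the classification arm reach the shared encoder", {
  m <- tiny_model(patch = 64L)
  xc <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  lg <- fibertrace:::net_loss_and_grad(m$ptr, NULL, NULL, 0.25, 2, TRUE,
                                       xc, 0.5, 1.0)
  # first encoder convolution parameters receive gradient
  n_first <- 9 * 3 * 8
  expect_gt(max(abs(lg$grad[seq_len(n_first)])), 0)
})

test_that("analytic gradients match finite differences", {
  m <- build_model(model_config(depth = 2L, base_channels = 4L,
                                fc_sizes = c(8L, 6L), patch_size = 16L,
                                seed = 42L))
  set.seed(4)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  xc <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  lg <- fibertrace:::net_loss_and_grad(m$ptr, x, y, 0.25, 2, TRUE, xc, 0.5, 1)
  th0 <- fibertrace:::net_get_params(m$ptr)
  # per-coordinate central differences; the engine is single precision,
  # so loss evaluations carry ~1e-6 relative noise and coordinates with
  # near-zero gradients are excluded from the strict comparison
  idx <- sort(sample(length(th0), 60))
  eps <- 1e-3
  rel <- vapply(idx, function(i) {
    th <- th0; th[i] <- th0[i] + eps
    fibertrace:::net_set_params(m$ptr, th)
    lp <- fibertrace:::net_loss_only(m$ptr, x, y, 0.25, 2, TRUE, xc, 0.5, 1)
    th[i] <- th0[i] - eps
    fibertrace:::net_set_params(m$ptr, th)
    lm <- fibertrace:::net_loss_only(m$ptr, x, y, 0.25, 2, TRUE, xc, 0.5, 1)
    fd <- (lp - lm) / (2 * eps)
    abs(fd - lg$grad[i]) / max(1e-6, abs(fd) + abs(lg$grad[i]))
  }, numeric(1))
  fibertrace:::net_set_params(m$ptr, th0)
  expect_lt(median(rel), 0.01)
  # directional derivatives aggregate the whole gradient and are robust
  # to single-coordinate noise
  set.seed(5)
  for (k in 1:3) {
    v <- rnorm(length(th0)); v <- v / sqrt(sum(v^2))
    de <- 5e-2
    fibertrace:::net_set_params(m$ptr, th0 + de * v)
    lp <- fibertrace:::net_loss_only(m$ptr, x, y, 0.25, 2, TRUE, xc, 0.5, 1)
    fibertrace:::net_set_params(m$ptr, th0 - de * v)
    lm <- fibertrace:::net_loss_only(m$ptr, x, y, 0.25, 2, TRUE, xc, 0.5, 1)
    fd <- (lp - lm) / (2 * de)
    an <- sum(lg$grad * v)
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 0.15)
    fibertrace:::net_set_params(m$ptr, th0)
  }
})

test_that("checkpoints round-trip parameters, stats and epoch", {
  m <- tiny_model()
  # perturb state so defaults are not what is tested
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- array(rbinom(64 * 64 * 2, 1, 0.2), c(64, 64, 2))
  fibertrace:::net_train_step(m$ptr, x, y, 0.25, 2, TRUE, NULL, 0.5, 1,
                              NULL, NULL, 0, 1e-3, TRUE)
  m$epoch <- 5L
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(fibertrace:::net_get_params(m2$ptr),
                   fibertrace:::net_get_params(m$ptr))
  expect_identical(fibertrace:::net_get_bn_stats(m2$ptr),
                   fibertrace:::net_get_bn_stats(m$ptr))
  expect_equal(m2$epoch, 5L)
  p1 <- forward_seg(m, x)
  p2 <- forward_seg(m2, x)
  expect_identical(p1, p2)
})
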