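toy_saliency_model <- function(seed = 50L, conv2_filters = 2L) {
  stage1_init(stage1_config(conv1_filters = 3L, conv1_kernel = 3L,
                            conv2_filters = conv2_filters,
                            conv2_kernel = 3L,
                            dense_widths = c(8L, 5L, 2L), seed = seed),
              tiny_input_dim)
}

test_that("Grad-CAM localises the target logit's evidence", {
  m <- toy_saliency_model()
  set.seed(51)
  x <- matrix(rnorm(prod(tiny_input_dim)), tiny_input_dim[1])
  h <- encode_task_hint("Rest1")
  sal <- gradcam(m, x, h, "PD")
  expect_identical(dim(sal$weights), tiny_input_dim)
  expect_true(all(sal$weights >= 0 & sal$weights <= 1))
  # constant logit (zero output weights) -> all-zero map, flagged
  m0 <- m
  m0$params$W5[] <- 0
  sal0 <- gradcam(m0, x, h, "PD")
  expect_true(sal0$degenerate)
  expect_true(all(sal0$weights == 0))
  # the maps depend only on the discriminative direction: adding the
  # same vector to both output columns (a pure common mode) changes
  # neither class's map
  m2 <- m
  shift <- rnorm(nrow(m2$params$W5))
  m2$params$W5 <- m2$params$W5 + cbind(shift, shift)
  expect_equal(gradcam(m, x, h, "PD")$weights,
               gradcam(m2, x, h, "PD")$weights, tolerance = 1e-12)
  expect_equal(gradcam(m, x, h, "ET")$weights,
               gradcam(m2, x, h, "ET")$weights, tolerance = 1e-12)
  # single conv-2 channel: the map is the rectified feature map scaled
  # by its mean gradient (up to upsampling and normalisation)
  m1 <- toy_saliency_model(seed = 52L, conv2_filters = 1L)
  cf <- tremorid:::conv_forward(m1, x, keep = TRUE)
  fw <- tremorid:::dense_forward(m1, matrix(cf$flat, 1), matrix(h, 1))
  fw$Fm <- matrix(cf$flat, 1)
  bk <- tremorid:::dense_backward(m1, fw, matrix(c(1, -1), 1))
  dA2 <- tremorid:::conv2_activation_grad(m1, cf, bk$dFm[1, ])
  w <- mean(dA2)
  cam <- pmax(w * cf$A2[, , 1], 0)
  up <- tremorid:::bilinear_upsample(cam, tiny_input_dim[1],
                                     tiny_input_dim[2])
  want <- if (max(up) > 0) (up - min(up)) / (max(up) - min(up)) else up
  expect_equal(gradcam(m1, x, h, "PD")$weights, want, tolerance = 1e-12)
})

test_that("dense-head saliency gradients match finite differences", {
  m <- toy_saliency_model(seed = 53L)
  set.seed(54)
  x <- matrix(rnorm(prod(tiny_input_dim)), tiny_input_dim[1])
  h <- encode_task_hint("Posture2")
  cf <- tremorid:::conv_forward(m, x, keep = TRUE)
  fw <- tremorid:::dense_forward(m, matrix(cf$flat, 1), matrix(h, 1))
  fw$Fm <- matrix(cf$flat, 1)
  bk <- tremorid:::dense_backward(m, fw, matrix(c(1, 0), 1))
  logit1 <- function(flat) {
    f <- tremorid:::dense_forward(m, matrix(flat, 1), matrix(h, 1))
    f$Z5[1, 1]
  }
  eps <- 1e-6
  for (i in c(1L, 20L, length(cf$flat))) {
    fp <- cf$flat; fp[i] <- fp[i] + eps
    fm <- cf$flat; fm[i] <- fm[i] - eps
    fd <- (logit1(fp) - logit1(fm)) / (2 * eps)
    expect_equal(bk$dFm[1, i], fd, tolerance = 1e-5)
  }
  # unpooling routes gradients to the argmax positions exactly
  X <- array(c(4, 1, 2, 3, 0, 0, 0, 5), dim = c(2L, 2L, 2L))
  pl <- tremorid:::cpp_maxpool(X, 2L)
  g <- array(c(7, 9), dim = c(1L, 1L, 2L))
  back <- tremorid:::cpp_maxpool_bwd(g, pl$argmax, 2L, 2L)
  expect_equal(back[, , 1], matrix(c(7, 0, 0, 0), 2), tolerance = 0)
  expect_equal(back[, , 2], matrix(c(0, 0, 0, 9), 2), tolerance = 0)
})

test_that("group statistics stream exactly", {
  set.seed(55)
  maps <- lapply(1:7, function(i) matrix(runif(12), 3, 4))
  st <- group_saliency_stats(maps)
  expect_identical(st$n, 7)
  # two-pass oracle
  arr <- simplify2array(maps)
  expect_equal(st$mean, apply(arr, c(1, 2), mean), tolerance = 1e-10)
  expect_equal(st$variance, apply(arr, c(1, 2), stats::var),
               tolerance = 1e-10)
  same <- group_saliency_stats(rep(maps[1], 3))
  expect_true(all(same$variance == 0))
  expect_error(group_saliency_stats(maps[1]), "at least 2")
})

test_that("the pixel-wise z grid matches the two-sample z oracle", {
  mk <- function(mean, var, n) {
    structure(list(mean = matrix(mean, 2, 2), variance = matrix(var, 2, 2),
                   n = n), class = "group_saliency_stats")
  }
  z <- pixelwise_z(mk(0.6, 0.01, 100), mk(0.4, 0.01, 100))
  # 0.2 / sqrt(0.0002) = 10 * sqrt(2)
  expect_equal(z[1, 1], 10 * sqrt(2), tolerance = 1e-12)
  expect_true(all(z == z[1, 1]))
  # antisymmetry and the identical-group null
  a <- mk(0.5, 0.02, 40); b <- mk(0.3, 0.05, 25)
  expect_equal(pixelwise_z(a, b), -pixelwise_z(b, a), ignore_attr = TRUE)
  expect_true(all(pixelwise_z(a, a) == 0))
  z0 <- pixelwise_z(mk(0.5, 0, 10), mk(0.5, 0, 10))
  expect_true(all(z0 == 0))
  expect_identical(attr(z0, "zero_variance"), 4L)
  expect_error(pixelwise_z(a, structure(list(mean = matrix(0, 3, 3),
                                             variance = matrix(1, 3, 3),
                                             n = 5),
                                        class = "group_saliency_stats")),
               "shape")
})

test_that("significance masks follow the normal-CDF thresholds", {
  z0 <- matrix(0, 4, 4)
  m0 <- significance_masks(z0)
  expect_false(any(m0$et_mask))
  expect_false(any(m0$pd_mask))
  z3 <- matrix(3, 4, 4)
  m3 <- significance_masks(z3)  # Phi(3) = 0.9987 > 0.99
  expect_true(all(m3$et_mask))
  expect_false(any(m3$pd_mask))
  set.seed(56)
  zr <- matrix(rnorm(400, sd = 3), 20, 20)
  mr <- significance_masks(zr, mean_et = matrix(1, 20, 20),
                           mean_pd = matrix(1, 20, 20))
  expect_false(any(mr$et_mask & mr$pd_mask))
  expect_true(all(mr$masked_mean_et[!mr$et_mask] == 0))
  # tightening the threshold never adds pixels
  tight <- significance_masks(zr, alpha = 0.002)
  expect_true(all(!tight$et_mask | mr$et_mask))
  expect_true(all(!tight$pd_mask | mr$pd_mask))
  expect_error(significance_masks(zr, alpha = 1.5), "alpha")
})

test_that("the K^2 statistic matches an external reference value", {
  # frozen oracle computed with an independent implementation of the
  # D'Agostino-Pearson omnibus test (scipy.stats.normaltest)
  x <- c(0.001230153357, 0.2987455375, -0.2741378554, -0.8905918388,
         -0.4546707852, -0.991646555, 0.0601436026, 1.340215246,
         -0.4922065186, -0.6204748998, 0.4898420502, 0.3568870082,
         0.105414249, -0.9304680447, -0.02925182246, 0.6953031945,
         -1.344214547, -0.457615761, -1.90122274, -1.28953774)
  r <- dagostino_pearson(matrix(x, ncol = 1))
  expect_equal(r$statistic, 0.0511897247, tolerance = 1e-8)
  expect_equal(r$p_value, 0.9747299094, tolerance = 1e-8)
})

test_that("the normality gate is calibrated and detects heavy tails", {
  set.seed(57)
  gauss <- lapply(1:80, function(i) matrix(rnorm(15 * 15), 15, 15))
  p <- normality_gate(gauss)
  rate <- mean(p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
  heavy <- lapply(1:80, function(i)
    matrix(stats::rt(15 * 15, df = 2), 15, 15))
  expect_gt(mean(normality_gate(heavy) < 0.05, na.rm = TRUE), 0.5)
  # constant pixels are skipped, small groups refuse the test
  const <- lapply(1:30, function(i) matrix(1, 2, 2))
  pc <- normality_gate(const)
  expect_true(all(is.na(pc)))
  expect_identical(attr(pc, "n_skipped"), 4L)
  expect_warning(out <- normality_gate(gauss[1:5]), "skipped")
  expect_null(out)
})
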