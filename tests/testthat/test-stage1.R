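test_that("task hints are one-hot at the fixed index", {
  expect_identical(encode_task_hint("Rest1"), c(1, 0, 0, 0, 0, 0))
  expect_identical(encode_task_hint("Load2"), c(0, 0, 0, 0, 0, 1))
  for (task in included_tasks()) {
    h <- encode_task_hint(task)
    expect_identical(sum(h), 1)
    expect_identical(which(h == 1) - 1L, task_hint_index(task))
  }
  expect_error(encode_task_hint("FingerToNose"), "excluded")
})

test_that("forward pass is a deterministic softmax pair", {
  m <- stage1_init(tiny_cnn_config(), tiny_input_dim)
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(rnorm(prod(tiny_input_dim)), tiny_input_dim[1])
    p <- stage1_forward(m, x, encode_task_hint("Posture1"))
    expect_true(all(p > 0 & p < 1))
    expect_lt(abs(sum(p) - 1), 1e-6)
    expect_identical(p, stage1_forward(m, x, encode_task_hint("Posture1")))
  }
  # symmetric logits from a zeroed output layer
  m0 <- m
  m0$params$W5[] <- 0
  m0$params$b5[] <- 0
  p <- stage1_forward(m0, x, encode_task_hint("Rest1"))
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_error(stage1_forward(m, x[-1, ], encode_task_hint("Rest1")),
               "shape")
  expect_error(stage1_forward(m, x, c(1, 1, 0, 0, 0, 0)), "one-hot")
})

test_that("hint bits contribute exactly their weight columns", {
  # with a linear second dense activation the logit difference between
  # two hints is exactly (e_a - e_b)' W4[hint rows, ] W5
  cfg <- tiny_cnn_config(leaky_slope = 1)
  m <- stage1_init(cfg, tiny_input_dim)
  set.seed(4)
  x <- matrix(rnorm(prod(tiny_input_dim)), tiny_input_dim[1])
  logits <- function(hint) {
    cf <- tremorid:::conv_forward(m, x)
    fw <- tremorid:::dense_forward(m, matrix(cf$flat, 1), matrix(hint, 1))
    as.numeric(fw$Z5)
  }
  d1 <- m$config$dense_widths[1]
  ha <- encode_task_hint("Rest1"); hb <- encode_task_hint("Load2")
  got <- logits(ha) - logits(hb)
  want <- as.numeric((ha - hb) %*% m$params$W4[d1 + 1:6, ] %*%
                       m$params$W5)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_cnn_config()
  m <- stage1_init(cfg, tiny_input_dim)
  set.seed(5)
  x <- matrix(rnorm(prod(tiny_input_dim)), tiny_input_dim[1])
  hint <- encode_task_hint("Rest2")
  y <- c(1, 0)
  loss <- function(mm, xx = x) {
    cf <- tremorid:::conv_forward(mm, xx)
    fw <- tremorid:::dense_forward(mm, matrix(cf$flat, 1), matrix(hint, 1))
    -sum(y * log(fw$P))
  }
  cf <- tremorid:::conv_forward(m, x, keep = TRUE)
  fw <- tremorid:::dense_forward(m, matrix(cf$flat, 1), matrix(hint, 1))
  fw$Fm <- matrix(cf$flat, 1)
  bk <- tremorid:::dense_backward(m, fw, fw$P - matrix(y, 1))
  cg <- tremorid:::conv_backward(m, x, bk$dFm[1, ], input_grad = TRUE)
  grads <- c(bk$grads, cg[c("W1", "b1", "W2", "b2")])
  eps <- 1e-6
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (i in unique(pmin(length(g), c(1L, 3L, length(g))))) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      fd <- (loss(mp) - loss(mm)) / (2 * eps)
      expect_equal(as.numeric(g[i]), fd, tolerance = 1e-5)
    }
  }
  for (i in c(1L, 77L, 311L)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (loss(m, xp) - loss(m, xm)) / (2 * eps)
    expect_equal(cg$dX[i], fd, tolerance = 1e-5)
  }
})

test_that("training runs the configured epochs and learns", {
  samples <- random_tiny_samples(48L, seed = 6L)
  cfg <- tiny_cnn_config(epochs = 3L, learning_rate = 1e-3)
  m <- train_stage1(samples, cfg, tiny_input_dim)
  expect_identical(nrow(m$training_log), 3L)
  expect_lte(m$training_log$loss[3], m$training_log$loss[1])
  # zero learning rate leaves the parameters at initialisation
  m0 <- train_stage1(samples, tiny_cnn_config(epochs = 2L,
                                              learning_rate = 0),
                     tiny_input_dim)
  init <- stage1_init(tiny_cnn_config(epochs = 2L, learning_rate = 0),
                      tiny_input_dim)
  expect_equal(m0$params, init$params, tolerance = 1e-15)
  # single-class input is rejected
  one_class <- Filter(function(s) s$label == "PD", samples)
  expect_error(train_stage1(one_class, cfg, tiny_input_dim), "both classes")
  # seeded training is reproducible
  m2 <- train_stage1(samples, cfg, tiny_input_dim)
  expect_identical(m$params, m2$params)
})

test_that("cross-validation folds partition patients", {
  folds <- tremorid:::patient_folds(sprintf("P%02d", 1:10), 5L, seed = 2L)
  expect_length(folds, 5L)
  expect_true(all(lengths(folds) == 2L))
  expect_setequal(unlist(folds), sprintf("P%02d", 1:10))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0L)
  }
  expect_error(tremorid:::patient_folds(c("a", "b"), 5L, 1L), "exceeds")

  samples <- random_tiny_samples(32L, seed = 8L)
  cv <- crossvalidate_stage1(samples, tiny_cnn_config(epochs = 2L,
                                                      learning_rate = 1e-3),
                             k = 4L, input_dim = tiny_input_dim)
  expect_length(cv$fold_accuracy, 4L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  pids <- unique(vapply(samples, `[[`, character(1), "patient_id"))
  expect_setequal(unlist(cv$folds), pids)
})

test_that("checkpoints round-trip bit-identically and are versioned", {
  m <- stage1_init(stage1_config(), c(129L, 191L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_stage1(m, path)
  m2 <- load_stage1(path)
  expect_identical(m2$config$epochs, 44L)
  expect_identical(m2$config$learning_rate, 1e-4)
  set.seed(10)
  x <- matrix(rnorm(129 * 191), 129)
  h <- encode_task_hint("Load1")
  expect_identical(stage1_forward(m, x, h), stage1_forward(m2, x, h))
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_stage1(bad), "corrupted")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_stage1(other), "version")
})
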