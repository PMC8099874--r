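test_that("feature slots follow the canonical trial/task/axis order", {
  # independent enumeration oracle over all 54 tuples
  i <- 0L
  for (trial in 1:3) for (task in included_tasks()) for (axis in c("x", "y", "z")) {
    expect_identical(feature_index(trial, task, axis), i)
    i <- i + 1L
  }
  expect_identical(feature_index(2L, "Posture1", "z"), 26L)
  expect_identical(feature_label(2L, "Posture1", "z"), "2-Posture1-z")
  ord <- feature_order()
  expect_identical(nrow(ord), 54L)
  expect_identical(ord$index, 0:53)
})

test_that("assembled features carry stage-1 votes in order", {
  cohort <- small_cohort(n_pd = 1L, n_et = 0L, seed = 13L)
  a <- assemble_assessments(cohort)[[1]]
  m <- stage1_init(stage1_config())
  m$params$W5[] <- 0
  m$params$b5[] <- 0
  f <- assemble_features(a, m, mode = "probabilistic")
  expect_length(f, 54L)
  expect_true(all(f == 0.5))
  fb <- assemble_features(a, m, mode = "binary")
  expect_true(all(fb == 0))  # p = 0.5 is not > 0.5
  expect_identical(names(f), feature_order()$label)
  a53 <- a
  a53$signals <- a53$signals[-1]
  expect_error(assemble_features(a53, m), "incomplete")
})

test_that("QDA fitting matches the textbook covariance", {
  set.seed(20)
  X <- matrix(rnorm(60 * 4), 60, 4)
  labels <- rep(c("PD", "ET"), each = 30L)
  X[labels == "PD", ] <- X[labels == "PD", ] + 1
  fit <- fit_qda(X, labels, shrinkage = 0)
  Xp <- X[labels == "PD", ]
  Xc <- sweep(Xp, 2L, colMeans(Xp))
  S <- crossprod(Xc) / (nrow(Xp) - 1L)
  eps <- 1e-6 * mean(diag(S))
  expect_equal(fit$mu_pd, colMeans(Xp), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$sigma_pd, S + diag(eps, 4), tolerance = 1e-10)
  expect_true(all(eigen(fit$sigma_pd, only.values = TRUE)$values > 0))
  # zero-variance class: identical vectors per class, full shrinkage
  X2 <- rbind(matrix(1, 2, 3), matrix(0, 2, 3))
  l2 <- c("PD", "PD", "ET", "ET")
  fit2 <- fit_qda(X2, l2, shrinkage = 1)
  expect_equal(as.numeric(fit2$mu_pd), rep(1, 3))
  expect_true(all(diag(fit2$sigma_pd) > 0))
  expect_true(all(fit2$sigma_pd[upper.tri(fit2$sigma_pd)] == 0))
  expect_error(fit_qda(X2[-1, ], l2[-1]), "at least 2")
})

test_that("the likelihood ratio equals the Gaussian density ratio oracle", {
  # closed form: mu_PD = (1,0), mu_ET = (0,0), identity covariances
  toy <- structure(list(mu_pd = c(1, 0), mu_et = c(0, 0),
                        sigma_pd = diag(2), sigma_et = diag(2),
                        shrinkage = 0, priors = c(PD = .5, ET = .5),
                        d = 2L, kind = "qda"), class = "qda_model")
  expect_equal(qda_likelihood_ratio(toy, c(1, 0)), exp(0.5),
               tolerance = 1e-12)
  # identical class densities give ratio 1 everywhere
  same <- toy; same$mu_pd <- c(0, 0)
  for (i in 1:5) {
    expect_equal(qda_likelihood_ratio(same, rnorm(2)), 1, tolerance = 1e-12)
  }
  # density-ratio identity against the naive solve/det oracle
  model <- structure(list(mu_pd = c(0.2, -0.1, 0.4), mu_et = c(-0.3, 0, 0.1),
                          sigma_pd = random_spd(3, 1),
                          sigma_et = random_spd(3, 2),
                          shrinkage = 0, priors = c(PD = .5, ET = .5),
                          d = 3L, kind = "qda"), class = "qda_model")
  set.seed(21)
  for (i in 1:100) {
    f <- rnorm(3)
    want <- naive_mvn_density(f, model$mu_pd, model$sigma_pd) /
      naive_mvn_density(f, model$mu_et, model$sigma_et)
    expect_equal(qda_likelihood_ratio(model, f), want,
                 tolerance = 1e-8)
  }
  expect_error(qda_log_ratio(model, rnorm(4)), "dimension")
  # swapping the classes inverts the ratio
  sw <- model
  sw$mu_pd <- model$mu_et; sw$mu_et <- model$mu_pd
  sw$sigma_pd <- model$sigma_et; sw$sigma_et <- model$sigma_pd
  f <- rnorm(3)
  expect_equal(qda_likelihood_ratio(sw, f),
               1 / qda_likelihood_ratio(model, f), tolerance = 1e-10)
})

test_that("the log ratio is an exact quadratic in the features", {
  model <- structure(list(mu_pd = c(0.5, -0.2), mu_et = c(0, 0.3),
                          sigma_pd = random_spd(2, 3),
                          sigma_et = random_spd(2, 4),
                          shrinkage = 0, priors = c(PD = .5, ET = .5),
                          d = 2L, kind = "qda"), class = "qda_model")
  set.seed(22)
  f1 <- rnorm(40); f2 <- rnorm(40)
  y <- vapply(seq_along(f1), function(i)
    qda_log_ratio(model, c(f1[i], f2[i])), numeric(1))
  fit <- stats::lm(y ~ f1 + f2 + I(f1^2) + I(f2^2) + I(f1 * f2))
  expect_lt(max(abs(stats::residuals(fit))), 1e-8)
})

test_that("assessment decisions use the strict-threshold rule", {
  same <- structure(list(mu_pd = c(0, 0), mu_et = c(0, 0),
                         sigma_pd = diag(2), sigma_et = diag(2),
                         shrinkage = 0, priors = c(PD = .5, ET = .5),
                         d = 2L, kind = "qda"), class = "qda_model")
  # ratio exactly 1 at threshold 1 votes ET
  d <- classify_assessment(same, c(0.3, -0.8), threshold = 1)
  expect_identical(d$predicted, "ET")
  expect_equal(d$log_likelihood_ratio, 0)
  toy <- same; toy$mu_pd <- c(1, 0)
  f <- c(0.4, 0.1)
  expect_identical(classify_assessment(toy, f, threshold = 1e-12)$predicted,
                   "PD")
  expect_identical(classify_assessment(toy, f, threshold = 1e12)$predicted,
                   "ET")
  expect_error(classify_assessment(toy, f, threshold = 0), "> 0")
})

test_that("patient fusion is a logical AND over assessments", {
  d <- function(p) structure(list(predicted = p, log_likelihood_ratio = 0,
                                  threshold_used = 1),
                             class = "assessment_decision")
  expect_true(decide_patient(list(d("PD"), d("PD")), "PD")$correct)
  expect_false(decide_patient(list(d("PD"), d("ET")), "PD")$correct)
  expect_true(decide_patient(list(d("ET")), "ET")$correct)
  expect_error(decide_patient(list(), "PD"), "no assessment")
  # disagreeing assessments count incorrect and take the majority label
  r <- decide_patient(list(d("PD"), d("ET"), d("ET")), "PD")
  expect_false(r$correct)
  expect_identical(r$predicted, "ET")
  tie <- decide_patient(list(d("PD"), d("ET")), "PD")
  expect_false(tie$correct)
  expect_identical(tie$predicted, "ET")
  # monotone: adding a wrong decision never repairs a patient
  set.seed(23)
  for (i in 1:25) {
    preds <- sample(c("PD", "ET"), sample(1:4, 1), replace = TRUE)
    base <- decide_patient(lapply(preds, d), "PD")
    more <- decide_patient(lapply(c(preds, "ET"), d), "PD")
    if (!base$correct) expect_false(more$correct)
  }
})

test_that("naive Bayes is the diagonal-covariance quadratic discriminant", {
  set.seed(24)
  X <- matrix(rnorm(80 * 5), 80, 5)
  labels <- rep(c("PD", "ET"), each = 40L)
  X[labels == "PD", ] <- X[labels == "PD", ] + 0.8
  nb <- fit_naive_bayes(X, labels)
  qd <- fit_qda(X, labels, shrinkage = 1)
  for (i in 1:100) {
    f <- rnorm(5)
    expect_equal(qda_log_ratio(nb, f), qda_log_ratio(qd, f),
                 tolerance = 1e-10)
  }
  # univariate closed form
  x1 <- X[, 1, drop = FALSE]
  nb1 <- fit_naive_bayes(x1, labels)
  v_pd <- stats::var(x1[labels == "PD", 1])
  v_et <- stats::var(x1[labels == "ET", 1])
  eps_pd <- 1e-6 * v_pd; eps_et <- 1e-6 * v_et
  for (f in c(-1, 0, 0.5, 2)) {
    want <- stats::dnorm(f, mean(x1[labels == "PD", 1]),
                         sqrt(v_pd + eps_pd)) /
      stats::dnorm(f, mean(x1[labels == "ET", 1]), sqrt(v_et + eps_et))
    expect_equal(qda_likelihood_ratio(nb1, f), want, tolerance = 1e-9)
  }
  # identical class distributions give ratio 1
  X0 <- rbind(X[1:10, ], X[1:10, ])
  l0 <- rep(c("PD", "ET"), each = 10L)
  nb0 <- fit_naive_bayes(X0, l0)
  expect_equal(qda_likelihood_ratio(nb0, rnorm(5)), 1, tolerance = 1e-9)
})
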