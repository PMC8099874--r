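#' Assemble the 54-feature vector of one assessment
#'
#' Collects the stage-1 network's vote for each of the 54 signals of a
#' tremor assessment, in canonical order (trial-major, then task in
#' hint-index order, then axis x/y/z; see [feature_order()]).
#' Probabilistic mode stores p_PD per signal; binary mode stores
#' 1 if p_PD > 0.5 else 0 (ties map to 0).
#'
#' @param assessment a `tremor_assessment`.
#' @param model a trained `stage1_model`.
#' @param mode "probabilistic" or "binary".
#' @param params [spectrogram_params()] used for preprocessing.
#' @return numeric vector of length 54 with attributes `mode`,
#'   `patient_id`, `group`, `visit`, `hand`.
#' @export
assemble_features <- function(assessment, model,
                              mode = c("probabilistic", "binary"),
                              params = spectrogram_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(assessment, "tremor_assessment"))
  if (length(assessment$signals) != 54L) {
    stop("incomplete assessment: expected 54 signals")
  }
  samples <- prepare_stage1_samples(list(assessment), params = params)
  features_from_probs(predict_stage1(model, samples)[, "PD"],
                      vapply(samples, `[[`, integer(1), "trial"),
                      vapply(samples, `[[`, character(1), "task"),
                      vapply(samples, `[[`, character(1), "axis"),
                      mode = mode, assessment = assessment)
}

# Order p_PD votes canonically and apply the feature mode.
features_from_probs <- function(p_pd, trial, task, axis,
                                mode = "probabilistic",
                                assessment = NULL) {
  idx <- feature_index(trial, task, axis)
  if (anyDuplicated(idx)) stop("duplicate feature slots")
  v <- numeric(54)
  v[idx + 1L] <- p_pd
  if (mode == "binary") v <- as.numeric(v > 0.5)
  names(v) <- feature_order()$label
  attr(v, "mode") <- mode
  if (!is.null(assessment)) {
    attr(v, "patient_id") <- assessment$patient_id
    attr(v, "group") <- assessment$group
    attr(v, "visit") <- assessment$visit
    attr(v, "hand") <- assessment$hand
  }
  v
}

class_cov <- function(X) {
  if (nrow(X) < 2L) stop("each class needs at least 2 assessments")
  stats::cov(X)
}

regularize_cov <- function(S, shrinkage) {
  Sig <- (1 - shrinkage) * S + shrinkage * diag(diag(S), nrow(S))
  eps <- 1e-6 * mean(diag(S))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-8
  Sig + diag(eps, nrow(S))
}

#' Fit the quadratic discriminant model
#'
#' Models each class's feature vector as a multivariate Gaussian with its
#' own mean and covariance. With tens of assessments in 54 dimensions the
#' sample covariances are singular, so they are shrunk towards their
#' diagonal: Sigma_c = (1-s) S_c + s diag(S_c) + eps I, with
#' eps = 1e-6 x mean diagonal of S_c. The result is symmetric positive
#' definite by construction.
#'
#' @param X n x d matrix of feature vectors (rows = assessments).
#' @param labels character vector of "PD"/"ET" per row.
#' @param shrinkage diagonal shrinkage weight in `[0, 1]`.
#' @return a `qda_model` with `mu_pd`, `mu_et`, `sigma_pd`, `sigma_et`.
#' @export
fit_qda <- function(X, labels, shrinkage = 0.1) {
  X <- as.matrix(X)
  stopifnot(shrinkage >= 0, shrinkage <= 1, nrow(X) == length(labels))
  if (!all(labels %in% c("PD", "ET"))) stop("labels must be PD or ET")
  Xp <- X[labels == "PD", , drop = FALSE]
  Xe <- X[labels == "ET", , drop = FALSE]
  Sp <- class_cov(Xp); Se <- class_cov(Xe)
  structure(list(mu_pd = colMeans(Xp), mu_et = colMeans(Xe),
                 sigma_pd = regularize_cov(Sp, shrinkage),
                 sigma_et = regularize_cov(Se, shrinkage),
                 shrinkage = shrinkage, priors = c(PD = 0.5, ET = 0.5),
                 d = ncol(X), kind = "qda"),
            class = "qda_model")
}

#' Fit the diagonal (naive Bayes) second-stage model
#'
#' Per-feature univariate Gaussians per class: structurally a quadratic
#' discriminant whose covariances are fully diagonal. Same interface and
#' decision rule as [fit_qda()].
#'
#' @inheritParams fit_qda
#' @return a `qda_model` with diagonal covariances (`kind = "nb"`).
#' @export
fit_naive_bayes <- function(X, labels) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  if (!all(labels %in% c("PD", "ET"))) stop("labels must be PD or ET")
  Xp <- X[labels == "PD", , drop = FALSE]
  Xe <- X[labels == "ET", , drop = FALSE]
  if (nrow(Xp) < 2L || nrow(Xe) < 2L) {
    stop("each class needs at least 2 assessments")
  }
  diag_cov <- function(Xc) {
    v <- apply(Xc, 2L, stats::var)
    eps <- 1e-6 * mean(v)
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
    diag(v + eps, ncol(Xc))
  }
  structure(list(mu_pd = colMeans(Xp), mu_et = colMeans(Xe),
                 sigma_pd = diag_cov(Xp), sigma_et = diag_cov(Xe),
                 shrinkage = 1, priors = c(PD = 0.5, ET = 0.5),
                 d = ncol(X), kind = "nb"),
            class = "qda_model")
}

#' @export
print.qda_model <- function(x, ...) {
  cat(sprintf("<qda_model> %s, %d features, shrinkage %.2f\n", x$kind, x$d,
              x$shrinkage))
  invisible(x)
}

mvn_logdens_chol <- function(f, mu, sigma) {
  R <- chol(sigma)
  z <- backsolve(R, f - mu, transpose = TRUE)
  -0.5 * (length(f) * log(2 * pi) + sum(z * z)) - sum(log(diag(R)))
}

#' Likelihood ratio of the quadratic discriminant
#'
#' N(f; mu_PD, Sigma_PD) / N(f; mu_ET, Sigma_ET), computed in log space
#' via Cholesky factors for numerical stability. Values above 1 favour the
#' PD class.
#'
#' @param model a fitted `qda_model`.
#' @param f feature vector of length `model$d`.
#' @return `qda_log_ratio` returns the log likelihood ratio;
#'   `qda_likelihood_ratio` its exponential.
#' @export
qda_log_ratio <- function(model, f) {
  stopifnot(inherits(model, "qda_model"))
  f <- as.numeric(f)
  if (length(f) != model$d) {
    stop(sprintf("dimension mismatch: expected %d features, got %d",
                 model$d, length(f)))
  }
  mvn_logdens_chol(f, model$mu_pd, model$sigma_pd) -
    mvn_logdens_chol(f, model$mu_et, model$sigma_et)
}

#' @rdname qda_log_ratio
#' @export
qda_likelihood_ratio <- function(model, f) exp(qda_log_ratio(model, f))

#' Classify one tremor assessment
#'
#' PD if and only if the likelihood ratio strictly exceeds `threshold`
#' (a ratio exactly at the threshold votes ET). The log ratio is returned
#' so ROC curves can be swept over thresholds.
#'
#' @param model a fitted `qda_model`.
#' @param f 54-feature vector (or `model$d` features).
#' @param threshold decision threshold on the likelihood-ratio scale.
#' @return an `assessment_decision`: `predicted`, `log_likelihood_ratio`,
#'   `threshold_used`, plus the feature vector's provenance attributes.
#' @export
classify_assessment <- function(model, f, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  llr <- qda_log_ratio(model, f)
  structure(list(predicted = if (llr > log(threshold)) "PD" else "ET",
                 log_likelihood_ratio = llr, threshold_used = threshold,
                 patient_id = attr(f, "patient_id"),
                 group = attr(f, "group"), visit = attr(f, "visit"),
                 hand = attr(f, "hand")),
            class = "assessment_decision")
}

#' Patient-level decision fusion
#'
#' A patient is counted correctly classified if and only if every one of
#' their test assessments (both hands, all visits in the test set) is
#' classified correctly -- the logical-AND rule. For confusion matrices a
#' patient-level label is also produced: the unanimous label when all
#' assessment decisions agree, otherwise the majority label (a tie goes to
#' the label opposing the truth, keeping the patient on the incorrect side
#' of the matrix).
#'
#' @param decisions list of `assessment_decision`s for one patient.
#' @param truth the patient's true label ("PD"/"ET").
#' @return list(correct, predicted, n_assessments).
#' @export
decide_patient <- function(decisions, truth) {
  if (length(decisions) == 0L) stop("no assessment decisions for patient")
  preds <- vapply(decisions, `[[`, character(1), "predicted")
  correct <- all(preds == truth)
  predicted <- if (length(unique(preds)) == 1L) preds[1L] else {
    n_pd <- sum(preds == "PD")
    n_et <- sum(preds == "ET")
    if (n_pd > n_et) "PD" else if (n_et > n_pd) "ET" else
      setdiff(c("PD", "ET"), truth)
  }
  list(correct = correct, predicted = predicted,
       n_assessments = length(decisions))
}
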