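round_half_away <- function(x) floor(x + 0.5)

#' Derive a per-stage seed from the master seed
#'
#' One master seed fans out to every stochastic stage (splits, weight
#' initialisation, shuffling) through this documented counter scheme, so a
#' whole evaluation is reproducible from a single integer. Results stay
#' below 2^31.
#'
#' @param master master seed (integer).
#' @param i stage counter (integer >= 0).
#' @return derived integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647L)
}

#' Patient-wise train/test split
#'
#' Splits patients (never signals or assessments) into train and test
#' sets, stratified by class. The total test count is
#' round-half-away-from-zero of `n x test_fraction`, apportioned to the
#' two classes by largest remainder with a floor of one test patient per
#' class; a fraction that would empty a class on the training side is an
#' error. All of a patient's assessments -- both hands, every visit --
#' follow the patient.
#'
#' @param patients data frame with columns `patient_id` and `group`
#'   (one row per patient).
#' @param test_fraction fraction of patients assigned to the test set.
#' @param seed RNG seed for the draw.
#' @return list(train, test): disjoint character vectors of patient ids
#'   covering all patients.
#' @export
split_patients <- function(patients, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  patients <- unique(patients[, c("patient_id", "group")])
  counts <- table(factor(patients$group, levels = c("PD", "ET")))
  if (any(counts < 2L)) {
    stop("need at least 2 patients per class to split")
  }
  raw <- as.numeric(counts) * test_fraction
  base <- floor(raw)
  total <- round_half_away(sum(raw))
  extra <- total - sum(base)
  target <- base
  if (extra > 0) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(extra)]
    target[give] <- target[give] + 1L
  }
  target <- pmax(target, 1L)
  if (any(target > as.numeric(counts) - 1L)) {
    stop("test_fraction leaves an empty class on the training side")
  }
  set.seed(seed)
  test <- character(0)
  for (ci in seq_along(counts)) {
    ids <- patients$patient_id[patients$group == names(counts)[ci]]
    test <- c(test, sample(ids, target[ci]))
  }
  list(train = setdiff(patients$patient_id, test), test = test)
}

#' ROC curve and AUC of assessment-level scores
#'
#' Sweeps the decision threshold over all observed log-likelihood ratios,
#' with PD as the positive class, and integrates sensitivity against
#' (1 - specificity) by the trapezoid rule. Tied scores are grouped, so
#' the AUC equals the pairwise-concordance (Mann-Whitney) statistic with
#' ties counted 1/2.
#'
#' @param scores numeric scores (higher favours PD).
#' @param truth true labels ("PD"/"ET") per score.
#' @return list(roc = data frame (fpr, tpr), auc).
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == "PD"
  if (!any(pos) || all(pos)) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  boundary <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[boundary]
  fp <- cumsum(!y)[boundary]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

assessment_table <- function(assessments) {
  data.frame(
    assessment = vapply(assessments, function(a)
      assessment_key(a$patient_id, a$visit, a$hand), character(1)),
    patient_id = vapply(assessments, `[[`, character(1), "patient_id"),
    group = vapply(assessments, `[[`, character(1), "group"),
    visit = vapply(assessments, `[[`, integer(1), "visit"),
    hand = vapply(assessments, `[[`, character(1), "hand"))
}

# Features for every assessment from one stage-1 prediction pass.
cohort_features <- function(model, samples, mode) {
  probs <- predict_stage1(model, samples)[, "PD"]
  akeys <- vapply(samples, `[[`, character(1), "assessment")
  out <- list()
  for (k in unique(akeys)) {
    sel <- which(akeys == k)
    sub <- samples[sel]
    out[[k]] <- features_from_probs(
      probs[sel],
      vapply(sub, `[[`, integer(1), "trial"),
      vapply(sub, `[[`, character(1), "task"),
      vapply(sub, `[[`, character(1), "axis"),
      mode = mode)
  }
  out
}

fit_stage2 <- function(X, labels, config) {
  if (config$stage2 == "nb") fit_naive_bayes(X, labels) else
    fit_qda(X, labels, shrinkage = config$shrinkage)
}

# One train/evaluate repeat over a prepared cohort.
evaluate_once <- function(samples, atable, config, test_fraction,
                          repeat_seed, first_visit_only = FALSE) {
  ptable <- unique(atable[, c("patient_id", "group")])
  split <- split_patients(ptable, test_fraction, seed = repeat_seed)
  pids <- vapply(samples, `[[`, character(1), "patient_id")
  cfg1 <- config$stage1
  cfg1$seed <- repeat_seed
  model <- train_stage1(samples[pids %in% split$train], cfg1,
                        input_dim = dim(samples[[1]]$x),
                        use_hint = config$use_hint)
  feats <- cohort_features(model, samples, config$feature_mode)
  train_rows <- atable$patient_id %in% split$train
  Xtr <- do.call(rbind, feats[atable$assessment[train_rows]])
  s2 <- fit_stage2(Xtr, atable$group[train_rows], config)
  test_tab <- atable[atable$patient_id %in% split$test, , drop = FALSE]
  if (first_visit_only) {
    has_v1 <- tapply(test_tab$visit, test_tab$patient_id,
                     function(v) any(v == 1L))
    absent <- names(has_v1)[!has_v1]
    if (length(absent) > 0L) {
      warning(sprintf("test patient(s) without a visit-1 assessment excluded: %s",
                      paste(absent, collapse = ", ")))
    }
    test_tab <- test_tab[test_tab$visit == 1L, , drop = FALSE]
  }
  decisions <- lapply(test_tab$assessment, function(k)
    classify_assessment(s2, feats[[k]], threshold = config$threshold))
  pred <- vapply(decisions, `[[`, character(1), "predicted")
  llr <- vapply(decisions, `[[`, numeric(1), "log_likelihood_ratio")
  patient_rows <- split(seq_len(nrow(test_tab)), test_tab$patient_id)
  pdec <- lapply(names(patient_rows), function(pid) {
    rows <- patient_rows[[pid]]
    decide_patient(decisions[rows], truth = test_tab$group[rows[1L]])
  })
  ptruth <- vapply(names(patient_rows), function(pid)
    test_tab$group[patient_rows[[pid]][1L]], character(1))
  list(model = model, stage2 = s2, split = split,
       assessment_accuracy = mean(pred == test_tab$group),
       patient_accuracy = mean(vapply(pdec, `[[`, logical(1), "correct")),
       patient_predicted = vapply(pdec, `[[`, character(1), "predicted"),
       patient_truth = ptruth,
       scores = llr, score_truth = test_tab$group)
}

build_report <- function(runs, config, test_fraction, first_visit_only) {
  pa <- vapply(runs, `[[`, numeric(1), "patient_accuracy")
  aa <- vapply(runs, `[[`, numeric(1), "assessment_accuracy")
  pred <- unlist(lapply(runs, `[[`, "patient_predicted"))
  truth <- unlist(lapply(runs, `[[`, "patient_truth"))
  confusion <- table(truth = factor(truth, c("PD", "ET")),
                     predicted = factor(pred, c("PD", "ET")))
  tp <- confusion["PD", "PD"]; fn <- confusion["PD", "ET"]
  tn <- confusion["ET", "ET"]; fp <- confusion["ET", "PD"]
  scores <- unlist(lapply(runs, `[[`, "scores"))
  struth <- unlist(lapply(runs, `[[`, "score_truth"))
  roc <- roc_auc(scores, struth)
  structure(list(
    patient_accuracy = mean(pa), per_repeat = pa,
    assessment_accuracy = mean(aa), per_repeat_assessment = aa,
    confusion = confusion,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    roc = roc$roc, auc = roc$auc, n_repeats = length(runs),
    test_fraction = test_fraction, first_visit_only = first_visit_only,
    epochs = config$stage1$epochs, seed = config$seed,
    config_hash = config_hash(config)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> %d repeat(s), test fraction %.2f%s\n",
           "  patient accuracy    %.4f\n  assessment accuracy %.4f\n",
           "  sensitivity %.4f  specificity %.4f  AUC %.4f\n"),
    x$n_repeats, x$test_fraction,
    if (x$first_visit_only) " (first-visit test)" else "",
    x$patient_accuracy, x$assessment_accuracy, x$sensitivity,
    x$specificity, x$auc))
  invisible(x)
}

#' Monte-Carlo evaluation of the full two-stage pipeline
#'
#' Repeats `n_repeats` times: draw a patient-wise train/test split, train
#' the stage-1 network on the training patients' signals, fit the
#' second-stage discriminant on the training assessments' feature vectors,
#' then classify the test assessments and fuse them into patient decisions
#' (logical AND). Reports the mean and per-repeat patient-level accuracy,
#' the pooled patient confusion matrix (PD positive, ET negative) and the
#' assessment-level ROC/AUC over the pooled log-likelihood ratios.
#' All randomness derives from `config$seed` via [derive_seed()].
#'
#' @param cohort a [tremor_cohort()].
#' @param config a validated pipeline config ([validate_config()]).
#' @param test_fraction fraction of patients reserved for testing.
#' @param n_repeats number of Monte-Carlo repeats.
#' @return an `evaluation_report`.
#' @export
monte_carlo_evaluate <- function(cohort, config = validate_config(),
                                 test_fraction = 0.25, n_repeats = 30L) {
  config <- validate_config(config)
  assessments <- assemble_assessments(cohort)
  samples <- prepare_stage1_samples(assessments,
                                    params = config$spectrogram)
  atable <- assessment_table(assessments)
  runs <- lapply(seq_len(n_repeats), function(r)
    evaluate_once(samples, atable, config, test_fraction,
                  repeat_seed = derive_seed(config$seed, r)))
  build_report(runs, config, test_fraction, first_visit_only = FALSE)
}

#' First-visit evaluation
#'
#' Identical to [monte_carlo_evaluate()] except that test metrics are
#' computed only on the visit-1 assessments of the test patients (training
#' still uses all visits of the training patients). For a single-visit
#' cohort this coincides with the standard evaluation.
#'
#' @inheritParams monte_carlo_evaluate
#' @return an `evaluation_report` with `first_visit_only = TRUE`.
#' @export
first_visit_evaluate <- function(cohort, config = validate_config(),
                                 test_fraction = 0.25, n_repeats = 30L) {
  config <- validate_config(config)
  assessments <- assemble_assessments(cohort)
  samples <- prepare_stage1_samples(assessments,
                                    params = config$spectrogram)
  atable <- assessment_table(assessments)
  runs <- lapply(seq_len(n_repeats), function(r)
    evaluate_once(samples, atable, config, test_fraction,
                  repeat_seed = derive_seed(config$seed, r),
                  first_visit_only = TRUE))
  build_report(runs, config, test_fraction, first_visit_only = TRUE)
}

#' Wrapper ranking of the 54 features
#'
#' Ranks each feature by the patient-wise k-fold cross-validated accuracy
#' of the second-stage classifier using that single feature alone (the
#' features-considered-independently wrapper). Ties are broken by
#' canonical feature index; labels follow the
#' "TrialNumber-TaskName-RecordingChannel" convention.
#'
#' @param X n x 54 feature matrix (rows = assessments).
#' @param labels "PD"/"ET" per row.
#' @param patient_ids patient id per row (folds partition patients).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param classifier "qda" or "nb".
#' @param shrinkage shrinkage for the QDA fit.
#' @return data frame (rank, index, label, cv_accuracy) sorted by rank.
#' @export
rank_features_wrapper <- function(X, labels, patient_ids, k = 5L,
                                  seed = 1L, classifier = c("qda", "nb"),
                                  shrinkage = 0.1) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels), nrow(X) == length(patient_ids))
  folds <- patient_folds(unique(patient_ids), k, seed)
  order_df <- feature_order()
  acc <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    correct <- 0L; total <- 0L
    for (i in seq_len(k)) {
      val <- patient_ids %in% folds[[i]]
      xj_tr <- X[!val, j, drop = FALSE]
      fit <- if (classifier == "nb") fit_naive_bayes(xj_tr, labels[!val])
             else fit_qda(xj_tr, labels[!val], shrinkage = shrinkage)
      pred <- vapply(X[val, j], function(v)
        if (qda_log_ratio(fit, v) > 0) "PD" else "ET", character(1))
      correct <- correct + sum(pred == labels[val])
      total <- total + sum(val)
    }
    acc[j] <- correct / total
  }
  ord <- order(-acc, seq_along(acc))
  labs <- if (ncol(X) == 54L) order_df$label else
    sprintf("feature%d", seq_len(ncol(X)))
  data.frame(rank = seq_along(ord), index = ord[seq_along(ord)] - 1L,
             label = labs[ord], cv_accuracy = acc[ord])
}
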