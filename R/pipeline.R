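#' Default pipeline configuration
#'
#' The defaults are the published winning combination: probabilistic
#' features into a QDA second stage, Adam at learning rate 1e-4 for 44
#' epochs, Leaky-ReLU slope 0.1, decision threshold 1 (uniform priors),
#' 30 Monte-Carlo repeats at test fraction 0.25, saliency alpha 0.02.
#'
#' @return a named list accepted by [validate_config()].
#' @export
default_config <- function() {
  list(stage1 = stage1_config(),
       stage2 = "qda",
       shrinkage = 0.1,
       feature_mode = "probabilistic",
       use_hint = TRUE,
       threshold = 1,
       test_fraction = 0.25,
       n_repeats = 30L,
       alpha = 0.02,
       spectrogram = spectrogram_params(),
       seed = 1L)
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults for absent fields, rejects unknown keys and
#' out-of-range values, and returns the normalised config.
#'
#' @param config partial configuration list (possibly empty).
#' @return the full validated configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, config)
  if (!inherits(out$stage1, "stage1_config")) {
    out$stage1 <- do.call(stage1_config, out$stage1)
  }
  if (!out$stage2 %in% c("qda", "nb")) stop("stage2 must be 'qda' or 'nb'")
  if (!out$feature_mode %in% c("probabilistic", "binary")) {
    stop("feature_mode must be 'probabilistic' or 'binary'")
  }
  if (out$shrinkage < 0 || out$shrinkage > 1) {
    stop("shrinkage must be in [0, 1]")
  }
  if (out$stage1$learning_rate < 0) stop("learning_rate must be >= 0")
  if (out$threshold <= 0) stop("threshold must be > 0")
  if (out$test_fraction <= 0 || out$test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  if (out$n_repeats < 1L) stop("n_repeats must be >= 1")
  if (out$alpha <= 0 || out$alpha >= 1) stop("alpha must be in (0, 1)")
  if (!inherits(out$spectrogram, "spectrogram_params")) {
    out$spectrogram <- do.call(spectrogram_params, out$spectrogram)
  }
  out$seed <- as.integer(out$seed)
  out
}

#' Stable hash of a configuration
#'
#' 32-bit FNV-1a over the JSON serialisation; embedded in every emitted
#' artifact so outputs can be traced back to the exact configuration.
#'
#' @param config a configuration list.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    # keep the multiply in double precision, reduce mod 2^32
    h <- (as.numeric(h + 2^30) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the end-to-end pipeline
#'
#' Simulates (or accepts) a cohort, runs the Monte-Carlo evaluation and,
#' optionally, the Grad-CAM group explanation, stamping every artifact
#' with the config hash and master seed.
#'
#' @param config pipeline configuration (see [validate_config()]).
#' @param cohort a [tremor_cohort()]; when NULL, `cohort_spec` must be
#'   given and a cohort is simulated.
#' @param cohort_spec a [cohort_spec()] used when `cohort` is NULL.
#' @param explain also compute saliency statistics and significance masks
#'   (uses the final repeat's trained model over the whole cohort).
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return list with elements `report` (an `evaluation_report`),
#'   optionally `explanation`, and `provenance` (config hash + seed).
#' @export
run_pipeline <- function(config = list(), cohort = NULL,
                         cohort_spec = NULL, explain = FALSE,
                         out_dir = NULL) {
  config <- validate_config(config)
  t0 <- Sys.time()
  if (is.null(cohort)) {
    if (is.null(cohort_spec)) stop("either cohort or cohort_spec required")
    message("simulating cohort...")
    cohort <- simulate_cohort(cohort_spec)
  }
  message(sprintf("evaluating (%d repeat(s), test fraction %.2f)...",
                  config$n_repeats, config$test_fraction))
  report <- monte_carlo_evaluate(cohort, config,
                                 test_fraction = config$test_fraction,
                                 n_repeats = config$n_repeats)
  out <- list(report = report,
              provenance = list(config_hash = config_hash(config),
                                seed = config$seed,
                                elapsed_s = as.numeric(difftime(Sys.time(),
                                                                t0, "secs"))))
  if (explain) {
    message("computing saliency statistics...")
    out$explanation <- explain_cohort(cohort, config)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(repeat_ = seq_along(report$per_repeat),
                                patient_accuracy = report$per_repeat,
                                assessment_accuracy =
                                  report$per_repeat_assessment),
                     file.path(out_dir, "per_repeat.csv"),
                     row.names = FALSE)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(patient_accuracy = report$patient_accuracy,
           assessment_accuracy = report$assessment_accuracy,
           sensitivity = report$sensitivity,
           specificity = report$specificity, auc = report$auc,
           n_repeats = report$n_repeats,
           test_fraction = report$test_fraction,
           epochs = report$epochs,
           config_hash = out$provenance$config_hash,
           seed = config$seed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Grad-CAM group explanation of a cohort
#'
#' Trains the pipeline once on a patient-wise split, computes Grad-CAM
#' maps for every signal of every correctly classified assessment
#' (whole-cohort scope), and derives the pixel-wise z grid and the
#' alpha = 0.02 significance masks.
#'
#' @param cohort a [tremor_cohort()].
#' @param config pipeline configuration.
#' @return list(stats, z, masks, normality_p, model).
#' @export
explain_cohort <- function(cohort, config = list()) {
  config <- validate_config(config)
  assessments <- assemble_assessments(cohort)
  samples <- prepare_stage1_samples(assessments,
                                    params = config$spectrogram)
  atable <- assessment_table(assessments)
  run <- evaluate_once(samples, atable, config, config$test_fraction,
                       repeat_seed = derive_seed(config$seed, 1L))
  feats <- cohort_features(run$model, samples, config$feature_mode)
  correct <- vapply(atable$assessment, function(k) {
    d <- classify_assessment(run$stage2, feats[[k]],
                             threshold = config$threshold)
    d$predicted == atable$group[atable$assessment == k]
  }, logical(1))
  stats <- collect_group_maps(run$model, samples,
                              atable$assessment[correct])
  z <- pixelwise_z(stats$et, stats$pd)
  masks <- significance_masks(z, alpha = config$alpha,
                              mean_et = stats$et$mean,
                              mean_pd = stats$pd$mean)
  list(stats = stats, z = z, masks = masks, model = run$model,
       n_correct = sum(correct), n_assessments = length(correct))
}
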