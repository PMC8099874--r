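#' One-hot task hint vector
#'
#' The network receives, next to the spectrogram, a 6-bit one-hot encoding
#' of the recorded task, concatenated with the output of the first dense
#' layer to form the input of the second dense layer. Different tasks
#' stimulate different tremor components (rest vs postural vs loaded), so
#' the hint tells the network which behavioural condition it is looking at.
#'
#' @param task one of the 6 included tasks; the excluded finger-to-nose
#'   task is rejected.
#' @return numeric vector of 6 bits with exactly one bit set.
#' @export
encode_task_hint <- function(task) {
  idx <- task_hint_index(task)
  bits <- numeric(6)
  bits[idx + 1L] <- 1
  bits
}

#' Stage-1 network configuration
#'
#' Two convolutional layers (each followed by ReLU and 2x2 max pooling)
#' and three dense layers. ReLU follows the first dense layer,
#' Leaky-ReLU (slope 0.1) the second; the final 2-unit layer feeds a
#' softmax. Training minimises mean softmax cross-entropy with Adam at
#' learning rate 1e-4 for a fixed 44 epochs (no early stopping). The
#' exact filter counts and dense widths are this package's choice: the
#' smallest architecture that trains on a CPU.
#'
#' @param conv1_filters,conv1_kernel first conv layer: filters, square
#'   kernel size.
#' @param conv2_filters,conv2_kernel second conv layer.
#' @param pool square max-pool size after each conv layer.
#' @param dense_widths 3 integers; the last must be 2 (PD/ET logits).
#' @param leaky_slope Leaky-ReLU slope after the second dense layer.
#' @param learning_rate Adam learning rate.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param seed seed for weight initialisation and shuffling.
#' @return a `stage1_config` object.
#' @export
stage1_config <- function(conv1_filters = 8L, conv1_kernel = 5L,
                          conv2_filters = 16L, conv2_kernel = 3L,
                          pool = 2L, dense_widths = c(128L, 64L, 2L),
                          leaky_slope = 0.1, learning_rate = 1e-4,
                          epochs = 44L, batch_size = 32L, seed = 1L) {
  if (length(dense_widths) != 3L || dense_widths[3] != 2L) {
    stop("dense_widths must be 3 integers ending in 2")
  }
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_kernel = as.integer(conv2_kernel),
                 pool = as.integer(pool),
                 dense_widths = as.integer(dense_widths),
                 leaky_slope = leaky_slope,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "stage1_config")
}

stage1_dims <- function(config, input_dim) {
  H <- input_dim[1]; W <- input_dim[2]
  k1 <- config$conv1_kernel; k2 <- config$conv2_kernel; p <- config$pool
  c1 <- c(H - k1 + 1L, W - k1 + 1L)
  p1 <- c1 %/% p
  c2 <- c(p1[1] - k2 + 1L, p1[2] - k2 + 1L)
  p2 <- c2 %/% p
  if (any(c(c1, p1, c2, p2) < 1L)) stop("input too small for architecture")
  list(input = input_dim, conv1 = c1, pool1 = p1, conv2 = c2, pool2 = p2,
       flat = p2[1] * p2[2] * config$conv2_filters)
}

# Uniform fan-in ("He uniform") initialisation: U(+-sqrt(6/fan_in)).
init_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -sqrt(6 / nr), sqrt(6 / nr)), nr, nc)
}

#' Initialise an untrained stage-1 model
#'
#' @param config a [stage1_config()].
#' @param input_dim spectrogram dimensions (bins x frames), 129 x 191 for
#'   the standard preprocessing.
#' @return a `stage1_model` with seeded random weights.
#' @export
stage1_init <- function(config = stage1_config(), input_dim = c(129L, 191L)) {
  stopifnot(inherits(config, "stage1_config"))
  dims <- stage1_dims(config, as.integer(input_dim))
  set.seed(config$seed)
  k1 <- config$conv1_kernel; k2 <- config$conv2_kernel
  d <- config$dense_widths
  params <- list(
    W1 = init_mat(k1 * k1, config$conv1_filters),
    b1 = numeric(config$conv1_filters),
    W2 = init_mat(k2 * k2 * config$conv1_filters, config$conv2_filters),
    b2 = numeric(config$conv2_filters),
    W3 = init_mat(dims$flat, d[1]), b3 = numeric(d[1]),
    W4 = init_mat(d[1] + 6L, d[2]), b4 = numeric(d[2]),
    W5 = init_mat(d[2], 2L), b5 = numeric(2))
  structure(list(params = params, config = config, dims = dims,
                 use_hint = TRUE, training_log = NULL,
                 version = "tremorid-stage1-1"),
            class = "stage1_model")
}

#' @export
print.stage1_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<stage1_model> input %dx%d, %d parameters, %s\n",
              x$dims$input[1], x$dims$input[2], n_par,
              if (is.null(x$training_log)) "untrained" else
                sprintf("trained %d epochs", nrow(x$training_log))))
  invisible(x)
}

relu <- function(x) pmax(x, 0)

# Convolutional front end for one sample (fused C++ stack). With
# keep = TRUE also returns the post-ReLU conv2 maps and pool-2 argmax
# needed for Grad-CAM unpooling.
conv_forward <- function(model, x, keep = FALSE) {
  cfg <- model$config; pr <- model$params
  res <- cpp_conv_stack_fwd(x, pr$W1, pr$b1, pr$W2, pr$b2,
                            cfg$conv1_kernel, cfg$conv2_kernel, cfg$pool,
                            keep)
  res$flat <- as.numeric(res$flat)
  if (keep) res$x <- x
  res
}

# Dense head over a batch. Fm: B x flat, Hm: B x 6 hint matrix.
dense_forward <- function(model, Fm, Hm) {
  pr <- model$params; slope <- model$config$leaky_slope
  B <- nrow(Fm)
  if (!isTRUE(model$use_hint)) Hm <- matrix(0, B, 6L)
  Z3 <- Fm %*% pr$W3 + rep(pr$b3, each = B)
  A3 <- relu(Z3)
  H <- cbind(A3, Hm)
  Z4 <- H %*% pr$W4 + rep(pr$b4, each = B)
  A4 <- ifelse(Z4 > 0, Z4, slope * Z4)
  Z5 <- A4 %*% pr$W5 + rep(pr$b5, each = B)
  zmax <- apply(Z5, 1L, max)
  E <- exp(Z5 - zmax)
  P <- E / rowSums(E)
  list(Z3 = Z3, A3 = A3, H = H, Z4 = Z4, A4 = A4, Z5 = Z5, P = P)
}

# Batch backprop of the dense head given dZ5 (B x 2). Returns parameter
# gradients and dFm, the gradient at the flattened conv features.
dense_backward <- function(model, fwd, dZ5) {
  pr <- model$params; slope <- model$config$leaky_slope
  d1 <- model$config$dense_widths[1]
  dW5 <- crossprod(fwd$A4, dZ5); db5 <- colSums(dZ5)
  dA4 <- tcrossprod(dZ5, pr$W5)
  dZ4 <- dA4 * ifelse(fwd$Z4 > 0, 1, slope)
  dW4 <- crossprod(fwd$H, dZ4); db4 <- colSums(dZ4)
  dH <- tcrossprod(dZ4, pr$W4)
  dA3 <- dH[, seq_len(d1), drop = FALSE]
  dZ3 <- dA3 * (fwd$Z3 > 0)
  dW3 <- crossprod(fwd$Fm, dZ3); db3 <- colSums(dZ3)
  dFm <- tcrossprod(dZ3, pr$W3)
  list(grads = list(W3 = dW3, b3 = db3, W4 = dW4, b4 = db4, W5 = dW5,
                    b5 = db5),
       dFm = dFm)
}

# Backprop one sample's dflat through pool2 to the post-ReLU conv2 maps
# (the Grad-CAM target layer).
conv2_activation_grad <- function(model, store, dflat) {
  cfg <- model$config; dims <- model$dims
  g <- array(dflat, dim = c(dims$pool2, cfg$conv2_filters))
  cpp_maxpool_bwd(g, store$argmax2, dims$conv2[1], dims$conv2[2])
}

# Conv parameter gradients for one sample; the C++ kernel recomputes the
# forward activations internally.
conv_backward <- function(model, x, dflat, input_grad = FALSE) {
  cfg <- model$config; pr <- model$params
  cpp_conv_stack_bwd(x, pr$W1, pr$b1, pr$W2, pr$b2, cfg$conv1_kernel,
                     cfg$conv2_kernel, cfg$pool, dflat, input_grad)
}

as_spec_matrix <- function(spec) {
  if (inherits(spec, "spectrogram")) spec$power else as.matrix(spec)
}

#' Stage-1 forward pass
#'
#' Maps one network-scaled spectrogram plus its task hint to class
#' probabilities. Deterministic given fixed parameters; the two outputs
#' are a softmax pair summing to one.
#'
#' @param model a `stage1_model`.
#' @param spec network-scaled `spectrogram` or a bins x frames matrix.
#' @param hint 6-bit hint from [encode_task_hint()].
#' @return named numeric vector c(PD = p_PD, ET = p_ET).
#' @export
stage1_forward <- function(model, spec, hint) {
  stopifnot(inherits(model, "stage1_model"))
  x <- as_spec_matrix(spec)
  if (!all(dim(x) == model$dims$input)) {
    stop(sprintf("shape error: expected %dx%d input, got %dx%d",
                 model$dims$input[1], model$dims$input[2], nrow(x), ncol(x)))
  }
  if (length(hint) != 6L || !all(hint %in% c(0, 1)) || sum(hint) != 1) {
    stop("hint must be a 6-bit one-hot vector")
  }
  cf <- conv_forward(model, x)
  fwd <- dense_forward(model, matrix(cf$flat, 1L), matrix(hint, 1L))
  stats::setNames(as.numeric(fwd$P), c("PD", "ET"))
}

label_onehot <- function(labels) {
  lab <- match(labels, c("PD", "ET"))
  if (anyNA(lab)) stop("labels must be PD or ET")
  cbind(PD = as.numeric(lab == 1L), ET = as.numeric(lab == 2L))
}

check_samples <- function(samples) {
  labs <- vapply(samples, `[[`, character(1), "label")
  if (length(unique(labs)) < 2L) {
    stop("training requires both classes to be present")
  }
  labs
}

#' Train the stage-1 network
#'
#' Minimises mean softmax cross-entropy with Adam over minibatches,
#' running exactly `config$epochs` epochs with seeded shuffling. The
#' training log records the mean cross-entropy per epoch (and validation
#' accuracy when a validation set is supplied).
#'
#' @param samples list of training samples, each a list with elements
#'   `x` (network-scaled bins x frames matrix), `hint` (6-bit vector),
#'   `label` ("PD"/"ET") and optionally `patient_id`.
#' @param config a [stage1_config()].
#' @param input_dim spectrogram dimensions.
#' @param validation optional list of samples evaluated after each epoch.
#' @param use_hint set FALSE to ablate the task hint (zeros fed instead).
#' @return a trained `stage1_model` with `training_log`.
#' @export
train_stage1 <- function(samples, config = stage1_config(),
                         input_dim = c(129L, 191L), validation = NULL,
                         use_hint = TRUE) {
  labs <- check_samples(samples)
  model <- stage1_init(config, input_dim)
  model$use_hint <- isTRUE(use_hint)
  Y <- label_onehot(labs)
  hints <- t(vapply(samples, function(s) as.numeric(s$hint), numeric(6)))
  n <- length(samples)
  # private copies of the parameter vectors: the Adam step mutates them
  # in place (C++) to avoid reallocating the dense weights every batch
  params <- lapply(model$params, function(p) p + 0)
  model$params <- params
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  tstep <- 0L
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total_ce <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(idx)
      Fm <- matrix(0, B, model$dims$flat)
      for (b in seq_len(B)) {
        Fm[b, ] <- conv_forward(model, samples[[idx[b]]]$x)$flat
      }
      fwd <- dense_forward(model, Fm, hints[idx, , drop = FALSE])
      fwd$Fm <- Fm
      yb <- Y[idx, , drop = FALSE]
      total_ce <- total_ce - sum(yb * log(pmax(fwd$P, 1e-300)))
      dZ5 <- (fwd$P - yb) / B
      bk <- dense_backward(model, fwd, dZ5)
      grads <- bk$grads
      cgrads <- NULL
      for (b in seq_len(B)) {
        cg <- conv_backward(model, samples[[idx[b]]]$x, bk$dFm[b, ])
        if (is.null(cgrads)) cgrads <- cg else {
          for (nm in names(cg)) cgrads[[nm]] <- cgrads[[nm]] + cg[[nm]]
        }
      }
      grads <- c(grads, cgrads)
      tstep <- tstep + 1L
      cpp_adam_step(params, grads, m_state, v_state, tstep,
                    config$learning_rate, 0.9, 0.999, 1e-8)
    }
    val_acc <- NA_real_
    if (!is.null(validation)) {
      pv <- predict_stage1(model, validation)
      truth <- vapply(validation, `[[`, character(1), "label")
      val_acc <- mean(colnames(pv)[max.col(pv, ties.method = "first")] ==
                        truth)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = total_ce / n,
                                    val_accuracy = val_acc)
  }
  model$training_log <- if (config$epochs > 0L) do.call(rbind, log_rows) else
    data.frame(epoch = integer(0), loss = numeric(0),
               val_accuracy = numeric(0))
  model
}

#' Predict stage-1 probabilities for a list of samples
#'
#' @param model a trained `stage1_model`.
#' @param samples list of samples as in [train_stage1()].
#' @return matrix with columns PD, ET of per-signal probabilities.
#' @export
predict_stage1 <- function(model, samples) {
  n <- length(samples)
  Fm <- matrix(0, n, model$dims$flat)
  for (i in seq_len(n)) {
    Fm[i, ] <- conv_forward(model, samples[[i]]$x)$flat
  }
  hints <- t(vapply(samples, function(s) as.numeric(s$hint), numeric(6)))
  fwd <- dense_forward(model, Fm, hints)
  colnames(fwd$P) <- c("PD", "ET")
  fwd$P
}

# Seeded partition of patients into k folds of near-equal size.
patient_folds <- function(patients, k, seed) {
  if (k > length(patients)) stop("k exceeds the number of patients")
  set.seed(seed)
  shuffled <- sample(patients)
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Patient-wise k-fold cross-validation of the stage-1 network
#'
#' Folds partition patients, never signals: all recordings of one patient
#' fall in exactly one validation fold, so no information leaks between
#' training and validation.
#'
#' @param samples list of samples (each must carry `patient_id`).
#' @param config a [stage1_config()].
#' @param k number of folds.
#' @param input_dim spectrogram dimensions.
#' @param use_hint set FALSE to ablate the task hint.
#' @return list with `fold_accuracy` (length k), `mean_accuracy` and the
#'   fold assignment.
#' @export
crossvalidate_stage1 <- function(samples, config = stage1_config(), k = 5L,
                                 input_dim = c(129L, 191L),
                                 use_hint = TRUE) {
  pids <- vapply(samples, `[[`, character(1), "patient_id")
  folds <- patient_folds(unique(pids), k, config$seed)
  acc <- numeric(k)
  for (i in seq_len(k)) {
    val_idx <- pids %in% folds[[i]]
    model <- train_stage1(samples[!val_idx], config, input_dim,
                          use_hint = use_hint)
    p <- predict_stage1(model, samples[val_idx])
    truth <- vapply(samples[val_idx], `[[`, character(1), "label")
    acc[i] <- mean(colnames(p)[max.col(p, ties.method = "first")] == truth)
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc), folds = folds)
}

#' Save / load a stage-1 model
#'
#' Checkpoints carry a format version; loading a file with a different
#' version (or an unreadable file) is an error. A save/load round trip
#' reproduces forward outputs bit-identically.
#'
#' @param model a `stage1_model`.
#' @param path checkpoint path.
#' @return `load_stage1` returns the model.
#' @export
save_stage1 <- function(model, path) {
  stopifnot(inherits(model, "stage1_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_stage1
#' @export
load_stage1 <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupted checkpoint: ",
                                             conditionMessage(e)))
  if (!inherits(model, "stage1_model") ||
      !identical(model$version, "tremorid-stage1-1")) {
    stop("checkpoint version mismatch")
  }
  model
}

#' Preprocess cohort assessments into stage-1 samples
#'
#' Runs downsample -> demean -> spectrogram -> network scaling for every
#' signal of every assessment and attaches the task hint, label and
#' provenance. This is the bridge between the data model and the network.
#'
#' @param assessments list of `tremor_assessment`s from
#'   [assemble_assessments()].
#' @param params [spectrogram_params()].
#' @return list of samples (x, hint, label, patient_id, visit, hand,
#'   assessment, task, trial, axis).
#' @export
prepare_stage1_samples <- function(assessments,
                                   params = spectrogram_params()) {
  out <- vector("list", length(assessments) * 54L)
  j <- 0L
  for (a in assessments) {
    akey <- assessment_key(a$patient_id, a$visit, a$hand)
    for (s in a$signals) {
      spec <- preprocess_signal(s, params = params)
      j <- j + 1L
      out[[j]] <- list(x = spec$power, hint = encode_task_hint(s$task),
                       label = a$group, patient_id = a$patient_id,
                       visit = a$visit, hand = a$hand, assessment = akey,
                       task = s$task, trial = s$trial, axis = s$axis)
    }
  }
  out[seq_len(j)]
}
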