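bilinear_upsample <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  ri <- if (out_h == 1L) rep(1, out_h) else
    (seq_len(out_h) - 1) * (H - 1) / (out_h - 1) + 1
  ci <- if (out_w == 1L) rep(1, out_w) else
    (seq_len(out_w) - 1) * (W - 1) / (out_w - 1) + 1
  r0 <- pmin(floor(ri), H - 1L); r1 <- r0 + 1L; fr <- ri - r0
  c0 <- pmin(floor(ci), W - 1L); c1 <- c0 + 1L; fc <- ci - c0
  if (H == 1L) { r0 <- r1 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (W == 1L) { c0 <- c1 <- rep(1L, out_w); fc <- rep(0, out_w) }
  top <- m[r0, c0, drop = FALSE] * (1 - fr) + m[r1, c0, drop = FALSE] * fr
  bot <- m[r0, c1, drop = FALSE] * (1 - fr) + m[r1, c1, drop = FALSE] * fr
  sweep(top, 2L, 1 - fc, `*`) + sweep(bot, 2L, fc, `*`)
}

#' Grad-CAM saliency for the stage-1 network
#'
#' The target class's score is backpropagated (the other output node
#' zeroed) to the last convolutional layer's post-activation feature
#' maps. With a two-node softmax head the score is taken on the
#' discriminative scale -- the class log-odds, target logit minus the
#' other -- because the two logits' common mode cancels in the softmax
#' and carries no class evidence (backpropagating a raw logit can then
#' yield an all-negative, uninformative map). Channel weights are the
#' spatial averages of those gradients; the weighted sum of feature maps
#' is rectified, upsampled bilinearly to the spectrogram grid and min-max
#' normalised to `[0, 1]`. A degenerate map (zero gradient everywhere)
#' stays all-zero and is flagged.
#'
#' @param model a trained `stage1_model`.
#' @param spec network-scaled spectrogram (or matrix).
#' @param hint 6-bit task hint.
#' @param target_class "PD" or "ET": the class whose evidence is located.
#' @return a `saliency_map`: list(weights = bins x frames matrix in
#'   `[0, 1]`, target_class, degenerate flag).
#' @export
gradcam <- function(model, spec, hint, target_class = c("PD", "ET")) {
  target_class <- match.arg(target_class)
  x <- as_spec_matrix(spec)
  cf <- conv_forward(model, x, keep = TRUE)
  fwd <- dense_forward(model, matrix(cf$flat, 1L), matrix(hint, 1L))
  fwd$Fm <- matrix(cf$flat, 1L)
  # gradient of the class log-odds: z_target - z_other
  dZ5 <- if (target_class == "PD") matrix(c(1, -1), 1L) else
    matrix(c(-1, 1), 1L)
  bk <- dense_backward(model, fwd, dZ5)
  dA2 <- conv2_activation_grad(model, cf, bk$dFm[1L, ])
  w <- apply(dA2, 3L, mean)
  cam <- matrix(0, nrow(cf$A2), ncol(cf$A2))
  for (k in seq_along(w)) cam <- cam + w[k] * cf$A2[, , k]
  cam <- pmax(cam, 0)
  up <- bilinear_upsample(cam, nrow(x), ncol(x))
  rng <- range(up)
  degenerate <- rng[2] <= 0
  weights <- if (degenerate) up * 0 else
    (up - rng[1]) / (rng[2] - rng[1])
  structure(list(weights = weights, target_class = target_class,
                 degenerate = degenerate,
                 source = if (inherits(spec, "spectrogram")) spec$source),
            class = "saliency_map")
}

#' Streaming per-pixel saliency statistics of one group
#'
#' Accumulates per-pixel mean and variance (Welford's algorithm) over a
#' stream of saliency maps, so population statistics never require holding
#' all maps in memory.
#'
#' @param maps list of `saliency_map`s (or matrices) of one group.
#' @return a `group_saliency_stats`: mean grid, variance grid (n-1
#'   denominator), count n.
#' @export
group_saliency_stats <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps per group")
  n <- 0
  mean_g <- NULL; m2 <- NULL
  for (m in maps) {
    g <- if (inherits(m, "saliency_map")) m$weights else m
    if (is.null(mean_g)) {
      mean_g <- g * 0; m2 <- g * 0
    }
    n <- n + 1
    delta <- g - mean_g
    mean_g <- mean_g + delta / n
    m2 <- m2 + delta * (g - mean_g)
  }
  structure(list(mean = mean_g, variance = m2 / (n - 1), n = n),
            class = "group_saliency_stats")
}

#' Collect group saliency maps over a classified cohort
#'
#' Computes Grad-CAM maps (targeting each signal's true class) for all
#' signals belonging to correctly classified assessments and accumulates
#' them into per-class statistics. Scope defaults to the whole cohort.
#'
#' @param model a trained `stage1_model`.
#' @param samples prepared stage-1 samples ([prepare_stage1_samples()]).
#' @param correct_assessments character vector of assessment keys that the
#'   second stage classified correctly.
#' @return list(et, pd): [group_saliency_stats()] per true class.
#' @export
collect_group_maps <- function(model, samples, correct_assessments) {
  keep <- vapply(samples, `[[`, character(1), "assessment") %in%
    correct_assessments
  samples <- samples[keep]
  labs <- vapply(samples, `[[`, character(1), "label")
  make_maps <- function(sel) {
    lapply(samples[sel], function(s)
      gradcam(model, s$x, s$hint, target_class = s$label))
  }
  list(et = group_saliency_stats(make_maps(labs == "ET")),
       pd = group_saliency_stats(make_maps(labs == "PD")))
}

#' Pixel-wise two-sample z statistic between group saliency maps
#'
#' z = (gbar_ET - gbar_PD) / sqrt(var_ET/n_ET + var_PD/n_PD) per pixel.
#' Positive z marks pixels the network attends to more for ET, negative
#' for PD. Pixels with zero pooled variance get z = 0 and are counted in
#' the `zero_variance` attribute.
#'
#' @param et,pd `group_saliency_stats` for the ET and PD groups.
#' @return z matrix with attribute `zero_variance`.
#' @export
pixelwise_z <- function(et, pd) {
  stopifnot(inherits(et, "group_saliency_stats"),
            inherits(pd, "group_saliency_stats"))
  if (!all(dim(et$mean) == dim(pd$mean))) stop("shape mismatch")
  se2 <- et$variance / et$n + pd$variance / pd$n
  z <- (et$mean - pd$mean) / sqrt(se2)
  zero <- se2 <= 0
  z[zero] <- 0
  attr(z, "zero_variance") <- sum(zero)
  z
}

#' Significance masks from the z grid
#'
#' Thresholds the standard-normal CDF of z at alpha = 0.02 split over the
#' two tails: the ET mask selects pixels with Phi(z) > 1 - alpha/2
#' (= 0.99), the PD mask pixels with Phi(z) < alpha/2 (= 0.01). The two
#' masks are disjoint by construction. When group mean grids are supplied
#' the masked means (group mean zeroed outside its mask) are attached.
#'
#' @param z z-score matrix from [pixelwise_z()].
#' @param alpha two-sided significance level in (0, 1).
#' @param mean_et,mean_pd optional group mean saliency grids.
#' @return a `significance_masks` object: z, et_mask, pd_mask, alpha and
#'   (optionally) masked_mean_et / masked_mean_pd.
#' @export
significance_masks <- function(z, alpha = 0.02, mean_et = NULL,
                               mean_pd = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  phi <- stats::pnorm(z)
  et_mask <- phi > 1 - alpha / 2
  pd_mask <- phi < alpha / 2
  out <- list(z = z, et_mask = et_mask, pd_mask = pd_mask, alpha = alpha)
  if (!is.null(mean_et)) out$masked_mean_et <- mean_et * et_mask
  if (!is.null(mean_pd)) out$masked_mean_pd <- mean_pd * pd_mask
  structure(out, class = "significance_masks")
}

#' @export
print.significance_masks <- function(x, ...) {
  cat(sprintf("<significance_masks> alpha %.3f: %d ET pixels, %d PD pixels of %d\n",
              x$alpha, sum(x$et_mask), sum(x$pd_mask), length(x$z)))
  invisible(x)
}

# Mean 0-based frequency-bin index of a mask, weighted by mask membership.
mask_mean_freq_index <- function(mask) {
  if (!any(mask)) return(NA_real_)
  idx <- row(mask) - 1L
  mean(idx[mask])
}

#' Omnibus normality test (skewness + kurtosis)
#'
#' D'Agostino-Pearson K^2: combines the transformed sample skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) z statistics into
#' K^2 = z_s^2 + z_k^2 ~ chi^2(2) under normality. Vectorised over the
#' columns of `x`. Constant columns are undefined and return NA.
#'
#' @param x numeric matrix, observations in rows, variables in columns.
#' @return list(statistic, p_value) per column.
#' @export
dagostino_pearson <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 8L) stop("normality test requires n >= 8")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  m2 <- colMeans(xc^2); m3 <- colMeans(xc^3); m4 <- colMeans(xc^4)
  const <- m2 <= .Machine$double.eps * pmax(1, mu^2)
  g1 <- m3 / m2^1.5
  # skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe-Glynn (1983) transformation
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z_k <- ((1 - 2 / (9 * a)) -
            ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_s^2 + z_k^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  k2[const] <- NA_real_
  p[const] <- NA_real_
  list(statistic = k2, p_value = p)
}

#' Per-pixel normality gate for the z-test
#'
#' Runs the D'Agostino-Pearson test on every pixel's saliency sample
#' before the two-sample z comparison. The gate is advisory: p-values are
#' reported, constant pixels are flagged as skipped, and the pipeline
#' proceeds regardless (the z-test's large-sample justification does not
#' hinge on per-pixel normality).
#'
#' @param maps list of `saliency_map`s (or matrices) of one group.
#' @param min_n minimum sample size for the test to be attempted.
#' @return matrix of p-values (NA where skipped), with attribute
#'   `n_skipped`; or NULL with a warning when n < `min_n`.
#' @export
normality_gate <- function(maps, min_n = 20L) {
  n <- length(maps)
  if (n < min_n) {
    warning(sprintf("normality gate skipped: n = %d < %d", n, min_n))
    return(NULL)
  }
  g1 <- if (inherits(maps[[1]], "saliency_map")) maps[[1]]$weights else
    maps[[1]]
  X <- matrix(0, n, length(g1))
  for (i in seq_len(n)) {
    m <- maps[[i]]
    X[i, ] <- as.numeric(if (inherits(m, "saliency_map")) m$weights else m)
  }
  res <- dagostino_pearson(X)
  p <- matrix(res$p_value, nrow(g1), ncol(g1))
  attr(p, "n_skipped") <- sum(is.na(res$p_value))
  p
}
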