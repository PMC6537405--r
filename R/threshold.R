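#' Intensity histogram of pooled pixels
#'
#' Equal-width bins spanning `[0, max(x)]` (the 8-bit convention, stable for
#' 16-bit data after flat-field correction). The histogram is the substrate
#' for automatic thresholding; thresholds are reported as bin edges.
#'
#' @param x numeric vector of non-negative intensities.
#' @param n_bins number of bins (default 256).
#' @param cap_quantile the bin range spans `[0, quantile(x, cap_quantile)]`
#'   (an order statistic, no interpolation); brighter pixels fall into the
#'   top bin. Capping at the 99.99th percentile instead of the absolute
#'   maximum keeps one freak-bright pixel (overlapping nuclei summing in a
#'   widefield stack) from stretching the range and squeezing the whole
#'   intensity structure into a couple of bins, which degrades any
#'   histogram-shape threshold. Set to 1 for the raw `[0, max]` span.
#' @return an object of class `intensity_histogram`: `counts` (length
#'   `n_bins`), `edges` (length `n_bins + 1`, ascending).
#' @export
intensity_histogram <- function(x, n_bins = 256L, cap_quantile = 0.9999) {
  stopifnot(length(x) > 0L, n_bins >= 2L,
            cap_quantile > 0, cap_quantile <= 1)
  if (!all(is.finite(x))) stop("non-finite intensities")
  if (min(x) < 0) stop("negative intensities")
  mx <- if (cap_quantile >= 1) max(x) else
    unname(stats::quantile(x, cap_quantile, type = 1L, names = FALSE))
  if (mx <= 0) mx <- max(x)
  if (mx <= 0) stop("no contrast: all intensities are zero")
  width <- mx / n_bins
  bin <- pmin(floor(x / width) + 1L, n_bins)
  structure(list(counts = tabulate(bin, nbins = n_bins),
                 edges = seq(0, mx, length.out = n_bins + 1L)),
            class = "intensity_histogram")
}

#' Yen's maximum-correlation threshold
#'
#' Maximizes the entropic-correlation criterion
#' \deqn{TC(t) = -\ln\frac{(\sum_{i\le t} p_i^2)(\sum_{i>t} p_i^2)}
#'                        {P(t)^2 (1-P(t))^2}}
#' over all interior cut points of the histogram, where \eqn{p_i} are the
#' normalized bin probabilities and \eqn{P(t)} the cumulative probability.
#' The criterion prefers thresholded images of low complexity, which on
#' stained specimens captures the in-focus nuclei and not the irregular
#' out-of-focus halo shapes. Ties break toward the lower threshold. The
#' returned threshold is the bin edge just above the selected cut bin.
#'
#' @param hist an [intensity_histogram()].
#' @return a single numeric threshold (a bin edge).
#' @export
yen_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  counts <- hist$counts
  if (sum(counts > 0) < 2L) stop("no contrast: single-valued histogram")
  p <- counts / sum(counts)
  P <- cumsum(p)
  A <- cumsum(p^2)
  B <- A[length(A)] - A
  nb <- length(p)
  t_idx <- seq_len(nb - 1L)
  # a valid cut leaves at least one pixel in each class (integer-exact)
  csum <- cumsum(counts)
  valid <- csum[t_idx] > 0L & csum[t_idx] < csum[nb]
  tiny <- .Machine$double.xmin
  tc <- rep(-Inf, nb - 1L)
  # suffix probability computed as its own sum (not 1 - P) so that valid
  # cuts can never see an exactly-zero complement through rounding
  Q <- rev(cumsum(rev(p)))[-1L]
  tc[valid] <- -log(pmax(A[t_idx][valid] * B[t_idx][valid], tiny)) +
    2 * log(P[t_idx][valid]) + 2 * log(Q[valid])
  # ties break toward the lower threshold; the criterion is exactly
  # constant across runs of empty bins, so snap within rounding noise
  top <- max(tc)
  best <- which(tc >= top - 1e-10 * max(1, abs(top)))[1L]
  hist$edges[best + 1L]
}

#' Robust-background threshold (alternative backend)
#'
#' Discards the dimmest and brightest `trim_fraction` of pixels and sets the
#' threshold at `mean + k_sd * SD` of the remainder. This mirrors the robust
#' background method commonly used in CellProfiler-style pipelines and is
#' offered as an alternative to [yen_threshold()].
#'
#' @param pixels numeric vector of intensities (at least 10).
#' @param trim_fraction fraction trimmed from each tail (default 0.05).
#' @param k_sd number of SDs above the trimmed mean (default 2).
#' @return a single numeric threshold.
#' @export
robust_background_threshold <- function(pixels, trim_fraction = 0.05, k_sd = 2) {
  stopifnot(length(pixels) >= 10L, trim_fraction >= 0, trim_fraction < 0.5)
  s <- sort(pixels)
  n <- length(s)
  k <- floor(trim_fraction * n)
  core <- if (k > 0) s[(k + 1L):(n - k)] else s
  m <- mean(core)
  sdev <- stats::sd(core)
  if (!is.finite(sdev) || sdev == 0) {
    message("robust background: zero spread after trimming; threshold = trimmed mean")
    return(m)
  }
  m + k_sd * sdev
}

#' The ten-fold signal-absence rule
#'
#' A stack whose threshold is less than `signal_fold` times its background
#' mean is declared devoid of meaningful biological signal (weak
#' signal-to-noise) and contributes zero foreground. "Less than" is strict:
#' exactly ten-fold passes.
#'
#' @param threshold estimated intensity threshold.
#' @param background_mean mean intensity of sub-threshold pixels (`>= 0`).
#' @param signal_fold required fold over background (default 10).
#' @return `TRUE` if the stack has signal.
#' @export
apply_signal_rule <- function(threshold, background_mean, signal_fold = 10) {
  stopifnot(background_mean >= 0)
  threshold >= signal_fold * background_mean
}

#' Estimate one threshold per stack from its central z-slices
#'
#' Out-of-focus halos concentrate at the extremes of the z-stack, so the
#' threshold is estimated only from the central block of slices: the
#' histogram of the central `ceiling(central_fraction * n_slices)` slices
#' (at least 1) is pooled, the threshold computed on it, and that single
#' threshold applied to every slice of the stack. The background mean is the
#' mean of the pooled pixels strictly below the threshold, and the ten-fold
#' rule then decides whether the stack has signal at all. Degenerate
#' histograms (a blank, single-valued stack) yield `has_signal = FALSE` with
#' an infinite threshold (empty mask) rather than an error.
#'
#' @param planes list of corrected (non-negative) numeric matrices in z
#'   order, or an `image_stack`.
#' @param central_fraction fraction of slices in the central block (default
#'   0.2).
#' @param n_bins histogram bins (default 256).
#' @param signal_fold fold-over-background needed to accept signal.
#' @param method `"yen"` (default) or `"robust_background"`.
#' @return an object of class `threshold_decision`: `threshold`,
#'   `has_signal`, `background_mean`, `fold_over_background`,
#'   `central_slices` (1-based z indices), `method`.
#' @export
estimate_stack_threshold <- function(planes, central_fraction = 0.2,
                                     n_bins = 256L, signal_fold = 10,
                                     method = c("yen", "robust_background")) {
  method <- match.arg(method)
  if (inherits(planes, "image_stack")) planes <- planes$planes
  stopifnot(is.list(planes), length(planes) >= 1L,
            central_fraction > 0, central_fraction <= 1)
  n <- length(planes)
  m <- min(n, max(1L, ceiling(central_fraction * n)))
  start <- floor((n - m) / 2) + 1L
  central <- start:(start + m - 1L)
  px <- unlist(lapply(planes[central], as.vector), use.names = FALSE)
  dec <- function(threshold, has_signal, bg, fold, note = NULL) {
    structure(list(threshold = threshold, has_signal = has_signal,
                   background_mean = bg, fold_over_background = fold,
                   central_slices = central, method = method, note = note),
              class = "threshold_decision")
  }
  thr <- tryCatch({
    if (method == "yen") yen_threshold(intensity_histogram(px, n_bins))
    else robust_background_threshold(px)
  }, error = function(e) e)
  if (inherits(thr, "error")) {
    return(dec(Inf, FALSE, mean(px), 0, note = conditionMessage(thr)))
  }
  below <- px[px < thr]
  bg <- if (length(below)) mean(below) else 0
  fold <- thr / max(bg, .Machine$double.xmin)
  dec(thr, apply_signal_rule(thr, bg, signal_fold), bg, fold)
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf(
    "<threshold_decision> %s: threshold %.4g, background %.4g (%.1f-fold), %s\n",
    x$method, x$threshold, x$background_mean, x$fold_over_background,
    if (x$has_signal) "signal present" else "NO SIGNAL"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Foreground mask of one plane under a stack threshold
#'
#' Strictly-greater comparison (a plane equal to the threshold everywhere is
#' all background); a no-signal decision gives an all-false mask regardless
#' of the plane.
#'
#' @param plane corrected numeric matrix.
#' @param decision a [estimate_stack_threshold()] decision from the same
#'   stack's channel.
#' @return logical matrix of the same shape.
#' @export
segment_foreground <- function(plane, decision) {
  stopifnot(is.matrix(plane), inherits(decision, "threshold_decision"))
  if (!decision$has_signal)
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  plane > decision$threshold
}
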