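#' Illumination (flat-field) correction parameters
#'
#' Raw widefield planes carry a smooth center-bright bias (vignetting). The
#' correction estimates the background of each plane as a large-scale Gaussian
#' blur of the plane itself, subtracts it, and clamps negatives to zero
#' (negative intensity is impossible). `sigma_px` must be much larger than a
#' nucleus so that nuclei survive the subtraction; the default 50 px suits
#' 512-2048 px planes with ~5-10 px nucleus radii.
#'
#' @param sigma_px Gaussian scale of the background estimate, in pixels.
#' @param enabled if `FALSE`, [correct_illumination()] is the identity.
#' @param nucleus_radius_px optional expected nucleus radius; used only to
#'   warn when `sigma_px` is not comfortably larger than the nuclei.
#' @return an object of class `correction_params`.
#' @export
correction_params <- function(sigma_px = 50, enabled = TRUE,
                              nucleus_radius_px = NULL) {
  stopifnot(is.numeric(sigma_px), length(sigma_px) == 1L, sigma_px > 0)
  if (sigma_px < 5)
    warning("sigma_px < 5 px: background estimate will eat into nuclei")
  if (!is.null(nucleus_radius_px) && sigma_px < 2 * nucleus_radius_px)
    warning("sigma_px < 2 x nucleus radius: correction may suppress signal")
  structure(list(sigma_px = sigma_px, enabled = isTRUE(enabled)),
            class = "correction_params")
}

# 1D Gaussian tap weights, truncated at 4 sigma, normalized.
gaussian_taps <- function(sigma) {
  r <- ceiling(4 * sigma)
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# Dense n x n operator applying the 1D kernel with symmetric (reflective,
# edge-repeating) padding. Cached: the same (n, sigma) pair recurs for every
# plane of a run.
.blur_cache <- new.env(parent = emptyenv())

blur_operator_dense <- function(n, sigma) {
  w <- gaussian_taps(sigma)
  r <- (length(w) - 1L) %/% 2L
  idx <- seq_len(n)
  M <- matrix(0, n, n)
  for (k in seq_along(w)) {
    p <- idx + (k - 1L - r)
    # symmetric reflection: ... 2 1 | 1 2 ... n | n n-1 ...
    while (any(p < 1L) || any(p > n)) {
      p <- ifelse(p < 1L, 1L - p, p)
      p <- ifelse(p > n, 2L * n + 1L - p, p)
    }
    M[cbind(idx, p)] <- M[cbind(idx, p)] + w[k]
  }
  M
}

blur_operator <- function(n, sigma) {
  key <- paste0(n, "_", format(sigma, digits = 12))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- blur_operator_dense(n, sigma)
  fac <- list(M = M, Mt = t(M))
  .blur_cache[[key]] <- fac
  fac
}

#' Gaussian blur of a plane (reflective boundary)
#'
#' Separable Gaussian convolution with symmetric edge padding, used as the
#' background estimator for flat-field correction. Exposed because tests and
#' diagnostics want the background itself.
#'
#' @param plane numeric matrix.
#' @param sigma_px Gaussian scale in pixels.
#' @return numeric matrix of the same shape.
#' @export
gaussian_blur <- function(plane, sigma_px) {
  stopifnot(is.matrix(plane))
  Ry <- blur_operator(nrow(plane), sigma_px)
  Rx <- blur_operator(ncol(plane), sigma_px)
  Ry$M %*% plane %*% Rx$Mt
}

#' Flat-field illumination correction of one plane
#'
#' `output = plane - gaussian_blur(plane, sigma_px)`, elementwise, with every
#' negative value replaced by exactly zero. A constant plane therefore maps to
#' an (all but numerically) all-zero plane, and output is non-negative
#' everywhere. Correction is per-plane: every z-slice is treated
#' independently, matching the slice-by-slice analysis contract of the
#' pipeline.
#'
#' @param plane numeric matrix of finite, non-negative intensities.
#' @param params a [correction_params()] object.
#' @return numeric matrix, same shape, all values `>= 0`.
#' @export
correct_illumination <- function(plane, params = correction_params()) {
  stopifnot(is.matrix(plane), inherits(params, "correction_params"))
  if (!all(is.finite(plane))) stop("non-finite values in input plane")
  if (!params$enabled) return(plane)
  bg <- gaussian_blur(plane, params$sigma_px)
  out <- plane - bg
  out[out < 0] <- 0
  out
}
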