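# Spatial filters: mean, median, bilateral. All three share the same
# contract: numeric-matrix in, numeric-matrix out, same dimensions, values
# rounded half-up to integers, borders handled by edge replication so dark
# halos never leak into downstream projection profiles.

#' Kernel specification for windowed filters
#'
#' Window dimensions must be odd so the window centers on the processed
#' pixel; `a` and `b` are the half-width `(Kw - 1)/2` and half-height
#' `(Kh - 1)/2`.
#'
#' @param width,height odd window dimensions in pixels.
#' @return list of class `kernel_spec` with fields `width`, `height`,
#'   `a`, `b`.
#' @export
#' @examples
#' kernel_spec(3, 3)
kernel_spec <- function(width = 3L, height = width) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L || width %% 2L == 0L || height %% 2L == 0L) {
    stop("kernel dimensions must be odd and >= 1", call. = FALSE)
  }
  structure(list(width = width, height = height,
                 a = (width - 1L) %/% 2L, b = (height - 1L) %/% 2L),
            class = "kernel_spec")
}

as_kernel_spec <- function(k) {
  if (inherits(k, "kernel_spec")) return(k)
  if (is.numeric(k) && length(k) %in% c(1L, 2L)) {
    return(kernel_spec(k[[1L]], k[[length(k)]]))
  }
  stop("supply a kernel_spec() or a (width, height) pair", call. = FALSE)
}

#' Bilateral filter parameters
#'
#' The spatial kernel is a Gaussian in Euclidean pixel distance with
#' standard deviation `sigma_spatial`; the range kernel is a Gaussian in
#' the neighbor-minus-center intensity difference with standard deviation
#' `sigma_range` (intensity levels).
#'
#' @param window_radius neighborhood radius in pixels (window is
#'   `(2r+1) x (2r+1)`); radius 0 reduces the filter to the identity.
#' @param sigma_spatial spatial Gaussian sd, pixels; must be positive.
#' @param sigma_range range Gaussian sd, intensity levels; must be positive.
#' @return list of class `bilateral_params`.
#' @export
bilateral_params <- function(window_radius = 4L, sigma_spatial = 2,
                             sigma_range = 30) {
  window_radius <- as.integer(window_radius)
  if (window_radius < 0L) stop("window_radius must be >= 0", call. = FALSE)
  if (!(sigma_spatial > 0) || !(sigma_range > 0)) {
    stop("sigmas must be positive", call. = FALSE)
  }
  structure(list(window_radius = window_radius,
                 sigma_spatial = sigma_spatial,
                 sigma_range = sigma_range),
            class = "bilateral_params")
}

#' Mean (box) filter
#'
#' Replaces each pixel by the arithmetic mean of its `width x height`
#' neighborhood, rounded half-up. Borders are edge-replicated.
#'
#' @param img grayscale image matrix (values in `[0, 255]`).
#' @param k a [kernel_spec()] or `(width, height)` pair; default 3x3.
#' @return filtered image, same dimensions.
#' @export
#' @examples
#' img <- matrix(c(0, 0, 0, 0, 90, 0, 0, 0, 0), 3, 3)
#' mean_filter(img, kernel_spec(3, 3))
mean_filter <- function(img, k = kernel_spec(3L, 3L)) {
  assert_gray(img)
  k <- as_kernel_spec(k)
  .mean_filter_cpp(img, k$width, k$height)
}

#' Median filter
#'
#' Replaces each pixel by the median of its neighborhood; with an odd
#' window pixel count this is an exact order statistic, so impulses
#' vanish while edges are preserved. Borders are edge-replicated.
#'
#' @inheritParams mean_filter
#' @return filtered image, same dimensions.
#' @export
median_filter <- function(img, k = kernel_spec(3L, 3L)) {
  assert_gray(img)
  k <- as_kernel_spec(k)
  .median_filter_cpp(img, k$width, k$height)
}

#' Bilateral filter
#'
#' Edge-preserving smoothing: each output pixel is a normalized weighted
#' mean over the window, the weight being the product of a spatial
#' Gaussian in pixel distance and a range Gaussian in the
#' neighbor-minus-center intensity difference. Pixels across a strong
#' edge get near-zero range weight, so edges survive while flat regions
#' are smoothed.
#'
#' @param img grayscale image matrix.
#' @param p a [bilateral_params()].
#' @return filtered image, same dimensions.
#' @export
bilateral_filter <- function(img, p = bilateral_params()) {
  assert_gray(img)
  if (!inherits(p, "bilateral_params")) {
    stop("`p` must be a bilateral_params()", call. = FALSE)
  }
  .bilateral_filter_cpp(img, p$window_radius, p$sigma_spatial, p$sigma_range)
}
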