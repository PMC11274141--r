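# Interdental edge-enhancement pipeline: median filter -> bilateral
# filter -> adaptive binarization -> binary morphology -> Canny edge
# detection -> colored overlay on the original crop. Calculus presents
# as subtle bright deposits at proximal tooth edges; the pipeline's job
# is to make those edge structures explicit before classification.

#' Enhancement configuration
#'
#' @param median_kernel [kernel_spec()] for the median stage.
#' @param bilateral a [bilateral_params()].
#' @param adaptive an [adaptive_params()].
#' @param se [structuring_element()] for the morphology stage.
#' @param morph_order character vector over `"opening"`/`"closing"`,
#'   applied left to right; default closing then opening (fill pinholes
#'   first, then drop specks).
#' @param canny_low,canny_high hysteresis thresholds on the Sobel
#'   gradient magnitude; `canny_low < canny_high`. Defaults 50/150, the
#'   common 1:3 heuristic on the 8-bit scale.
#' @param overlay_color `(R, G, B)` in 0-255; default pure green.
#' @param canny_input `"morphology"` (default: Canny sees the
#'   morphology output) or `"grayscale"` (Canny sees the bilateral
#'   output directly).
#' @return list of class `enhance_config`.
#' @export
enhance_config <- function(median_kernel = kernel_spec(3L, 3L),
                           bilateral = bilateral_params(),
                           adaptive = adaptive_params(),
                           se = se_cross(3L),
                           morph_order = c("closing", "opening"),
                           canny_low = 50,
                           canny_high = 150,
                           overlay_color = c(0L, 255L, 0L),
                           canny_input = c("morphology", "grayscale")) {
  if (!(canny_low < canny_high)) {
    stop("canny_low must be strictly below canny_high", call. = FALSE)
  }
  if (!all(morph_order %in% c("opening", "closing"))) {
    stop("morph_order entries must be 'opening' or 'closing'", call. = FALSE)
  }
  if (length(overlay_color) != 3L || any(overlay_color < 0) ||
      any(overlay_color > 255)) {
    stop("overlay_color must be three values in [0, 255]", call. = FALSE)
  }
  structure(list(median_kernel = as_kernel_spec(median_kernel),
                 bilateral = bilateral,
                 adaptive = adaptive,
                 se = check_se(se),
                 morph_order = morph_order,
                 canny_low = canny_low,
                 canny_high = canny_high,
                 overlay_color = as.numeric(overlay_color),
                 canny_input = match.arg(canny_input)),
            class = "enhance_config")
}

#' Canny edge detection
#'
#' Standard stages: 3x3 Sobel gradient, direction-quantized non-maximum
#' suppression (thinning edges to single-pixel lines), and
#' double-threshold hysteresis — pixels at or above `high` seed edges,
#' which grow through 8-connected pixels at or above `low`. No Gaussian
#' pre-smoothing is applied; in the enhancement pipeline the median and
#' bilateral stages have already denoised the crop.
#'
#' @param img grayscale or binary image matrix.
#' @param low,high hysteresis thresholds on gradient magnitude,
#'   `low < high`.
#' @return binary image; white (255) marks edges.
#' @export
canny_edges <- function(img, low = 50, high = 150) {
  assert_gray(img)
  if (!(low < high)) {
    stop("`low` must be strictly below `high`", call. = FALSE)
  }
  .canny_cpp(img, low, high)
}

#' Sobel gradient magnitude
#'
#' The gradient stage of [canny_edges()], exposed for inspection.
#'
#' @param img grayscale image matrix.
#' @return numeric matrix of gradient magnitudes.
#' @export
sobel_magnitude <- function(img) {
  assert_gray(img)
  .sobel_mag_cpp(img)
}

#' Overlay an edge mask onto a grayscale image in color
#'
#' The grayscale raster is replicated to three channels; pixels where
#' the mask is white are replaced by `color`, every other pixel stays
#' bit-identical to the replicated original.
#'
#' @param original grayscale image matrix.
#' @param edges binary edge mask of the same dimensions.
#' @param color `(R, G, B)` replacement, 0-255.
#' @return `height x width x 3` numeric array.
#' @export
overlay_edges <- function(original, edges, color = c(0, 255, 0)) {
  assert_gray(original)
  assert_binary(edges, "edges")
  if (!all(dim(original) == dim(edges))) {
    stop("image and edge mask dimensions differ", call. = FALSE)
  }
  rgb <- array(original, dim = c(dim(original), 3L))
  sel <- edges == 255
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[sel] <- color[ch]
    rgb[, , ch] <- plane
  }
  rgb
}

#' Run the full enhancement pipeline on a tooth crop
#'
#' Stage order is fixed: median filter, bilateral filter, adaptive
#' binarization, morphology (in `cfg$morph_order`), Canny, overlay onto
#' the original crop. Deterministic given the configuration. Set
#' `keep_stages = TRUE` to retain every intermediate raster.
#'
#' @param crop a [tooth_crop()] or plain grayscale matrix.
#' @param cfg an [enhance_config()].
#' @param keep_stages retain intermediates under `$stages`?
#' @return list of class `enhanced_crop`: `rgb` (H x W x 3 array),
#'   `edge_mask` (binary), `source` (the input crop), optionally
#'   `stages`.
#' @export
#' @examples
#' tc <- generate_tooth_crop(48, 64, with_calculus = TRUE, seed = 3)
#' out <- enhance_tooth(tc$image)
#' sum(out$edge_mask == 255) > 0
enhance_tooth <- function(crop, cfg = enhance_config(), keep_stages = FALSE) {
  img <- if (inherits(crop, "tooth_crop")) crop$image else crop
  assert_gray(img)
  if (!inherits(cfg, "enhance_config")) {
    stop("`cfg` must be an enhance_config()", call. = FALSE)
  }
  run <- function(stage, fn) {
    tryCatch(fn(), error = function(e) stop_stage(stage, conditionMessage(e)))
  }
  med <- run("median", function() median_filter(img, cfg$median_kernel))
  bil <- run("bilateral", function() bilateral_filter(med, cfg$bilateral))
  bin <- run("adaptive_binarize", function() binarize_adaptive(bil, cfg$adaptive))
  morph <- bin
  for (op in cfg$morph_order) {
    morph <- run(op, function() {
      if (op == "opening") opening(morph, cfg$se) else closing(morph, cfg$se)
    })
  }
  canny_src <- if (cfg$canny_input == "morphology") morph else bil
  edges <- run("canny", function() canny_edges(canny_src, cfg$canny_low,
                                               cfg$canny_high))
  rgb <- run("overlay", function() overlay_edges(img, edges, cfg$overlay_color))
  out <- list(rgb = rgb, edge_mask = edges,
              source = if (inherits(crop, "tooth_crop")) crop else
                tooth_crop(img, bbox(0, 0, ncol(img), nrow(img)), "upper",
                           "whole"))
  if (keep_stages) {
    out$stages <- list(median = med, bilateral = bil,
                       adaptive_binarize = bin, morphology = morph,
                       canny = edges)
  }
  structure(out, class = "enhanced_crop")
}
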