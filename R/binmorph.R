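# Binarization (global threshold and adaptive local-mean) and binary
# mathematical morphology on the white (255) set.

#' Global threshold binarization
#'
#' Pixels strictly greater than `threshold` become white (255), all
#' others black (0). The default 170 is the value used to simplify
#' bitewing images before projection-profile segmentation.
#'
#' @param img grayscale image matrix.
#' @param threshold intensity cut in `[0, 255]`; strict `>` rule.
#' @return binary image.
#' @export
#' @examples
#' binarize_global(matrix(c(170, 171), 1, 2), 170)  # -> 0, 255
binarize_global <- function(img, threshold = 170) {
  assert_gray(img)
  if (threshold < 0 || threshold > 255) {
    stop("threshold must lie in [0, 255]", call. = FALSE)
  }
  out <- matrix(0, nrow(img), ncol(img))
  out[img > threshold] <- 255
  out
}

#' Adaptive threshold parameters
#'
#' @param block_size odd edge length of the local window, pixels; >= 3.
#' @param offset_c signed offset subtracted from the local mean before
#'   comparison; positive values make the threshold more permissive.
#' @return list of class `adaptive_params`.
#' @export
adaptive_params <- function(block_size = 15L, offset_c = 0) {
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L) {
    stop("block_size must be odd and >= 3", call. = FALSE)
  }
  structure(list(block_size = block_size, offset_c = offset_c),
            class = "adaptive_params")
}

#' Adaptive (local mean) binarization
#'
#' A pixel becomes white when it exceeds the mean of its
#' `block_size x block_size` neighborhood minus `offset_c`. Local
#' thresholds compensate for uneven illumination across a radiograph.
#' Borders are edge-replicated for the local mean.
#'
#' @param img grayscale image matrix.
#' @param p an [adaptive_params()].
#' @return binary image.
#' @export
binarize_adaptive <- function(img, p = adaptive_params()) {
  assert_gray(img)
  if (!inherits(p, "adaptive_params")) {
    stop("`p` must be an adaptive_params()", call. = FALSE)
  }
  m <- .box_mean_cpp(img, p$block_size)
  out <- matrix(0, nrow(img), ncol(img))
  out[img > m - p$offset_c] <- 255
  out
}

#' Structuring elements
#'
#' A structuring element is a small logical mask with an origin cell; it
#' defines the neighborhood swept over the image by erosion and
#' dilation. `se_cross()` activates the center row and column (4-connected
#' neighborhood at size 3); `se_square()` activates every cell.
#'
#' @param size odd edge length.
#' @param mask logical matrix for a custom element.
#' @param origin 0-based `(row, col)` of the origin inside the mask;
#'   defaults to the center.
#' @return list of class `structuring_element` with fields `mask`,
#'   `origin`.
#' @export
structuring_element <- function(mask, origin = NULL) {
  if (!is.matrix(mask) || !is.logical(mask) || !any(mask)) {
    stop("mask must be a logical matrix with at least one TRUE cell",
         call. = FALSE)
  }
  if (is.null(origin)) {
    origin <- c((nrow(mask) - 1L) %/% 2L, (ncol(mask) - 1L) %/% 2L)
  }
  origin <- as.integer(origin)
  if (origin[1L] < 0L || origin[1L] >= nrow(mask) ||
      origin[2L] < 0L || origin[2L] >= ncol(mask)) {
    stop("origin must lie inside the mask", call. = FALSE)
  }
  structure(list(mask = mask, origin = origin), class = "structuring_element")
}

#' @rdname structuring_element
#' @export
se_cross <- function(size = 3L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("size must be odd", call. = FALSE)
  m <- matrix(FALSE, size, size)
  c0 <- (size + 1L) %/% 2L
  m[c0, ] <- TRUE
  m[, c0] <- TRUE
  structuring_element(m)
}

#' @rdname structuring_element
#' @export
se_square <- function(size = 3L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("size must be odd", call. = FALSE)
  structuring_element(matrix(TRUE, size, size))
}

#' Reflect a structuring element through its origin
#'
#' Needed to state erosion/dilation duality exactly:
#' `dilate(A, B)` complement equals `erode(A complement, reflect(B))`.
#'
#' @param se a [structuring_element()].
#' @return the reflected element.
#' @export
se_reflect <- function(se) {
  m <- se$mask[rev(seq_len(nrow(se$mask))), rev(seq_len(ncol(se$mask))),
               drop = FALSE]
  structuring_element(m, c(nrow(m) - 1L - se$origin[1L],
                           ncol(m) - 1L - se$origin[2L]))
}

check_se <- function(se) {
  if (!inherits(se, "structuring_element")) {
    stop("`se` must be a structuring_element()", call. = FALSE)
  }
  se
}

#' Binary dilation and erosion
#'
#' Set-theoretic Minkowski operations on the white (255) set. Everything
#' outside the raster counts as background, so erosion shrinks white
#' regions touching the border.
#'
#' @param img binary image (`{0, 255}`).
#' @param se a [structuring_element()].
#' @return binary image.
#' @export
dilate <- function(img, se = se_cross(3L)) {
  assert_binary(img)
  check_se(se)
  .dilate_cpp(img, se$mask, se$origin[1L], se$origin[2L])
}

#' @rdname dilate
#' @export
erode <- function(img, se = se_cross(3L)) {
  assert_binary(img)
  check_se(se)
  .erode_cpp(img, se$mask, se$origin[1L], se$origin[2L])
}

#' Morphological opening and closing
#'
#' Opening (erosion then dilation) removes small white objects and
#' spurs; closing (dilation then erosion) fills small holes and gaps.
#' Both compose the set-theoretic operations on the plane: the image is
#' padded with background before the first operation and cropped after
#' the second, so intermediate white pixels falling outside the raster
#' are not lost. This preserves the lattice identities exactly — both
#' operators are idempotent, opening is anti-extensive and closing
#' extensive on the white set.
#'
#' @inheritParams dilate
#' @return binary image.
#' @export
opening <- function(img, se = se_cross(3L)) {
  with_se_pad(img, se, function(p) dilate(erode(p, se), se))
}

#' @rdname opening
#' @export
closing <- function(img, se = se_cross(3L)) {
  with_se_pad(img, se, function(p) erode(dilate(p, se), se))
}

# run a composed morphological operation on a background-padded copy,
# then crop back to the original raster
with_se_pad <- function(img, se, fn) {
  assert_binary(img)
  check_se(se)
  pr <- nrow(se$mask); pc <- ncol(se$mask)
  padded <- matrix(0, nrow(img) + 2L * pr, ncol(img) + 2L * pc)
  padded[pr + seq_len(nrow(img)), pc + seq_len(ncol(img))] <- img
  out <- fn(padded)
  out[pr + seq_len(nrow(img)), pc + seq_len(ncol(img)), drop = FALSE]
}
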