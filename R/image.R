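# Shared validation helpers for the matrix-based image carrier.

#' Validate a grayscale image matrix
#'
#' Checks that `img` is a non-empty numeric matrix with all values in
#' `[0, 255]`, and returns it invisibly. Used at the boundary of every
#' image-consuming function.
#'
#' @param img object to check.
#' @param arg name used in error messages.
#' @return `img`, invisibly.
#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` must contain finite values in [0, 255]", arg), call. = FALSE)
  }
  invisible(img)
}

#' @rdname assert_gray
#' @keywords internal
assert_binary <- function(img, arg = "img") {
  assert_gray(img, arg)
  if (!all(img %in% c(0, 255))) {
    stop(sprintf("`%s` must be binary: values in {0, 255}", arg), call. = FALSE)
  }
  invisible(img)
}

#' Is an image binary?
#'
#' @param img numeric matrix.
#' @return `TRUE` when every pixel is 0 or 255.
#' @export
is_binary_image <- function(img) {
  is.matrix(img) && is.numeric(img) && all(img %in% c(0, 255))
}

clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Construct a bounding box
#'
#' Boxes are 0-based and half-open: the box covers pixel columns
#' `x0 .. x1 - 1` and rows `y0 .. y1 - 1`.
#'
#' @param x0,y0 inclusive top-left corner (column, row), 0-based.
#' @param x1,y1 exclusive bottom-right corner.
#' @return named numeric vector of class `bbox`.
#' @export
bbox <- function(x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1)) {
    stop("bbox requires x0 < x1 and y0 < y1", call. = FALSE)
  }
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "bbox")
}

#' Extract a box from an image
#'
#' @param img grayscale image matrix.
#' @param box a [bbox()] (0-based half-open pixel coordinates).
#' @return the sub-matrix covered by `box`.
#' @export
crop_image <- function(img, box) {
  assert_gray(img)
  rows <- (box[["y0"]] + 1L):box[["y1"]]
  cols <- (box[["x0"]] + 1L):box[["x1"]]
  if (box[["y1"]] > nrow(img) || box[["x1"]] > ncol(img) ||
      box[["y0"]] < 0 || box[["x0"]] < 0) {
    stop("box exceeds image bounds", call. = FALSE)
  }
  img[rows, cols, drop = FALSE]
}

# Structured stage-tagged errors so pipeline callers can report which
# processing stage failed.
stop_stage <- function(stage, message) {
  cond <- structure(
    class = c("bitewing_stage_error", "error", "condition"),
    list(message = sprintf("[stage %s] %s", stage, message),
         call = sys.call(-1), stage = stage)
  )
  stop(cond)
}

# Evaluate an RNG-consuming expression under a local seed, restoring the
# caller's RNG state so seeded generators never perturb a session.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
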