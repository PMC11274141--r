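# Projection-profile single-tooth segmentation: mean filter, global
# binarization, horizontal profile to split jaws at the dark occlusal
# band, per-jaw vertical profiles to find interdental valleys, margin-
# padded boxes, and vertical halving of each tooth crop. Cut decisions
# are made on the filtered/binarized raster but crops are always taken
# from the original grayscale image.

#' Projection profile
#'
#' Accumulated pixel sums per row (`axis = "horizontal"`) or per column
#' (`axis = "vertical"`). Dark valleys in these profiles mark the
#' occlusal band between jaws and the interdental gaps between teeth.
#'
#' @param img grayscale or binary image matrix.
#' @param axis `"horizontal"` (per-row sums) or `"vertical"` (per-column
#'   sums).
#' @return list of class `projection_profile` with `axis`, `values`,
#'   `source_dims`.
#' @export
#' @examples
#' m <- matrix(0, 4, 4); m[, 3] <- 255
#' projection_profile(m, "vertical")$values
projection_profile <- function(img, axis = c("horizontal", "vertical")) {
  assert_gray(img)
  axis <- match.arg(axis)
  values <- if (axis == "horizontal") rowSums(img) else colSums(img)
  structure(list(axis = axis, values = unname(values),
                 source_dims = c(rows = nrow(img), cols = ncol(img))),
            class = "projection_profile")
}

#' Locate the jaw split row
#'
#' Returns the 0-based row index of the global minimum of a horizontal
#' profile, searched within the central band of rows (default the
#' central 50%) so dark image borders cannot masquerade as the occlusal
#' gap. Ties (a flat dark band) are broken by the midmost tied index.
#'
#' @param profile a horizontal [projection_profile()].
#' @param central_frac fraction of rows, centered, to search within.
#' @return 0-based row index.
#' @export
find_jaw_split <- function(profile, central_frac = 0.5) {
  if (!inherits(profile, "projection_profile") ||
      profile$axis != "horizontal") {
    stop("`profile` must be a horizontal projection_profile", call. = FALSE)
  }
  v <- profile$values
  n <- length(v)
  if (n == 0L) stop("empty profile", call. = FALSE)
  skip <- as.integer(floor(n * (1 - central_frac) / 2))
  lo <- skip + 1L; hi <- n - skip
  window <- v[lo:hi]
  tied <- which(window == min(window))       # 1-based within window
  pick <- tied[(length(tied) + 1L) %/% 2L]   # midmost tie rule
  (lo - 1L) + pick - 1L                      # back to 0-based rows
}

#' Find interdental gap cuts
#'
#' Maximal runs of consecutive columns whose accumulated sum falls
#' strictly below `valley_threshold` are each collapsed to a single cut
#' at the run's center column. Runs touching either image border are
#' discarded so dark margins are not reported as interdental gaps. The
#' default threshold of 400 is on the binary profile scale (white
#' counted as 255), where it admits columns holding at most one white
#' pixel.
#'
#' @param profile a vertical [projection_profile()].
#' @param valley_threshold accumulated-sum cutoff (>= 0).
#' @return integer vector of 0-based cut columns (possibly empty),
#'   strictly increasing.
#' @export
find_gap_cuts <- function(profile, valley_threshold = 400) {
  if (!inherits(profile, "projection_profile") ||
      profile$axis != "vertical") {
    stop("`profile` must be a vertical projection_profile", call. = FALSE)
  }
  if (valley_threshold < 0) {
    stop("valley_threshold must be >= 0", call. = FALSE)
  }
  below <- profile$values < valley_threshold
  n <- length(below)
  if (!any(below)) return(integer(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cuts <- integer(0)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (starts[i] == 1L || ends[i] == n) next  # border-touching valley
    cuts <- c(cuts, (starts[i] - 1L + ends[i] - 1L) %/% 2L)  # 0-based center
  }
  cuts
}

#' Expand cuts into margin-padded tooth boxes
#'
#' Consecutive cut columns (with the image borders prepended/appended)
#' bound one tooth each; every box is widened by `margin` pixels on both
#' sides and clipped to the image, so `n` cuts yield `n + 1` boxes. The
#' default margin of 50 px guards against truncating tooth edges where
#' calculus sits.
#'
#' @param cuts strictly increasing 0-based cut columns.
#' @param jaw_rows `(y0, y1)` half-open row range of the jaw strip.
#' @param margin pixels added on each x side before clipping.
#' @param image_width raster width in pixels.
#' @return list of [bbox()] objects.
#' @export
cuts_to_boxes <- function(cuts, jaw_rows, margin = 50, image_width) {
  if (length(cuts) > 1L && any(diff(cuts) <= 0)) {
    stop("cuts must be strictly increasing", call. = FALSE)
  }
  edges <- c(0, cuts, image_width)
  lapply(seq_len(length(edges) - 1L), function(i) {
    bbox(max(0, edges[i] - margin), jaw_rows[1L],
         min(image_width, edges[i + 1L] + margin), jaw_rows[2L])
  })
}

#' Tooth crop container
#'
#' @param image grayscale sub-image.
#' @param source_box [bbox()] in the source image.
#' @param jaw `"upper"` or `"lower"`.
#' @param side `"left"`, `"right"` or `"whole"`.
#' @return list of class `tooth_crop`.
#' @export
tooth_crop <- function(image, source_box, jaw, side = "whole") {
  assert_gray(image)
  structure(list(image = image, source_box = source_box,
                 jaw = jaw, side = side),
            class = "tooth_crop")
}

#' Halve a tooth crop vertically
#'
#' Calculus forms on the proximal (left/right) surfaces, so each tooth
#' is split into two equal vertical halves before enhancement. The left
#' half takes columns `[0, floor(w/2))`, the right half the remainder;
#' no pixel is lost or duplicated.
#'
#' @param crop a [tooth_crop()] with width >= 2.
#' @return list of two crops (`left`, `right`).
#' @export
halve_crop <- function(crop) {
  if (!inherits(crop, "tooth_crop")) {
    stop("`crop` must be a tooth_crop", call. = FALSE)
  }
  w <- ncol(crop$image)
  if (w < 2L) stop("crop width must be >= 2 to halve", call. = FALSE)
  half <- w %/% 2L
  b <- crop$source_box
  left <- tooth_crop(crop$image[, 1:half, drop = FALSE],
                     bbox(b[["x0"]], b[["y0"]], b[["x0"]] + half, b[["y1"]]),
                     crop$jaw, "left")
  right <- tooth_crop(crop$image[, (half + 1L):w, drop = FALSE],
                      bbox(b[["x0"]] + half, b[["y0"]], b[["x1"]], b[["y1"]]),
                      crop$jaw, "right")
  list(left = left, right = right)
}

#' Segmentation configuration
#'
#' @param mean_kernel [kernel_spec()] for the preprocessing mean filter.
#' @param binarize_threshold global threshold (default 170).
#' @param valley_threshold interdental valley cutoff on the binary
#'   vertical profile (default 400).
#' @param margin box padding in pixels (default 50).
#' @param central_frac central row fraction searched for the jaw split.
#' @param halve split each tooth crop into vertical halves?
#' @return list of class `segment_config`.
#' @export
segment_config <- function(mean_kernel = kernel_spec(3L, 3L),
                           binarize_threshold = 170,
                           valley_threshold = 400,
                           margin = 50,
                           central_frac = 0.5,
                           halve = TRUE) {
  structure(list(mean_kernel = as_kernel_spec(mean_kernel),
                 binarize_threshold = binarize_threshold,
                 valley_threshold = valley_threshold,
                 margin = margin,
                 central_frac = central_frac,
                 halve = halve),
            class = "segment_config")
}

#' Segment a bitewing image into single-tooth crops
#'
#' Pipeline: mean filter, global binarization, horizontal profile and
#' jaw split, per-jaw vertical profiles, interdental valley cuts,
#' margin-padded boxes, crops taken from the **original** grayscale
#' image, then optional vertical halving. Failures raise a condition of
#' class `bitewing_stage_error` naming the failing stage.
#'
#' @param img grayscale image matrix.
#' @param config a [segment_config()].
#' @return list of `tooth_crop` objects; attribute `diagnostics` holds
#'   the jaw split row and per-jaw cut columns.
#' @export
#' @examples
#' ph <- generate_bitewing(phantom_spec(teeth_per_jaw = 4, seed = 2))
#' crops <- segment_bitewing(ph$image)
#' length(crops)  # 2 jaws x 4 teeth x 2 halves
segment_bitewing <- function(img, config = segment_config()) {
  assert_gray(img)
  if (!inherits(config, "segment_config")) {
    stop("`config` must be a segment_config()", call. = FALSE)
  }
  smoothed <- mean_filter(img, config$mean_kernel)
  binary <- binarize_global(smoothed, config$binarize_threshold)

  hp <- projection_profile(binary, "horizontal")
  split_row <- tryCatch(find_jaw_split(hp, config$central_frac),
                        error = function(e) stop_stage("jaw_split",
                                                       conditionMessage(e)))
  H <- nrow(img); W <- ncol(img)
  if (split_row <= 0L || split_row >= H - 1L) {
    stop_stage("jaw_split", "jaw split row fell on the image border")
  }

  jaw_rows <- list(upper = c(0L, split_row),
                   lower = c(split_row, H))
  crops <- list()
  cuts_by_jaw <- list()
  for (jaw in c("upper", "lower")) {
    yr <- jaw_rows[[jaw]]
    strip <- binary[(yr[1L] + 1L):yr[2L], , drop = FALSE]
    vp <- projection_profile(strip, "vertical")
    cuts <- find_gap_cuts(vp, config$valley_threshold)
    cuts_by_jaw[[jaw]] <- cuts
    if (length(cuts) == 0L) {
      stop_stage("gap_cuts",
                 sprintf("no interdental valleys found in the %s jaw", jaw))
    }
    boxes <- cuts_to_boxes(cuts, yr, config$margin, W)
    for (b in boxes) {
      crop <- tooth_crop(crop_image(img, b), b, jaw, "whole")
      if (config$halve) {
        halves <- halve_crop(crop)
        crops <- c(crops, list(halves$left, halves$right))
      } else {
        crops <- c(crops, list(crop))
      }
    }
  }
  attr(crops, "diagnostics") <- list(jaw_split_row = split_row,
                                     cuts = cuts_by_jaw)
  crops
}
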