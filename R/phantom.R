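# Synthetic bitewing phantom: two rows of bright tooth-like blobs
# separated by a dark occlusal band, with dark interdental gaps, optional
# bright proximal crescents (simulated calculus), additive Gaussian
# noise, and exhaustive ground truth. The phantom exists to give every
# downstream stage a known answer; it makes no claim to anatomical
# realism beyond the valley structure the segmentation stage relies on.

#' Phantom specification
#'
#' All geometry is in pixels, intensities on the 8-bit scale. Teeth are
#' drawn as superellipses (rounded rectangles) inscribed in their
#' bounding boxes; per-tooth widths, heights and interdental gap widths
#' are drawn uniformly from the given ranges by the seeded generator.
#'
#' @param image_width,image_height raster dimensions.
#' @param teeth_per_jaw teeth per row (>= 1).
#' @param tooth_width_range,tooth_height_range,gap_width_range
#'   `(min, max)` pixel ranges.
#' @param jaw_band_height height of the dark occlusal band separating
#'   the jaws.
#' @param tooth_intensity,background_intensity 8-bit levels; tooth must
#'   exceed background.
#' @param noise_sigma sd of additive Gaussian noise (0 disables).
#' @param calculus_probability per-tooth probability of a bright
#'   proximal crescent.
#' @param seed integer driving the single pseudo-random stream.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_width = 600L, image_height = 400L,
                         teeth_per_jaw = 8L,
                         tooth_width_range = c(40L, 60L),
                         tooth_height_range = c(100L, 140L),
                         gap_width_range = c(6L, 14L),
                         jaw_band_height = 40L,
                         tooth_intensity = 200,
                         background_intensity = 60,
                         noise_sigma = 8,
                         calculus_probability = 0.3,
                         seed = 1L) {
  spec <- list(image_width = as.integer(image_width),
               image_height = as.integer(image_height),
               teeth_per_jaw = as.integer(teeth_per_jaw),
               tooth_width_range = as.integer(tooth_width_range),
               tooth_height_range = as.integer(tooth_height_range),
               gap_width_range = as.integer(gap_width_range),
               jaw_band_height = as.integer(jaw_band_height),
               tooth_intensity = tooth_intensity,
               background_intensity = background_intensity,
               noise_sigma = noise_sigma,
               calculus_probability = calculus_probability,
               seed = as.integer(seed))
  for (rng in c("tooth_width_range", "tooth_height_range", "gap_width_range")) {
    r <- spec[[rng]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L) {
      stop(sprintf("%s must be (min, max) with 1 <= min <= max", rng),
           call. = FALSE)
    }
  }
  if (spec$teeth_per_jaw < 1L) stop("teeth_per_jaw must be >= 1", call. = FALSE)
  if (!(spec$tooth_intensity > spec$background_intensity)) {
    stop("tooth_intensity must exceed background_intensity", call. = FALSE)
  }
  if (spec$calculus_probability < 0 || spec$calculus_probability > 1) {
    stop("calculus_probability must lie in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  n <- spec$teeth_per_jaw
  min_needed <- n * spec$tooth_width_range[1L] +
    (n - 1L) * spec$gap_width_range[1L]
  if (min_needed > spec$image_width) {
    stop(sprintf("geometry infeasible: %d teeth need at least %d columns, image has %d",
                 n, min_needed, spec$image_width), call. = FALSE)
  }
  max_h <- spec$tooth_height_range[2L] + spec$jaw_band_height %/% 2L + 2L
  if (2L * max_h > spec$image_height) {
    stop("geometry infeasible: teeth plus occlusal band exceed image height",
         call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

# superellipse (exponent 4) membership mask for a tooth bounding box;
# hard mask, no anti-aliasing, so a noiseless phantom holds exactly the
# intensities it was painted with
tooth_mask <- function(x0, y0, x1, y1) {
  w <- x1 - x0; h <- y1 - y0
  cx <- (x0 + x1 - 1) / 2; cy <- (y0 + y1 - 1) / 2
  xs <- x0:(x1 - 1L); ys <- y0:(y1 - 1L)
  u <- abs(2 * (xs - cx) / w)
  v <- abs(2 * (ys - cy) / h)
  outer(v^4, u^4, `+`) <= 1   # rows = ys, cols = xs
}

# one jaw's horizontal layout: widths, gaps, left margin (all sampled
# from the running RNG stream)
sample_layout <- function(spec) {
  n <- spec$teeth_per_jaw
  widths <- sample(spec$tooth_width_range[1L]:spec$tooth_width_range[2L],
                   n, replace = TRUE)
  gaps <- if (n > 1L) {
    sample(spec$gap_width_range[1L]:spec$gap_width_range[2L],
           n - 1L, replace = TRUE)
  } else integer(0)
  total <- sum(widths) + sum(gaps)
  if (total > spec$image_width) {
    stop(sprintf("geometry infeasible: sampled teeth and gaps span %d columns, image has %d",
                 total, spec$image_width), call. = FALSE)
  }
  left <- (spec$image_width - total) %/% 2L
  x0 <- integer(n); x1 <- integer(n)
  x <- left
  for (i in seq_len(n)) {
    x0[i] <- x
    x1[i] <- x + widths[i]
    x <- x1[i] + if (i < n) gaps[i] else 0L
  }
  gap_centers <- if (n > 1L) {
    # gap i occupies columns [x1[i], x0[i+1]); record its center column
    (x1[seq_len(n - 1L)] + x0[2L:n] - 1L) %/% 2L
  } else integer(0)
  list(x0 = x0, x1 = x1, heights =
         sample(spec$tooth_height_range[1L]:spec$tooth_height_range[2L],
                n, replace = TRUE),
       gap_centers = gap_centers)
}

draw_crescent <- function(img, mask_rows, mask_cols, mask, side, x0, x1,
                          y0, y1, level) {
  w <- x1 - x0; h <- y1 - y0
  rx <- max(3L, round(0.12 * w))
  ry <- max(4L, round(0.30 * h))
  cx <- if (side == "left") x0 else x1 - 1L
  cy <- (y0 + y1 - 1) / 2
  xs <- mask_cols; ys <- mask_rows
  d <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`)
  sel <- (d <= 1) & mask   # clipped to the tooth footprint: a bright rim
  img[ys + 1L, xs + 1L][sel] <- level
  img
}

#' Generate a synthetic bitewing image with ground truth
#'
#' Deterministic given the spec (which carries the seed): the same spec
#' yields a bit-identical raster and truth. The truth records the jaw
#' split row, per-jaw interdental gap center columns, per-tooth bounding
#' boxes (0-based, half-open) with jaw tags, and per-tooth calculus
#' flags.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` (grayscale matrix) and `truth`
#'   (list of class `phantom_truth`: `jaw_split_row`,
#'   `gap_centers_upper`, `gap_centers_lower`, `tooth_boxes` data frame
#'   with columns `x0, y0, x1, y1, jaw, tooth`, `calculus_flags`,
#'   `calculus_sides`).
#' @export
#' @examples
#' ph <- generate_bitewing(phantom_spec(teeth_per_jaw = 4, seed = 7))
#' dim(ph$image)
#' ph$truth$gap_centers_upper
generate_bitewing <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec()", call. = FALSE)
  }
  with_local_seed(spec$seed, {
    W <- spec$image_width; H <- spec$image_height
    band_h <- spec$jaw_band_height
    band_y0 <- (H - band_h) %/% 2L
    band_y1 <- band_y0 + band_h
    jaw_split_row <- band_y0 + band_h %/% 2L

    img <- matrix(spec$background_intensity, H, W)
    calculus_level <- min(255, spec$tooth_intensity + 40)

    boxes <- list()
    flags <- logical(0)
    sides <- character(0)
    gap_centers <- list(upper = integer(0), lower = integer(0))

    for (jaw in c("upper", "lower")) {
      lay <- sample_layout(spec)
      gap_centers[[jaw]] <- lay$gap_centers
      for (i in seq_len(spec$teeth_per_jaw)) {
        h <- lay$heights[i]
        if (jaw == "upper") { y1 <- band_y0; y0 <- y1 - h }
        else { y0 <- band_y1; y1 <- y0 + h }
        x0 <- lay$x0[i]; x1 <- lay$x1[i]
        mask <- tooth_mask(x0, y0, x1, y1)
        rows <- y0:(y1 - 1L); cols <- x0:(x1 - 1L)
        sub <- img[rows + 1L, cols + 1L]
        sub[mask] <- spec$tooth_intensity
        img[rows + 1L, cols + 1L] <- sub
        has_calc <- runif(1) < spec$calculus_probability
        side <- if (has_calc) sample(c("left", "right"), 1L) else NA_character_
        if (has_calc) {
          img <- draw_crescent(img, rows, cols, mask, side, x0, x1, y0, y1,
                               calculus_level)
        }
        boxes[[length(boxes) + 1L]] <-
          data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                     jaw = jaw, tooth = i, stringsAsFactors = FALSE)
        flags <- c(flags, has_calc)
        sides <- c(sides, side)
      }
    }

    if (spec$noise_sigma > 0) {
      img <- round(clamp8(img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)))
    }

    truth <- structure(
      list(jaw_split_row = jaw_split_row,
           gap_centers_upper = gap_centers$upper,
           gap_centers_lower = gap_centers$lower,
           tooth_boxes = do.call(rbind, boxes),
           calculus_flags = flags,
           calculus_sides = sides,
           band = c(y0 = band_y0, y1 = band_y1)),
      class = "phantom_truth")
    list(image = img, truth = truth)
  })
}

#' Generate a single synthetic tooth crop
#'
#' A centered superellipse tooth on a dark background, optionally with a
#' bright proximal crescent on a uniformly chosen side. The crescent's
#' mean intensity exceeds the tooth body's by 40 intensity levels
#' (before noise).
#'
#' @param width,height crop dimensions in pixels; both >= 16.
#' @param with_calculus draw the crescent?
#' @param seed integer seed.
#' @param noise_sigma additive Gaussian noise sd.
#' @return list with `image`, `with_calculus`, `crescent_box` (a [bbox()]
#'   around the crescent, or `NULL`).
#' @export
generate_tooth_crop <- function(width, height, with_calculus = FALSE,
                                seed = 1L, noise_sigma = 4) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 16L || height < 16L) {
    stop("crop dimensions must be >= 16 pixels", call. = FALSE)
  }
  with_local_seed(seed, {
    bg <- 60; body <- 200
    img <- matrix(bg, height, width)
    x0 <- round(width * 0.15); x1 <- width - x0
    y0 <- round(height * 0.1); y1 <- height - y0
    mask <- tooth_mask(x0, y0, x1, y1)
    rows <- y0:(y1 - 1L); cols <- x0:(x1 - 1L)
    sub <- img[rows + 1L, cols + 1L]
    sub[mask] <- body
    img[rows + 1L, cols + 1L] <- sub
    crescent_box <- NULL
    if (with_calculus) {
      side <- sample(c("left", "right"), 1L)
      img <- draw_crescent(img, rows, cols, mask, side, x0, x1, y0, y1,
                           min(255, body + 40))
      w <- x1 - x0; h <- y1 - y0
      rx <- max(3L, round(0.12 * w)); ry <- max(4L, round(0.30 * h))
      cx <- if (side == "left") x0 else x1 - 1L
      cy <- (y0 + y1 - 1L) %/% 2L
      crescent_box <- bbox(max(0L, cx - rx), max(0L, cy - ry),
                           min(width, cx + rx + 1L), min(height, cy + ry + 1L))
    }
    if (noise_sigma > 0) {
      img <- round(clamp8(img + matrix(rnorm(height * width, 0, noise_sigma),
                                       height, width)))
    }
    list(image = img, with_calculus = with_calculus,
         crescent_box = crescent_box)
  })
}

#' Serialize / read phantom ground truth
#'
#' Truth is written as JSON (a plain-text schema: scalar
#' `jaw_split_row`, integer vectors of gap centers, the tooth-box table,
#' logical calculus flags) so CLI runs can round-trip it.
#'
#' @param truth a `phantom_truth`.
#' @param path file path.
#' @return `read_phantom_truth()` returns the truth list.
#' @export
write_phantom_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_phantom_truth
#' @export
read_phantom_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$jaw_split_row <- as.integer(x$jaw_split_row)
  x$gap_centers_upper <- as.integer(x$gap_centers_upper)
  x$gap_centers_lower <- as.integer(x$gap_centers_lower)
  structure(x, class = "phantom_truth")
}
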