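# Raster and annotation I/O plus the structured configuration file.
# Supported raster formats: PNG and TIFF (8- or 16-bit input; output is
# always 8-bit PNG-style). Color inputs collapse to grayscale by the
# Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B.

#' Load a grayscale image
#'
#' Reads PNG or TIFF, converts color to grayscale by the Rec. 601 luma
#' weights, and rescales to the 8-bit range: the decoded `[0, 1]`
#' values (PNG 16-bit included) are multiplied by 255 and rounded
#' half-up, so full-range 16-bit data maps onto 0-255.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return grayscale image matrix.
#' @export
load_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop(sprintf(
                     "cannot read PNG %s: %s", path, conditionMessage(e)),
                     call. = FALSE)),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop(sprintf(
                      "cannot read TIFF %s: %s", path, conditionMessage(e)),
                      call. = FALSE)),
    stop(sprintf("unsupported image format '.%s' for %s (PNG and TIFF are supported)",
                 ext, path), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  floor(arr * 255 + 0.5)
}

#' Save an image
#'
#' Writes a grayscale matrix or an `H x W x 3` RGB array as PNG or
#' TIFF. PNG save-then-load round-trips 8-bit data bit-exactly.
#'
#' @param img grayscale matrix (values 0-255) or RGB array.
#' @param path destination path; extension selects the format.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  data <- img / 255
  if (is.matrix(img)) assert_gray(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(data, path),
    tif = ,
    tiff = tiff::writeTIFF(data, path),
    stop(sprintf("unsupported image format '.%s' for %s", ext, path),
         call. = FALSE)
  )
  invisible(path)
}

#' Read YOLO-format annotations
#'
#' Each line is `class cx cy w h` with center/size normalized to the
#' image dimensions. Boxes are returned in 0-based half-open pixel
#' coordinates: `x0 = (cx - w/2) * W`, `x1 = (cx + w/2) * W`, and
#' likewise for rows. Coordinates are kept fractional so that
#' write-then-read round-trips to within 1e-6 in normalized units.
#'
#' @param path annotation text file.
#' @param image_dims `(width, height)` in pixels.
#' @param confidence expect a sixth per-line confidence value (as in
#'   detector prediction files)?
#' @return data frame `class_id, x0, y0, x1, y1` (plus `confidence`
#'   when requested).
#' @export
read_yolo_annotations <- function(path, image_dims, confidence = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  W <- image_dims[1L]; H <- image_dims[2L]
  if (W <= 0 || H <= 0) stop("image dimensions must be positive", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    nf <- if (confidence) 6L else 5L
    if (length(parts) != nf || anyNA(vals)) {
      stop(sprintf("%s: malformed annotation at line %d: '%s'",
                   path, i, lines[i]), call. = FALSE)
    }
    cls <- vals[1L]; cx <- vals[2L]; cy <- vals[3L]; w <- vals[4L]; h <- vals[5L]
    if (cls < 0 || cls != floor(cls)) {
      stop(sprintf("%s: invalid class id at line %d", path, i), call. = FALSE)
    }
    tol <- 1e-9
    if (cx < -tol || cx > 1 + tol || cy < -tol || cy > 1 + tol ||
        w <= 0 || w > 1 + tol || h <= 0 || h > 1 + tol ||
        cx - w / 2 < -1e-6 || cx + w / 2 > 1 + 1e-6 ||
        cy - h / 2 < -1e-6 || cy + h / 2 > 1 + 1e-6) {
      stop(sprintf("%s: box outside the unit square at line %d", path, i),
           call. = FALSE)
    }
    row <- data.frame(class_id = as.integer(cls),
                      x0 = (cx - w / 2) * W, y0 = (cy - h / 2) * H,
                      x1 = (cx + w / 2) * W, y1 = (cy + h / 2) * H)
    if (confidence) {
      if (vals[6L] < 0 || vals[6L] > 1) {
        stop(sprintf("%s: confidence outside [0, 1] at line %d", path, i),
             call. = FALSE)
      }
      row$confidence <- vals[6L]
    }
    out[[i]] <- row
  }
  if (length(out) == 0L) {
    return(data.frame(class_id = integer(0), x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0),
                      confidence = if (confidence) numeric(0))[
                        , c("class_id", "x0", "y0", "x1", "y1",
                            if (confidence) "confidence"), drop = FALSE])
  }
  do.call(rbind, out)
}

#' Write YOLO-format annotations
#'
#' @param items data frame with `class_id, x0, y0, x1, y1` (pixel
#'   coordinates, half-open).
#' @param image_dims `(width, height)` in pixels.
#' @param path destination text file.
#' @return `path`, invisibly.
#' @export
write_yolo_annotations <- function(items, image_dims, path) {
  W <- image_dims[1L]; H <- image_dims[2L]
  if (W <= 0 || H <= 0) stop("image dimensions must be positive", call. = FALSE)
  lines <- character(nrow(items))
  for (i in seq_len(nrow(items))) {
    cx <- (items$x0[i] + items$x1[i]) / 2 / W
    cy <- (items$y0[i] + items$y1[i]) / 2 / H
    w <- (items$x1[i] - items$x0[i]) / W
    h <- (items$y1[i] - items$y0[i]) / H
    lines[i] <- sprintf("%d %.6f %.6f %.6f %.6f",
                        as.integer(items$class_id[i]), cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Default toolkit configuration
#'
#' One structured list with a section per processing module, matching
#' the YAML config file schema consumed by the command-line interface.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    phantom = list(image_width = 600L, image_height = 400L,
                   teeth_per_jaw = 8L,
                   tooth_width_range = c(40L, 60L),
                   tooth_height_range = c(100L, 140L),
                   gap_width_range = c(6L, 14L),
                   jaw_band_height = 40L,
                   tooth_intensity = 200, background_intensity = 60,
                   noise_sigma = 8, calculus_probability = 0.3),
    filters = list(mean_kernel = c(3L, 3L),
                   median_kernel = c(3L, 3L),
                   bilateral = list(window_radius = 4L, sigma_spatial = 2,
                                    sigma_range = 30)),
    adaptive = list(block_size = 15L, offset_c = 0),
    morphology = list(se_shape = "cross", se_size = 3L,
                      order = c("closing", "opening")),
    segmentation = list(binarize_threshold = 170, valley_threshold = 400,
                        margin = 50, central_frac = 0.5, halve = TRUE),
    enhancement = list(canny_low = 50, canny_high = 150,
                       overlay_color = c(0L, 255L, 0L),
                       canny_input = "morphology"),
    dataset = list(holdout_fraction = 0.2, train_fraction_of_rest = 0.7),
    metrics = list(iou_threshold = 0.5, ap_mode = "all_point")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML configuration file over the defaults
#'
#' Values present in the file override [default_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  merge_config(cfg, yaml::read_yaml(path))
}

#' Assemble typed parameter objects from a configuration list
#'
#' Turns the nested list returned by [load_config()] into the
#' [segment_config()] and [enhance_config()] objects the pipeline
#' functions consume.
#'
#' @param cfg configuration list.
#' @return list with elements `segment` and `enhance`.
#' @export
config_objects <- function(cfg) {
  se <- if (identical(cfg$morphology$se_shape, "square")) {
    se_square(cfg$morphology$se_size)
  } else {
    se_cross(cfg$morphology$se_size)
  }
  list(
    segment = segment_config(
      mean_kernel = kernel_spec(cfg$filters$mean_kernel[1L],
                                cfg$filters$mean_kernel[length(cfg$filters$mean_kernel)]),
      binarize_threshold = cfg$segmentation$binarize_threshold,
      valley_threshold = cfg$segmentation$valley_threshold,
      margin = cfg$segmentation$margin,
      central_frac = cfg$segmentation$central_frac,
      halve = cfg$segmentation$halve),
    enhance = enhance_config(
      median_kernel = kernel_spec(cfg$filters$median_kernel[1L],
                                  cfg$filters$median_kernel[length(cfg$filters$median_kernel)]),
      bilateral = bilateral_params(cfg$filters$bilateral$window_radius,
                                   cfg$filters$bilateral$sigma_spatial,
                                   cfg$filters$bilateral$sigma_range),
      adaptive = adaptive_params(cfg$adaptive$block_size,
                                 cfg$adaptive$offset_c),
      se = se,
      morph_order = cfg$morphology$order,
      canny_low = cfg$enhancement$canny_low,
      canny_high = cfg$enhancement$canny_high,
      overlay_color = cfg$enhancement$overlay_color,
      canny_input = cfg$enhancement$canny_input)
  )
}
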