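# Projection profiles, valley detection, box arithmetic, and recovery
# of phantom ground truth by the full segmentation pipeline.

test_that("projection profiles equal double-loop summation", {
  img <- rand_img(8, 8, 42)
  hp <- projection_profile(img, "horizontal")
  vp <- projection_profile(img, "vertical")
  expect_equal(hp$values, sapply(1:8, function(r) sum(img[r, ])))
  expect_equal(vp$values, sapply(1:8, function(c) sum(img[, c])))
  zeros <- matrix(0, 5, 7)
  expect_true(all(projection_profile(zeros, "vertical")$values == 0))
  one_col <- matrix(0, 6, 6); one_col[, 4] <- 255
  expect_equal(projection_profile(one_col, "vertical")$values,
               c(0, 0, 0, 255 * 6, 0, 0))
})

test_that("jaw split finds the central minimum with midmost tie-breaking", {
  mk <- function(v) structure(list(axis = "horizontal", values = v,
                                   source_dims = c(rows = length(v), cols = 1)),
                              class = "projection_profile")
  v <- rep(500, 100)
  v[41] <- 10  # 0-based row 40, unique interior minimum
  expect_identical(find_jaw_split(mk(v)), 40L)
  v2 <- rep(500, 100)
  v2[39:43] <- 10  # plateau over 0-based rows 38..42
  expect_identical(find_jaw_split(mk(v2)), 40L)
  # minima outside the central band are ignored
  v3 <- rep(500, 100)
  v3[2] <- 0
  v3[51] <- 100
  expect_identical(find_jaw_split(mk(v3)), 50L)
})

test_that("gap cuts collapse sub-threshold runs and drop border valleys", {
  mk <- function(v) structure(list(axis = "vertical", values = v,
                                   source_dims = c(rows = 1, cols = length(v))),
                              class = "projection_profile")
  expect_identical(find_gap_cuts(mk(c(900, 900, 0, 0, 0, 900, 900)), 400), 3L)
  expect_identical(find_gap_cuts(mk(rep(900, 7)), 400), integer(0))
  two <- c(900, 0, 0, 900, 900, 350, 900, 900)
  expect_identical(find_gap_cuts(mk(two), 400), c(1L, 5L))
  # border-touching valleys are not interdental gaps
  expect_identical(find_gap_cuts(mk(c(0, 0, 900, 0, 900, 0)), 400), 3L)
  expect_error(find_gap_cuts(mk(c(1, 2)), -1), ">= 0")
})

test_that("cuts expand to margin-padded clipped boxes", {
  boxes <- cuts_to_boxes(c(100, 200), c(0, 50), margin = 50, image_width = 300)
  xr <- t(sapply(boxes, function(b) c(b[["x0"]], b[["x1"]])))
  expect_equal(xr, rbind(c(0, 150), c(50, 250), c(150, 300)))
  # no cuts: one full-width box
  single <- cuts_to_boxes(integer(0), c(0, 50), 50, 300)
  expect_length(single, 1)
  expect_equal(single[[1]][["x1"]] - single[[1]][["x0"]], 300)
  # zero margin partitions the width exactly
  part <- cuts_to_boxes(c(80, 160), c(0, 50), 0, 240)
  expect_equal(sapply(part, function(b) b[["x1"]] - b[["x0"]]),
               c(80, 80, 80))
  expect_error(cuts_to_boxes(c(5, 5), c(0, 10), 0, 20), "increasing")
})

test_that("halving splits columns without loss or duplication", {
  img <- rand_img(10, 101, 8)
  crop <- tooth_crop(img, bbox(0, 0, 101, 10), "upper")
  h <- halve_crop(crop)
  expect_equal(ncol(h$left$image), 50)
  expect_equal(ncol(h$right$image), 51)
  expect_identical(cbind(h$left$image, h$right$image), img)
  expect_identical(h$left$side, "left")
  expect_identical(h$right$side, "right")
  even <- halve_crop(tooth_crop(rand_img(4, 100, 1), bbox(0, 0, 100, 4), "lower"))
  expect_equal(ncol(even$left$image), 50)
  narrow <- tooth_crop(matrix(1, 4, 1), bbox(0, 0, 1, 4), "upper")
  expect_error(halve_crop(narrow), ">= 2")
})

test_that("segmentation recovers phantom structure", {
  hits <- 0; total_gaps <- 0
  for (seed in 1:10) {
    n <- 6 + seed %% 5
    spec <- phantom_spec(image_width = 90L * n, teeth_per_jaw = n,
                         noise_sigma = 10, seed = seed)
    ph <- generate_bitewing(spec)
    crops <- segment_bitewing(ph$image)
    d <- attr(crops, "diagnostics")
    expect_lte(abs(d$jaw_split_row - ph$truth$jaw_split_row), 5)
    for (jaw in c("upper", "lower")) {
      truth_gaps <- ph$truth[[paste0("gap_centers_", jaw)]]
      cuts <- d$cuts[[jaw]]
      total_gaps <- total_gaps + length(truth_gaps)
      hits <- hits + sum(sapply(truth_gaps,
                                function(g) any(abs(cuts - g) <= 10)))
    }
    if (all(lengths(d$cuts) == n - 1)) {
      expect_length(crops, 4 * n)
    }
  }
  expect_gte(hits / total_gaps, 0.95)
})

test_that("crops are cut from the unfiltered original image", {
  ph <- generate_bitewing(phantom_spec(seed = 33))
  crops <- segment_bitewing(ph$image)
  for (cr in crops[c(1, length(crops) %/% 2, length(crops))]) {
    b <- cr$source_box
    expect_identical(cr$image,
                     ph$image[(b[["y0"]] + 1):b[["y1"]],
                              (b[["x0"]] + 1):b[["x1"]], drop = FALSE])
  }
})

test_that("a blank image fails with a stage-named diagnostic", {
  blank <- matrix(0, 120, 160)
  err <- tryCatch(segment_bitewing(blank), condition = function(c) c)
  expect_s3_class(err, "bitewing_stage_error")
  expect_identical(err$stage, "gap_cuts")
})

test_that("segmentation defaults follow the published operating point", {
  cfg <- segment_config()
  expect_equal(cfg$binarize_threshold, 170)
  expect_equal(cfg$valley_threshold, 400)
  expect_equal(cfg$margin, 50)
})
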