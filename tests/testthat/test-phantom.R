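# Synthetic bitewing phantom: construction counts, determinism, and
# consistency between the raster and its recorded ground truth.

test_that("phantom truth carries the counts forced by construction", {
  ph <- generate_bitewing(phantom_spec(teeth_per_jaw = 8, seed = 11))
  expect_equal(nrow(ph$truth$tooth_boxes), 16)
  expect_length(ph$truth$gap_centers_upper, 7)
  expect_length(ph$truth$gap_centers_lower, 7)
  expect_length(ph$truth$calculus_flags, 16)
  # boxes are disjoint within a jaw
  for (jaw in c("upper", "lower")) {
    b <- ph$truth$tooth_boxes[ph$truth$tooth_boxes$jaw == jaw, ]
    b <- b[order(b$x0), ]
    expect_true(all(b$x1[-nrow(b)] <= b$x0[-1]))
  }
  # the split row lies strictly between the jaws
  expect_true(all(ph$truth$tooth_boxes$y1[ph$truth$tooth_boxes$jaw == "upper"] <=
                    ph$truth$jaw_split_row))
  expect_true(all(ph$truth$tooth_boxes$y0[ph$truth$tooth_boxes$jaw == "lower"] >
                    ph$truth$jaw_split_row))
})

test_that("identical specs produce bit-identical phantoms", {
  s <- phantom_spec(teeth_per_jaw = 6, noise_sigma = 10, seed = 77)
  a <- generate_bitewing(s)
  b <- generate_bitewing(s)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the session RNG
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_bitewing(s)); after <- runif(3)
  expect_identical(before, after)
})

test_that("noiseless calculus-free phantom holds exactly two intensities", {
  ph <- generate_bitewing(phantom_spec(noise_sigma = 0,
                                       calculus_probability = 0, seed = 5))
  expect_identical(sort(unique(as.vector(ph$image))), c(60, 200))
  # every tooth box mean exceeds background by at least half the contrast
  for (i in seq_len(nrow(ph$truth$tooth_boxes))) {
    b <- ph$truth$tooth_boxes[i, ]
    region <- ph$image[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1]
    expect_gte(mean(region), 60 + (200 - 60) / 2)
  }
})

test_that("column sums dip at every recorded gap center", {
  ph <- generate_bitewing(phantom_spec(noise_sigma = 0,
                                       calculus_probability = 0, seed = 9))
  split <- ph$truth$jaw_split_row
  strips <- list(upper = ph$image[1:split, ],
                 lower = ph$image[(split + 1):nrow(ph$image), ])
  gaps <- list(upper = ph$truth$gap_centers_upper,
               lower = ph$truth$gap_centers_lower)
  for (jaw in names(strips)) {
    cs <- colSums(strips[[jaw]])
    for (g in gaps[[jaw]]) {
      # local minimum within +-2 columns of the recorded center
      win <- cs[(g - 1):(g + 3)]  # 0-based g -> 1-based g+1
      expect_lte(min(win), min(cs[g - 4], cs[g + 6]))
    }
  }
})

test_that("calculus-flagged teeth carry a crescent brighter than the body", {
  ph <- generate_bitewing(phantom_spec(noise_sigma = 0,
                                       calculus_probability = 1, seed = 21))
  expect_true(all(ph$truth$calculus_flags))
  expect_true(max(ph$image) > 200)  # crescent level above the tooth body
  tc0 <- generate_tooth_crop(48, 64, with_calculus = FALSE, seed = 4,
                             noise_sigma = 0)
  tc1 <- generate_tooth_crop(48, 64, with_calculus = TRUE, seed = 4,
                             noise_sigma = 0)
  expect_identical(sort(unique(as.vector(tc0$image))), c(60, 200))
  cb <- tc1$crescent_box
  crescent <- tc1$image[(cb[["y0"]] + 1):cb[["y1"]], (cb[["x0"]] + 1):cb[["x1"]]]
  body <- tc1$image[tc1$image == 200]
  expect_gt(mean(crescent[crescent > 60]), mean(body))
})

test_that("tooth crops reproduce a pinned raster for a fixed seed", {
  tc <- generate_tooth_crop(48, 64, with_calculus = TRUE, seed = 3)
  expect_identical(dim(tc$image), c(64L, 48L))
  expect_identical(sum(tc$image), 419590)
  expect_identical(tc$image[20, 10], 243)
  expect_identical(tc$image[32, 24], 196)
  expect_error(generate_tooth_crop(8, 64), ">= 16")
})

test_that("infeasible phantom geometry raises an explicit error", {
  expect_error(phantom_spec(image_width = 100, teeth_per_jaw = 8),
               "infeasible")
  expect_error(phantom_spec(tooth_intensity = 50, background_intensity = 60),
               "exceed")
  expect_error(phantom_spec(calculus_probability = 1.5), "\\[0, 1\\]")
})

test_that("phantom truth round-trips through its text serialization", {
  ph <- generate_bitewing(phantom_spec(teeth_per_jaw = 5, seed = 2))
  path <- tempfile(fileext = ".json")
  write_phantom_truth(ph$truth, path)
  back <- read_phantom_truth(path)
  expect_identical(back$jaw_split_row, ph$truth$jaw_split_row)
  expect_identical(back$gap_centers_upper, ph$truth$gap_centers_upper)
  expect_identical(back$gap_centers_lower, ph$truth$gap_centers_lower)
  expect_equal(back$tooth_boxes$x0, ph$truth$tooth_boxes$x0)
  expect_identical(as.logical(back$calculus_flags), ph$truth$calculus_flags)
})
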