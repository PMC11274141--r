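# IoU, detection matching, the three ratio metrics, and average
# precision against a cut-point enumeration oracle.

test_that("iou follows exact area arithmetic", {
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 1)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(20, 20, 30, 30)), 0)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(5, 5, 15, 15)), 25 / 175)
  for (seed in 1:20) {
    set.seed(seed)
    a <- sort(runif(2, 0, 50)); b <- sort(runif(2, 0, 50))
    c2 <- sort(runif(2, 0, 50)); d <- sort(runif(2, 0, 50))
    boxa <- c(a[1], b[1], a[2] + 1, b[2] + 1)
    boxb <- c(c2[1], d[1], c2[2] + 1, d[2] + 1)
    expect_equal(iou(boxa, boxb), oracle_iou(boxa, boxb))
  }
})

test_that("greedy matching reproduces the exhaustive oracle", {
  truths <- data.frame(x0 = c(0, 20, 40, 60), y0 = 0,
                       x1 = c(10, 30, 50, 70), y1 = 10)
  dets <- data.frame(
    x0 = c(1, 21, 41, 80, 2), y0 = c(0, 0, 0, 0, 0),
    x1 = c(11, 31, 51, 90, 12), y1 = c(10, 10, 10, 10, 10),
    confidence = c(0.9, 0.8, 0.7, 0.6, 0.5))
  m <- match_detections(dets, truths, 0.5)
  want <- oracle_match_counts(dets, truths, 0.5)
  expect_equal(m$counts$tp, unname(want["tp"]))
  expect_equal(m$counts$fp, unname(want["fp"]))
  expect_equal(m$counts$fn, unname(want["fn"]))
  # hand check: three overlapping hits, one far miss, one duplicate
  expect_equal(m$counts$tp, 3)
  expect_equal(m$counts$fp, 2)
  expect_equal(m$counts$fn, 1)
  # randomized cross-check
  for (seed in 1:10) {
    set.seed(seed)
    nt <- sample(2:5, 1); nd <- sample(2:6, 1)
    tr <- data.frame(x0 = runif(nt, 0, 80), y0 = runif(nt, 0, 80))
    tr$x1 <- tr$x0 + runif(nt, 5, 20); tr$y1 <- tr$y0 + runif(nt, 5, 20)
    de <- data.frame(x0 = runif(nd, 0, 80), y0 = runif(nd, 0, 80))
    de$x1 <- de$x0 + runif(nd, 5, 20); de$y1 <- de$y0 + runif(nd, 5, 20)
    de$confidence <- runif(nd)
    got <- match_detections(de, tr, 0.3)$counts
    want <- oracle_match_counts(de, tr, 0.3)
    expect_equal(c(got$tp, got$fp, got$fn), unname(want))
  }
})

test_that("perfect and empty detection sets give the boundary counts", {
  truths <- data.frame(x0 = c(0, 20), y0 = 0, x1 = c(10, 30), y1 = 10)
  exact <- cbind(truths, confidence = c(0.9, 0.8))
  m <- match_detections(exact, truths, 0.5)
  expect_equal(m$counts$tp, 2)
  expect_equal(m$counts$fp + m$counts$fn, 0)
  none <- match_detections(
    data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
               y1 = numeric(0), confidence = numeric(0)), truths, 0.5)
  expect_equal(none$counts$fn, 2)
})

test_that("ratio metrics match closed-form hand values", {
  m <- classification_metrics(confusion_counts(tp = 97, fp = 3, fn = 3,
                                               tn = 97))
  expect_equal(unname(m), c(97, 97, 97))
  m2 <- classification_metrics(confusion_counts(tp = 50, fp = 0, fn = 10,
                                                tn = 20))
  expect_equal(unname(m2["precision"]), 100)
  expect_equal(unname(m2["recall"]), 100 * 50 / 60)
  expect_equal(unname(m2["specificity"]), 100)
  frac <- classification_metrics(confusion_counts(3, 1, 1, 3),
                                 as_percent = FALSE)
  expect_equal(unname(frac), c(0.75, 0.75, 0.75))
})

test_that("zero denominators signal undefined metrics, never silent zero", {
  expect_warning(
    m <- classification_metrics(confusion_counts(tp = 0, fp = 0, fn = 5,
                                                 tn = 5)),
    class = "bitewing_undefined_metric")
  expect_true(is.na(m[["precision"]]))
  expect_false(is.na(m[["recall"]]))
})

test_that("average precision equals the cut-point enumeration oracle", {
  truths <- data.frame(x0 = c(0, 20, 40), y0 = 0, x1 = c(10, 30, 50), y1 = 10)
  dets <- data.frame(
    x0 = c(0, 100, 20, 200, 40, 0), y0 = c(0, 100, 0, 200, 0, 0),
    x1 = c(10, 110, 30, 210, 50, 10), y1 = c(10, 110, 10, 210, 10, 10),
    confidence = c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5))
  got <- average_precision(dets, truths, 0.5)$ap
  expect_equal(got, oracle_ap_cutpoints(dets, truths, 0.5))
  expect_equal(got, 34 / 45)
  # randomized agreement with the oracle
  for (seed in 21:30) {
    set.seed(seed)
    nt <- sample(2:4, 1); nd <- sample(3:7, 1)
    tr <- data.frame(x0 = runif(nt, 0, 60), y0 = runif(nt, 0, 60))
    tr$x1 <- tr$x0 + runif(nt, 8, 15); tr$y1 <- tr$y0 + runif(nt, 8, 15)
    de <- data.frame(x0 = runif(nd, 0, 60), y0 = runif(nd, 0, 60))
    de$x1 <- de$x0 + runif(nd, 8, 15); de$y1 <- de$y0 + runif(nd, 8, 15)
    de$confidence <- sample(seq(0.05, 0.95, by = 0.05), nd)
    expect_equal(average_precision(de, tr, 0.4)$ap,
                 oracle_ap_cutpoints(de, tr, 0.4))
  }
})

test_that("AP boundary cases and confidence-rescaling invariance", {
  truths <- data.frame(x0 = c(0, 20), y0 = 0, x1 = c(10, 30), y1 = 10)
  perfect <- cbind(truths, confidence = c(0.9, 0.8))
  expect_equal(average_precision(perfect, truths)$ap, 1)
  wrong <- data.frame(x0 = c(100, 200), y0 = 100, x1 = c(110, 210), y1 = 110,
                      confidence = c(0.9, 0.8))
  expect_equal(average_precision(wrong, truths)$ap, 0)
  mixed <- rbind(perfect, wrong)
  a <- average_precision(mixed, truths)$ap
  rescaled <- mixed
  rescaled$confidence <- rescaled$confidence / 2
  expect_equal(average_precision(rescaled, truths)$ap, a)
  # an extra duplicate false positive can never raise AP
  extra <- rbind(mixed, data.frame(x0 = 100, y0 = 100, x1 = 110, y1 = 110,
                                   confidence = 0.85))
  expect_lte(average_precision(extra, truths)$ap, a)
})

test_that("mAP averages classes and excludes truthless classes", {
  truths <- data.frame(x0 = c(0, 20), y0 = 0, x1 = c(10, 30), y1 = 10)
  perfect <- cbind(truths, confidence = c(0.9, 0.8))
  wrong <- data.frame(x0 = 100, y0 = 100, x1 = 110, y1 = 110,
                      confidence = 0.9)
  res <- mean_average_precision(list(a = perfect, b = wrong),
                                list(a = truths, b = truths))
  expect_equal(res$map, 0.5)
  expect_warning(
    res2 <- mean_average_precision(
      list(a = perfect),
      list(a = truths, empty = truths[0, ])),
    "excluded")
  expect_equal(res2$map, 1)
})
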