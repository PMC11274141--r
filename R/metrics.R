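# Detection/classification evaluation: IoU, greedy confidence-ordered
# detection matching into confusion counts, precision / recall
# (sensitivity) / specificity, and PR-curve mean average precision.

#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative counts. For pure detection use,
#'   `tn` has no natural definition and defaults to 0.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

box_fields <- function(b) {
  if (inherits(b, "bbox")) return(as.numeric(b))
  if (is.numeric(b) && length(b) == 4L) return(as.numeric(b))
  stop("a box must be a bbox() or a length-4 (x0, y0, x1, y1) vector",
       call. = FALSE)
}

#' Intersection over union of two boxes
#'
#' Boxes are half-open `[x0, x1) x [y0, y1)`, so areas are
#' `(x1 - x0) * (y1 - y0)` exactly.
#'
#' @param a,b boxes ([bbox()] or `(x0, y0, x1, y1)` vectors).
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 5, 15, 15))  # 25/175
iou <- function(a, b) {
  a <- box_fields(a); b <- box_fields(b)
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  if (union <= 0) return(0)
  inter / union
}

as_box_df <- function(x) {
  if (is.data.frame(x)) {
    req <- c("x0", "y0", "x1", "y1")
    if (!all(req %in% names(x))) {
      stop(sprintf("data frame needs columns %s", paste(req, collapse = ", ")),
           call. = FALSE)
    }
    return(x)
  }
  if (is.list(x)) {
    df <- do.call(rbind, lapply(x, function(b) {
      v <- box_fields(b)
      data.frame(x0 = v[1L], y0 = v[2L], x1 = v[3L], y1 = v[4L])
    }))
    if (is.null(df)) df <- data.frame(x0 = numeric(0), y0 = numeric(0),
                                      x1 = numeric(0), y1 = numeric(0))
    return(df)
  }
  stop("supply a data frame of boxes or a list of bbox()", call. = FALSE)
}

#' Match detections to ground-truth boxes
#'
#' Detections are sorted by confidence (descending, ties kept stable)
#' and each is greedily assigned to the unmatched truth with the
#' highest IoU at or above `iou_threshold`. Matched detections are true
#' positives, unmatched detections false positives, unmatched truths
#' false negatives; `tn` is 0 (undefined for detection).
#'
#' @param dets data frame with columns `x0, y0, x1, y1, confidence`.
#' @param truths data frame of boxes or list of [bbox()].
#' @param iou_threshold matching cutoff in (0, 1].
#' @return list with `counts` (a [confusion_counts()]) and `matches` (a
#'   data frame, one row per detection in confidence order: `det`
#'   original row index, `truth` matched truth row or `NA`, `iou`,
#'   `confidence`).
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  if (!(iou_threshold > 0 && iou_threshold <= 1)) {
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  }
  dets <- as_box_df(dets)
  if (nrow(dets) > 0 && is.null(dets$confidence)) {
    stop("detections need a confidence column", call. = FALSE)
  }
  truths <- as_box_df(truths)
  nd <- nrow(dets); nt <- nrow(truths)
  ord <- if (nd > 0) order(-dets$confidence) else integer(0)
  used <- logical(nt)
  rows <- vector("list", nd)
  tp <- 0L
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- NA_integer_; best_iou <- 0
    for (j in seq_len(nt)) {
      if (used[j]) next
      v <- iou(unlist(dets[i, c("x0", "y0", "x1", "y1")]),
               unlist(truths[j, c("x0", "y0", "x1", "y1")]))
      if (v >= iou_threshold && v > best_iou) { best <- j; best_iou <- v }
    }
    if (!is.na(best)) { used[best] <- TRUE; tp <- tp + 1L }
    rows[[k]] <- data.frame(det = i, truth = best, iou = best_iou,
                            confidence = dets$confidence[i])
  }
  matches <- if (nd > 0) do.call(rbind, rows) else
    data.frame(det = integer(0), truth = integer(0), iou = numeric(0),
               confidence = numeric(0))
  list(counts = confusion_counts(tp = tp, fp = nd - tp, fn = nt - tp, tn = 0),
       matches = matches)
}

#' Precision, recall (sensitivity) and specificity
#'
#' Exact ratios `tp/(tp+fp)`, `tp/(tp+fn)`, `tn/(fp+tn)`. A metric with
#' a zero denominator is undefined: it is returned as `NA` and a
#' warning of class `bitewing_undefined_metric` is signalled, never a
#' silent zero.
#'
#' @param c a [confusion_counts()].
#' @param as_percent report on the 0-100 scale (default) or 0-1.
#' @return named numeric vector `precision`, `recall`, `specificity`.
#' @export
#' @examples
#' classification_metrics(confusion_counts(tp = 97, fp = 3, fn = 3, tn = 97))
classification_metrics <- function(c, as_percent = TRUE) {
  if (!inherits(c, "confusion_counts")) {
    stop("`c` must be confusion_counts()", call. = FALSE)
  }
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(structure(
        class = c("bitewing_undefined_metric", "warning", "condition"),
        list(message = sprintf("%s undefined: zero denominator", what),
             call = sys.call(-1))))
      return(NA_real_)
    }
    num / den
  }
  out <- c(precision = ratio(c$tp, c$tp + c$fp, "precision"),
           recall = ratio(c$tp, c$tp + c$fn, "recall"),
           specificity = ratio(c$tn, c$fp + c$tn, "specificity"))
  if (as_percent) out * 100 else out
}

#' Precision-recall curve and average precision for one class
#'
#' Detections are matched greedily in confidence order (see
#' [match_detections()]); cumulative true/false positives give one
#' (recall, precision) point per detection. AP is the area under the
#' interpolated curve: in `"all_point"` mode the precision envelope
#' (running maximum from the right) integrated over every recall step,
#' in `"11point"` mode the mean of the envelope sampled at recalls
#' 0, 0.1, ..., 1.
#'
#' @inheritParams match_detections
#' @param mode interpolation mode.
#' @return list with `ap` and `curve` (data frame `recall`,
#'   `precision`).
#' @export
average_precision <- function(dets, truths, iou_threshold = 0.5,
                              mode = c("all_point", "11point")) {
  mode <- match.arg(mode)
  truths <- as_box_df(truths)
  if (nrow(truths) == 0L) stop("no ground-truth boxes", call. = FALSE)
  m <- match_detections(dets, truths, iou_threshold)$matches
  if (nrow(m) == 0L) {
    return(list(ap = 0, curve = data.frame(recall = numeric(0),
                                           precision = numeric(0))))
  }
  is_tp <- !is.na(m$truth)
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  recall <- cum_tp / nrow(truths)
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope: best precision achievable at >= this recall
  env <- rev(cummax(rev(precision)))
  ap <- if (mode == "all_point") {
    sum(diff(c(0, recall)) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- recall >= r - 1e-12
      if (!any(ok)) 0 else max(env[ok])
    }, numeric(1)))
  }
  list(ap = ap, curve = data.frame(recall = recall, precision = precision))
}

#' Mean average precision over classes
#'
#' Computes [average_precision()] per class and averages. Classes with
#' no ground-truth boxes are excluded with a warning.
#'
#' @param per_class_dets named list of detection data frames, one per
#'   class.
#' @param per_class_truths named list of truth box sets, same names.
#' @inheritParams average_precision
#' @return list with `map`, `per_class` (named AP vector).
#' @export
mean_average_precision <- function(per_class_dets, per_class_truths,
                                   iou_threshold = 0.5,
                                   mode = c("all_point", "11point")) {
  mode <- match.arg(mode)
  classes <- names(per_class_truths)
  if (is.null(classes) || length(classes) == 0L) {
    stop("per_class_truths must be a non-empty named list", call. = FALSE)
  }
  aps <- numeric(0)
  for (cl in classes) {
    tr <- as_box_df(per_class_truths[[cl]])
    if (nrow(tr) == 0L) {
      warning(sprintf("class '%s' has no ground-truth boxes; excluded", cl))
      next
    }
    dets <- per_class_dets[[cl]]
    if (is.null(dets)) dets <- data.frame(x0 = numeric(0), y0 = numeric(0),
                                          x1 = numeric(0), y1 = numeric(0),
                                          confidence = numeric(0))
    aps[cl] <- average_precision(dets, tr, iou_threshold, mode)$ap
  }
  if (length(aps) == 0L) stop("no class with ground truth", call. = FALSE)
  list(map = mean(aps), per_class = aps)
}
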