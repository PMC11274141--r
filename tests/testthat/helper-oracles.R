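# Brute-force oracles, written as direct transcriptions of the
# definitions (double loops, explicit sorting, exhaustive sums). They
# deliberately share no code with the package internals.

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(as.numeric(sample(0:255, h * w, replace = TRUE)), h, w)
}

rand_mask <- function(h, w, seed, density = 0.5) {
  set.seed(seed)
  matrix(ifelse(runif(h * w) < density, 255, 0), h, w)
}

# edge-replicated pixel fetch, 1-based
px <- function(img, r, c) {
  img[min(max(r, 1L), nrow(img)), min(max(c, 1L), ncol(img))]
}

oracle_mean <- function(img, kw, kh) {
  a <- (kw - 1) / 2; b <- (kh - 1) / 2
  out <- img
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      s <- 0
      for (dr in -b:b) for (dc in -a:a) s <- s + px(img, r + dr, c + dc)
      out[r, c] <- floor(s / (kw * kh) + 0.5)
    }
  }
  out
}

oracle_median <- function(img, kw, kh) {
  a <- (kw - 1) / 2; b <- (kh - 1) / 2
  out <- img
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      vals <- numeric(0)
      for (dr in -b:b) for (dc in -a:a) vals <- c(vals, px(img, r + dr, c + dc))
      out[r, c] <- sort(vals)[(length(vals) + 1) / 2]
    }
  }
  out
}

oracle_bilateral <- function(img, radius, sigma_s, sigma_r) {
  out <- img
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      center <- img[r, c]
      wsum <- 0; acc <- 0
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          v <- px(img, r + dr, c + dc)
          w <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2)) *
            exp(-(v - center)^2 / (2 * sigma_r^2))
          wsum <- wsum + w
          acc <- acc + w * v
        }
      }
      out[r, c] <- floor(acc / wsum + 0.5)
    }
  }
  out
}

# pure spatial-Gaussian weighted mean (the flat-range limit of the
# bilateral filter)
oracle_spatial_gaussian <- function(img, radius, sigma_s) {
  out <- img
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      wsum <- 0; acc <- 0
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          w <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
          wsum <- wsum + w
          acc <- acc + w * px(img, r + dr, c + dc)
        }
      }
      out[r, c] <- floor(acc / wsum + 0.5)
    }
  }
  out
}

oracle_box_mean_threshold <- function(img, block, offset_c) {
  h <- (block - 1) / 2
  out <- img
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      s <- 0
      for (dr in -h:h) for (dc in -h:h) s <- s + px(img, r + dr, c + dc)
      out[r, c] <- if (img[r, c] > s / block^2 - offset_c) 255 else 0
    }
  }
  out
}

# structuring-element sweep with 0-based origin, everything off-raster
# treated as background
oracle_dilate <- function(img, mask, origin) {
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      hit <- FALSE
      for (i in seq_len(nrow(mask))) {
        for (j in seq_len(ncol(mask))) {
          if (!mask[i, j]) next
          rr <- r - (i - 1 - origin[1])
          cc <- c - (j - 1 - origin[2])
          if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img) &&
              img[rr, cc] == 255) hit <- TRUE
        }
      }
      out[r, c] <- if (hit) 255 else 0
    }
  }
  out
}

oracle_erode <- function(img, mask, origin) {
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      all_in <- TRUE
      for (i in seq_len(nrow(mask))) {
        for (j in seq_len(ncol(mask))) {
          if (!mask[i, j]) next
          rr <- r + (i - 1 - origin[1])
          cc <- c + (j - 1 - origin[2])
          if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img) ||
              img[rr, cc] != 255) all_in <- FALSE
        }
      }
      out[r, c] <- if (all_in) 255 else 0
    }
  }
  out
}

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# confidence-ordered matching transcribed independently: detections in
# descending confidence each claim the unmatched truth of highest IoU
# at or above the threshold
oracle_match_counts <- function(dets, truths, thr) {
  ord <- order(-dets$confidence)
  taken <- rep(FALSE, nrow(truths))
  tp <- 0
  for (i in ord) {
    ious <- sapply(seq_len(nrow(truths)), function(j) {
      if (taken[j]) return(-1)
      oracle_iou(as.numeric(dets[i, c("x0", "y0", "x1", "y1")]),
                 as.numeric(truths[j, c("x0", "y0", "x1", "y1")]))
    })
    if (length(ious) > 0 && max(ious) >= thr) {
      taken[which.max(ious)] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = nrow(dets) - tp, fn = nrow(truths) - tp)
}

# AP by explicit confidence cut-point enumeration: at every distinct
# confidence cutoff compute (recall, precision); AP sums, over recall
# steps, the best precision at any cutoff reaching at least that recall
oracle_ap_cutpoints <- function(dets, truths, thr) {
  ord <- order(-dets$confidence)
  taken <- rep(FALSE, nrow(truths))
  is_tp <- logical(nrow(dets))
  for (i in ord) {
    ious <- sapply(seq_len(nrow(truths)), function(j) {
      if (taken[j]) return(-1)
      oracle_iou(as.numeric(dets[i, c("x0", "y0", "x1", "y1")]),
                 as.numeric(truths[j, c("x0", "y0", "x1", "y1")]))
    })
    if (length(ious) > 0 && max(ious) >= thr) {
      taken[which.max(ious)] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  cuts <- sort(unique(dets$confidence), decreasing = TRUE)
  pts <- do.call(rbind, lapply(cuts, function(cf) {
    keep <- dets$confidence >= cf
    tp <- sum(is_tp & keep); fp <- sum(!is_tp & keep)
    data.frame(recall = tp / nrow(truths), precision = tp / (tp + fp))
  }))
  recalls <- sort(unique(pts$recall))
  ap <- 0
  prev <- 0
  for (r in recalls) {
    best <- max(pts$precision[pts$recall >= r - 1e-12])
    ap <- ap + (r - prev) * best
    prev <- r
  }
  ap
}

# interior mask: TRUE where a window of the given half-sizes fits
# entirely inside the raster
interior <- function(img, hr, hc) {
  m <- matrix(FALSE, nrow(img), ncol(img))
  rows <- (hr + 1):(nrow(img) - hr)
  cols <- (hc + 1):(ncol(img) - hc)
  m[rows, cols] <- TRUE
  m
}
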