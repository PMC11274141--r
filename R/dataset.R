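# Dataset preparation: flip/mirror augmentation, class balancing to a
# common per-class target, and the two-stage train/test/validation
# split (a held-out validation share, then a 7:3 train/test division of
# the remainder). Items are rows of a manifest data frame with columns
# id, label, transform_tag, source_id; images travel separately.

FLIP_TAGS <- c("hflip", "vflip", "hvflip")

#' Apply a flip/mirror transform to an image
#'
#' `hflip` mirrors columns, `vflip` mirrors rows, `hvflip` does both.
#' Every transform is an involution: applying it twice restores the
#' original raster.
#'
#' @param img grayscale image matrix.
#' @param tag one of `"none"`, `"hflip"`, `"vflip"`, `"hvflip"`.
#' @return transformed image.
#' @export
apply_flip <- function(img, tag) {
  assert_gray(img)
  switch(match.arg(tag, c("none", FLIP_TAGS)),
         none = img,
         hflip = img[, rev(seq_len(ncol(img))), drop = FALSE],
         vflip = img[rev(seq_len(nrow(img))), , drop = FALSE],
         hvflip = img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))),
                      drop = FALSE])
}

#' Random flip/mirror augmentation
#'
#' Applies one transform chosen uniformly from
#' `{hflip, vflip, hvflip}` and records which.
#'
#' @param img grayscale image matrix.
#' @param seed optional integer; when given, the choice is reproducible
#'   and the session RNG is left untouched.
#' @return list with `image` and `transform_tag`.
#' @export
augment_flip_mirror <- function(img, seed = NULL) {
  pick <- function() sample(FLIP_TAGS, 1L)
  tag <- if (is.null(seed)) pick() else with_local_seed(seed, pick())
  list(image = apply_flip(img, tag), transform_tag = tag)
}

normalize_pool <- function(pool) {
  if (!is.data.frame(pool) || !all(c("id", "label") %in% names(pool))) {
    stop("pool must be a data frame with columns id and label", call. = FALSE)
  }
  if (anyDuplicated(pool$id)) stop("pool ids must be unique", call. = FALSE)
  if (is.null(pool$transform_tag)) pool$transform_tag <- "none"
  if (is.null(pool$source_id)) pool$source_id <- pool$id
  pool
}

#' Balance a labeled pool to a common per-class count
#'
#' The minority class is grown to `target` by sampling source items
#' with replacement and attaching a random flip/mirror transform tag to
#' each new record; classes above `target` are subsampled without
#' replacement. With `target` omitted it defaults to
#' `floor(nrow(pool) / 2)`, so a 428/912 pool balances to 670/670.
#'
#' @param pool manifest data frame (`id`, `label`, optionally
#'   `transform_tag`, `source_id`).
#' @param target per-class count; `NULL` for `floor(total/2)`.
#' @param seed optional integer seed.
#' @param allow_shrink permit subsampling the minority class when
#'   `target` is below its natural count (off by default: that silently
#'   discards scarce positives).
#' @return balanced manifest with exactly `target` rows per class.
#' @export
#' @examples
#' pool <- data.frame(id = as.character(1:10),
#'                    label = rep(c("calculus", "no_calculus"), c(3, 7)))
#' table(balance_classes(pool, seed = 1)$label)
balance_classes <- function(pool, target = NULL, seed = NULL,
                            allow_shrink = FALSE) {
  pool <- normalize_pool(pool)
  labels <- unique(pool$label)
  if (length(labels) != 2L) {
    stop("pool must contain exactly two classes", call. = FALSE)
  }
  counts <- table(pool$label)
  if (any(counts == 0L)) stop("both classes must be non-empty", call. = FALSE)
  if (is.null(target)) target <- nrow(pool) %/% 2L
  target <- as.integer(target)
  if (target < 1L) stop("target must be >= 1", call. = FALSE)
  minority <- names(counts)[which.min(counts)]
  if (target < counts[[minority]] && !allow_shrink) {
    stop(sprintf(
      "target %d is below the minority class count %d; set allow_shrink = TRUE to subsample it",
      target, counts[[minority]]), call. = FALSE)
  }
  body <- function() {
    out <- list()
    for (lab in labels) {
      rows <- pool[pool$label == lab, , drop = FALSE]
      n <- nrow(rows)
      if (n >= target) {
        out[[lab]] <- rows[sample.int(n, target), , drop = FALSE]
      } else {
        extra_idx <- sample.int(n, target - n, replace = TRUE)
        extra <- rows[extra_idx, , drop = FALSE]
        extra$transform_tag <- sample(FLIP_TAGS, nrow(extra), replace = TRUE)
        extra$source_id <- extra$id
        extra$id <- paste0(extra$id, "_aug", seq_len(nrow(extra)))
        out[[lab]] <- rbind(rows, extra)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
  if (is.null(seed)) body() else with_local_seed(seed, body())
}

#' Two-stage train/test/validation split
#'
#' Stage one holds out a validation share of the pool; stage two splits
#' the remainder into train and test. Counts follow a floor-and-cascade
#' rule: with `N` items, `rest = floor(N * (1 - holdout_fraction))`,
#' `train = floor(rest * train_fraction_of_rest)`, `test = rest -
#' train`, `validation = N - rest`. A pool of 1340 with holdout 0.2 and
#' train fraction 0.7 therefore splits 750/322/268. Setting
#' `train_fraction_of_rest = 1` degenerates to a two-way
#' train/validation split.
#'
#' Augmented copies and their source item are kept in the same subset
#' (grouped by root `source_id`) so a transformed duplicate can never
#' leak across the train/test boundary; with group sizes small relative
#' to the subset quotas the stated counts are still met exactly.
#'
#' @param pool manifest data frame, or a vector of ids.
#' @param holdout_fraction validation share of the full pool, in (0,1).
#' @param train_fraction_of_rest train share of the remainder, in
#'   (0,1].
#' @param seed optional integer seed for the shuffle.
#' @return list of class `split_result` with disjoint id vectors
#'   `train`, `test`, `validation` whose union is the pool.
#' @export
#' @examples
#' ids <- as.character(seq_len(1340))
#' lengths(split_two_stage(ids, 0.2, 0.7, seed = 1))
split_two_stage <- function(pool, holdout_fraction = 0.2,
                            train_fraction_of_rest = 0.7, seed = NULL) {
  if (!is.data.frame(pool)) {
    pool <- data.frame(id = as.character(pool),
                       label = "unlabeled", stringsAsFactors = FALSE)
  }
  pool <- normalize_pool(pool)
  if (!(holdout_fraction > 0 && holdout_fraction < 1)) {
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!(train_fraction_of_rest > 0 && train_fraction_of_rest <= 1)) {
    stop("train_fraction_of_rest must lie in (0, 1]", call. = FALSE)
  }
  N <- nrow(pool)
  eps <- 1e-9
  rest <- floor(N * (1 - holdout_fraction) + eps)
  n_train <- floor(rest * train_fraction_of_rest + eps)
  n_test <- rest - n_train
  n_val <- N - rest
  two_way <- train_fraction_of_rest == 1
  if (n_train < 1L || n_val < 1L || (!two_way && n_test < 1L)) {
    stop("pool too small for non-empty splits at these fractions",
         call. = FALSE)
  }

  # group augmented items with their root source so no source family
  # straddles a subset boundary
  root <- pool$source_id
  repeat {
    parent <- ifelse(root %in% pool$id & root != pool$id,
                     pool$source_id[match(root, pool$id)], root)
    if (identical(parent, root)) break
    root <- parent
  }
  fams <- split(pool$id, root)
  shuffle <- function() fams[sample.int(length(fams))]
  fams <- if (is.null(seed)) shuffle() else with_local_seed(seed, shuffle())

  quota <- c(train = n_train, test = n_test, validation = n_val)
  out <- list(train = character(0), test = character(0),
              validation = character(0))
  for (fam in fams) {
    k <- length(fam)
    fits <- names(quota)[quota - lengths(out)[names(quota)] >= k]
    dest <- if (length(fits) > 0L) fits[1L]
    else names(which.max(quota - lengths(out)[names(quota)]))
    out[[dest]] <- c(out[[dest]], fam)
  }
  structure(out, class = "split_result", quota = quota)
}
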