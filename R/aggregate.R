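#' Pseudo-Allred score of a single reading
#'
#' The crowd analogue of the Allred score: the proportion answer (0--5,
#' corresponding to 0%, <1%, 1--9%, 10--33%, 34--66%, 67--100% of nuclei
#' staining positive) plus the intensity answer (0--3: none, weak, moderate,
#' strong), giving an ordinal score on 0--8. A score > 2 is conventionally
#' read as estrogen-receptor positive.
#'
#' @param proportion_bin integer vector in 0--5.
#' @param intensity_bin integer vector in 0--3.
#' @return integer vector in 0--8.
#' @export
pseudo_allred_event <- function(proportion_bin, intensity_bin) {
  if (length(proportion_bin) != length(intensity_bin))
    stop_invalid("proportion_bin and intensity_bin must have equal length")
  ok_p <- proportion_bin %in% 0:5
  ok_i <- intensity_bin %in% 0:3
  if (!all(ok_p)) stop_invalid("proportion_bin out of range 0-5")
  if (!all(ok_i)) stop_invalid("intensity_bin out of range 0-3")
  as.integer(proportion_bin + intensity_bin)
}

#' Weighted lower median
#'
#' Smallest value `v` such that the cumulative weight of items with value
#' `<= v` reaches half the total weight. With equal weights this reduces to
#' the plain lower median, so weighted and unweighted aggregation share one
#' convention. Used both to pool sub-image scores into a core score (weights
#' = number of cancer cells) and to pool individual readings (weights = user
#' performance scores).
#'
#' @param values numeric vector.
#' @param weights non-negative numeric vector, same length, positive sum.
#' @return an element of `values`.
#' @export
weighted_median <- function(values, weights) {
  if (length(values) == 0L) stop_invalid("weighted_median: empty input")
  if (length(values) != length(weights))
    stop_invalid("weighted_median: values and weights differ in length")
  if (any(weights < 0)) stop_invalid("weighted_median: negative weight")
  tot <- sum(weights)
  if (tot <= 0) stop_invalid("weighted_median: all weights are zero")
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  v[which(cw >= tot / 2)[1L]]
}

## Per-event contributions with the "no cancer" convention: a reading that
## answers cancer-absent contributes 0 to every ordinal question, so an
## all-negative sub-image still has a defined score.
event_ordinals <- function(events) {
  yes <- events$cancer_present
  cc <- ifelse(yes, events$cell_count_bin, 0L)
  pp <- ifelse(yes, events$proportion_bin, 0L)
  ii <- ifelse(yes, events$intensity_bin, 0L)
  list(cell = as.integer(cc), prop = as.integer(pp), intens = as.integer(ii),
       pa = as.integer(pp + ii))
}

#' Consensus score for one sub-image
#'
#' Combines all readings of one sub-image into a single consensus record
#' under one of three schemes: `"plain"` (lower median of readings),
#' `"ups_weighted"` (weighted lower median with each reader's final user
#' performance score as weight) or `"min5_filtered"` (plain median after
#' dropping readers who scored fewer than five sub-images; if no reading
#' survives the filter the plain median over all readings is used).
#'
#' @param events data frame of readings for a single sub-image with columns
#'   `user_id`, `cancer_present`, `cell_count_bin`, `proportion_bin`,
#'   `intensity_bin`.
#' @param users user table with `user_id`, `final_ups`, `n_scored`
#'   (required for the weighted and filtered variants).
#' @param variant one of `"plain"`, `"ups_weighted"`, `"min5_filtered"`.
#' @param min_scores filter threshold for `"min5_filtered"`.
#' @return one-row data frame: `modal_cancer_prob`, `n_scores`,
#'   `median_cell_count`, `median_proportion`, `median_intensity`,
#'   `median_pseudo_allred`.
#' @export
consensus_sub_image <- function(events, users = NULL,
                                variant = c("plain", "ups_weighted",
                                            "min5_filtered"),
                                min_scores = 5L) {
  variant <- match.arg(variant)
  if (nrow(events) == 0L) stop_invalid("consensus_sub_image: no events")
  w <- rep(1, nrow(events))
  if (variant == "ups_weighted") {
    if (is.null(users)) stop_invalid("ups_weighted variant needs a user table")
    w <- users$final_ups[match(events$user_id, users$user_id)]
    if (anyNA(w)) stop_invalid("event user_id missing from user table")
    if (sum(w) == 0) w <- rep(1, nrow(events))  # uninformative crowd: equal weights
  } else if (variant == "min5_filtered") {
    if (is.null(users)) stop_invalid("min5_filtered variant needs a user table")
    n_sc <- users$n_scored[match(events$user_id, users$user_id)]
    keep <- !is.na(n_sc) & n_sc >= min_scores
    if (any(keep)) events <- events[keep, , drop = FALSE]
    w <- rep(1, nrow(events))
  }
  ord <- event_ordinals(events)
  y <- as.numeric(events$cancer_present)
  data.frame(
    modal_cancer_prob = sum(w * y) / sum(w),
    n_scores = nrow(events),
    median_cell_count = weighted_median(ord$cell, w),
    median_proportion = weighted_median(ord$prop, w),
    median_intensity = weighted_median(ord$intens, w),
    median_pseudo_allred = weighted_median(ord$pa, w)
  )
}

#' Consensus table for all sub-images
#'
#' Applies [consensus_sub_image()] to every sub-image in an event table.
#'
#' @param events event table (multiple sub-images); must carry `sub_image_id`
#'   and, if present, `image_id` is propagated.
#' @inheritParams consensus_sub_image
#' @return data frame, one row per sub-image.
#' @export
consensus_table <- function(events, users = NULL,
                            variant = c("plain", "ups_weighted",
                                        "min5_filtered"),
                            min_scores = 5L) {
  variant <- match.arg(variant)
  check_columns(events, c("sub_image_id", "user_id", "cancer_present"),
                "event table")
  if (variant != "plain" && is.null(users))
    stop_invalid("variant %s needs a user table", variant)
  dt <- data.table::as.data.table(events)
  has_img <- "image_id" %in% names(events)
  ord <- event_ordinals(events)
  dt[, `:=`(.y = as.numeric(cancer_present), .cc = ord$cell,
            .pp = ord$prop, .ii = ord$intens, .pa = ord$pa)]
  dt[, .w := 1]
  dt[, .keep := TRUE]
  if (variant == "ups_weighted") {
    w <- users$final_ups[match(events$user_id, users$user_id)]
    if (anyNA(w)) stop_invalid("event user_id missing from user table")
    dt[, .w := w]
  } else if (variant == "min5_filtered") {
    n_sc <- users$n_scored[match(events$user_id, users$user_id)]
    dt[, .keep := !is.na(n_sc) & n_sc >= min_scores]
  }
  wmed <- function(v, w) {
    o <- order(v)
    cw <- cumsum(w[o])
    v[o][which(cw >= cw[length(cw)] / 2)[1L]]
  }
  res <- dt[, {
    k <- if (any(.keep)) .keep else rep(TRUE, .N)   # filter fallback
    w <- .w[k]
    if (sum(w) == 0) w <- rep(1, length(w))          # all-zero UPS fallback
    list(modal_cancer_prob = sum(w * .y[k]) / sum(w),
         n_scores = sum(k),
         median_cell_count = wmed(.cc[k], w),
         median_proportion = wmed(.pp[k], w),
         median_intensity = wmed(.ii[k], w),
         median_pseudo_allred = wmed(.pa[k], w))
  }, by = "sub_image_id"]
  res <- as.data.frame(res)
  if (has_img) {
    map <- unique(events[, c("sub_image_id", "image_id")])
    res$image_id <- map$image_id[match(res$sub_image_id, map$sub_image_id)]
    res <- res[, c("sub_image_id", "image_id",
                   setdiff(names(res), c("sub_image_id", "image_id")))]
  }
  res$variant <- variant
  res
}

#' Core-level image score
#'
#' Combines the consensus records of one core's sub-images (1--16, typically
#' 12) into the per-core summary: the cancer-cell-count score (sum of the
#' sub-image median count bins, range 0 to 4 per sub-image), the pseudo-Allred
#' score (weighted lower median of the sub-image median pseudo-Allred scores,
#' weighted by the sub-image median cell counts), the estrogen-receptor call
#' (pseudo-Allred > `er_cut`) and the cancer-present call (cell-count score at
#' or above `cancer_threshold`). When every sub-image has median cell count 0
#' there is no evidence of tumor: the pseudo-Allred score is 0 and the ER call
#' negative.
#'
#' @param sub_consensus consensus rows for one image (see [consensus_table()]).
#' @param cancer_threshold minimum cell-count score to call cancer present
#'   (default 10, the maximum-accuracy operating point; 1 is the most
#'   sensitive setting).
#' @param er_cut ER positivity cut on the pseudo-Allred scale (call positive
#'   when strictly greater; default 2).
#' @return one-row data frame (`cell_count_score`, `pseudo_allred`, `er_call`,
#'   `cancer_present_call`, `n_sub_images`).
#' @export
image_score <- function(sub_consensus, cancer_threshold = 10L, er_cut = 2L) {
  n <- nrow(sub_consensus)
  if (n < 1L || n > 16L)
    stop_invalid("image_score: expected 1-16 sub-image records, got %d", n)
  wt <- sub_consensus$median_cell_count
  ccs <- as.integer(sum(wt))
  pa <- if (sum(wt) > 0) {
    as.integer(weighted_median(sub_consensus$median_pseudo_allred, wt))
  } else 0L
  data.frame(
    cell_count_score = ccs,
    pseudo_allred = pa,
    er_call = pa > er_cut,
    cancer_present_call = ccs >= cancer_threshold,
    n_sub_images = n
  )
}

#' Score all images from a consensus table
#'
#' @param consensus consensus table with `image_id` (see [consensus_table()]).
#' @inheritParams image_score
#' @return data frame, one row per image.
#' @export
score_images <- function(consensus, cancer_threshold = 10L, er_cut = 2L) {
  check_columns(consensus, c("image_id", "median_cell_count",
                             "median_pseudo_allred"), "consensus table")
  dt <- data.table::as.data.table(consensus)
  res <- dt[, image_score(.SD, cancer_threshold = cancer_threshold,
                          er_cut = er_cut), by = "image_id"]
  res <- as.data.frame(res)
  if ("variant" %in% names(consensus)) res$variant <- consensus$variant[1L]
  res
}

#' Cancer-present call from a cell-count score
#'
#' @param cell_count_score integer score(s) (sum of sub-image median count
#'   bins).
#' @param threshold minimum score to call cancer present (>= 1).
#' @return logical vector.
#' @export
classify_cancer_present <- function(cell_count_score, threshold = 10L) {
  threshold <- check_count(threshold, "threshold", min = 1L)
  cell_count_score >= threshold
}
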