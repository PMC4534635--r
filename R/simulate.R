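## Synthetic crowds, cores and reference sets.
##
## The generator reproduces the statistical structure the downstream
## analysis assumes: a long-tailed scores-per-user distribution (median 6,
## 5th percentile 1, 95th percentile 47), a bimodal 5/20 mixture of scores
## per sub-image, cores split into cancer-bearing (69%) and empty, and
## cancer-bearing cores split into ER-positive (76%) and ER-negative by the
## Allred > 2 convention.

#' Default crowd simulation parameters
#'
#' @param p_detect_shape1,p_detect_shape2 Beta parameters for each scorer's
#'   probability of answering the cancer-present question correctly
#'   (default Beta(7, 3): mean 0.7 with a tail of unreliable scorers).
#' @param noise_shape,noise_scale Gamma parameters for the standard
#'   deviation of the rounded Gaussian noise on ordinal answers.
#' @param n_scores_meanlog,n_scores_sdlog log-normal parameters of the
#'   scores-per-user distribution; the defaults put the median at 6 with
#'   5th/95th percentiles near 1 and 47.
#' @param p_detect_fixed,noise_fixed optional fixed values overriding the
#'   distributions (used for perfect-crowd configurations).
#' @return named list of parameters.
#' @export
crowd_config <- function(p_detect_shape1 = 7, p_detect_shape2 = 3,
                         noise_shape = 2, noise_scale = 0.35,
                         n_scores_meanlog = log(6), n_scores_sdlog = 1.251,
                         p_detect_fixed = NULL, noise_fixed = NULL) {
  as.list(environment())
}

#' Simulate a crowd of scorers
#'
#' Draws per-scorer reliability profiles: the probability of answering the
#' binary cancer-present question correctly, the noise level on ordinal
#' answers, and the number of sub-images the scorer will evaluate (a
#' discretized log-normal with median 6).
#'
#' @param n_users number of scorers (>= 1).
#' @param config see [crowd_config()].
#' @param seed RNG seed.
#' @return data frame `user_id`, `p_detect`, `ordinal_noise_sd`, `n_scores`.
#' @export
simulate_crowd <- function(n_users, config = crowd_config(), seed = 1L) {
  n_users <- check_count(n_users, "n_users", min = 1L)
  set.seed(seed)
  p <- config$p_detect_fixed %||%
    rbeta(n_users, config$p_detect_shape1, config$p_detect_shape2)
  ns <- config$noise_fixed %||%
    rgamma(n_users, shape = config$noise_shape, scale = config$noise_scale)
  n_scores <- pmax(1L, as.integer(round(
    rlnorm(n_users, config$n_scores_meanlog, config$n_scores_sdlog))))
  data.frame(
    user_id = sprintf("u%06d", seq_len(n_users)),
    p_detect = rep_len(p, n_users),
    ordinal_noise_sd = rep_len(ns, n_users),
    n_scores = n_scores,
    stringsAsFactors = FALSE
  )
}

#' Default core simulation parameters
#'
#' @param p_cancer_core probability a core contains cancer cells
#'   (default 0.69).
#' @param p_er_positive probability a cancer-bearing core is ER positive
#'   (default 0.76).
#' @param p_empty_sub fraction of cancer-free sub-images within a
#'   cancer-bearing core (default 0.25; tumor cells are unevenly
#'   distributed across a core).
#' @param n_sub_images sub-images per core (default 12).
#' @param cell_count_probs probabilities of cell-count bins 1--4 in a
#'   cancer-bearing sub-image.
#' @return named list.
#' @export
core_config <- function(p_cancer_core = 0.69, p_er_positive = 0.76,
                        p_empty_sub = 0.25, n_sub_images = 12L,
                        cell_count_probs = c(0.15, 0.2, 0.25, 0.4)) {
  as.list(environment())
}

## Draw a core-level (proportion, intensity) pair conditional on ER status.
## ER-positive staining is concentrated at high Allred totals, ER-negative
## at 0-2, in line with the usual bimodal Allred distribution.
draw_allred_bins <- function(n, er_positive) {
  pairs_pos <- expand.grid(p = 2:5, i = 1:3)
  pairs_pos <- pairs_pos[pairs_pos$p + pairs_pos$i > 2, ]
  w_pos <- (pairs_pos$p + pairs_pos$i)^2          # skew toward strong staining
  pairs_neg <- data.frame(p = c(0, 1, 1, 2, 0), i = c(0, 0, 1, 0, 2))
  w_neg <- c(6, 2, 1, 1, 0.5)
  out_p <- integer(n); out_i <- integer(n)
  if (any(er_positive)) {
    k <- sample(nrow(pairs_pos), sum(er_positive), replace = TRUE,
                prob = w_pos)
    out_p[er_positive] <- pairs_pos$p[k]
    out_i[er_positive] <- pairs_pos$i[k]
  }
  if (any(!er_positive)) {
    k <- sample(nrow(pairs_neg), sum(!er_positive), replace = TRUE,
                prob = w_neg)
    out_p[!er_positive] <- pairs_neg$p[k]
    out_i[!er_positive] <- pairs_neg$i[k]
  }
  list(p = out_p, i = out_i)
}

#' Simulate ground-truth tumor cores
#'
#' Each core carries a true Allred score (core proportion bin + intensity
#' bin, ER positive iff > 2) and a set of sub-images; cancer-bearing
#' sub-images inherit the core's staining truth with a per-sub-image cell
#' count bin, cancer-free sub-images have all bins zero.
#'
#' @param n_cores number of cores (>= 1).
#' @param config see [core_config()].
#' @param seed RNG seed.
#' @return data frame of class `true_cores`, one row per sub-image:
#'   `image_id`, `sub_image_id`, `true_cancer_present`,
#'   `true_cell_count_bin`, `true_proportion_bin`, `true_intensity_bin`,
#'   `core_allred`, `core_er_positive`, `core_cancer`.
#' @export
simulate_cores <- function(n_cores, config = core_config(), seed = 1L) {
  n_cores <- check_count(n_cores, "n_cores", min = 1L)
  set.seed(seed)
  nsub <- check_count(config$n_sub_images, "n_sub_images", 1L)
  if (nsub > 16L) stop_invalid("n_sub_images must be <= 16")
  cancer <- runif(n_cores) < config$p_cancer_core
  er <- cancer & (runif(n_cores) < config$p_er_positive)
  bins <- draw_allred_bins(n_cores, er)
  bins$p[!cancer] <- 0L; bins$i[!cancer] <- 0L
  allred <- ifelse(cancer, bins$p + bins$i, 0L)

  image_id <- sprintf("img%05d", seq_len(n_cores))
  df <- data.frame(
    image_id = rep(image_id, each = nsub),
    sub_image_id = sprintf("img%05d_s%02d",
                           rep(seq_len(n_cores), each = nsub),
                           rep(seq_len(nsub), n_cores)),
    sub_index = rep(seq_len(nsub), n_cores),
    stringsAsFactors = FALSE
  )
  core_cancer <- rep(cancer, each = nsub)
  sub_cancer <- core_cancer & (runif(nrow(df)) >= config$p_empty_sub)
  # a cancer-bearing core keeps at least one cancer-bearing sub-image
  first <- !duplicated(df$image_id)
  sub_cancer[first & core_cancer] <- TRUE
  cc <- integer(nrow(df))
  cc[sub_cancer] <- sample(1:4, sum(sub_cancer), replace = TRUE,
                           prob = config$cell_count_probs)
  df$true_cancer_present <- sub_cancer
  df$true_cell_count_bin <- as.integer(cc)
  df$true_proportion_bin <-
    as.integer(ifelse(sub_cancer, rep(bins$p, each = nsub), 0L))
  df$true_intensity_bin <-
    as.integer(ifelse(sub_cancer, rep(bins$i, each = nsub), 0L))
  df$core_allred <- rep(as.integer(allred), each = nsub)
  df$core_er_positive <- rep(allred > 2, each = nsub)
  df$core_cancer <- core_cancer
  class(df) <- c("true_cores", "data.frame")
  df
}

#' Simulate crowd classification events
#'
#' Assigns scorers to sub-images and corrupts the truth per scorer profile:
#' the binary cancer-present answer is correct with probability `p_detect`;
#' when the scorer answers "cancer present" the three ordinal answers are
#' the sub-image truth plus rounded Gaussian noise, clipped to their scales
#' (cell count 1--4, proportion 0--5, intensity 0--3); when the scorer
#' answers "no cancer" the ordinal answers are absent.
#'
#' Two assignment schemes are available. `"by_subimage"` (default) draws a
#' target number of scores for each sub-image from a bimodal 5/20 mixture
#' and fills the slots by weighted sampling of scorers with remaining
#' capacity, reproducing the bimodal scores-per-sub-image distribution seen
#' on live platforms. `"by_user"` gives each scorer exactly `n_scores`
#' distinct sub-images (plus a top-up pass so every sub-image receives at
#' least one score).
#'
#' @param cores `true_cores` table from [simulate_cores()].
#' @param scorers scorer table from [simulate_crowd()].
#' @param seed RNG seed.
#' @param assignment `"by_subimage"` or `"by_user"`.
#' @param mix_sizes,mix_probs scores-per-sub-image mixture for
#'   `"by_subimage"` (default 5 vs 20 with probability 0.6/0.4).
#' @return data frame of events: `user_id`, `sub_image_id`, `image_id`,
#'   `cancer_present`, `cell_count_bin`, `proportion_bin`, `intensity_bin`
#'   (ordinal columns `NA` when `cancer_present` is `FALSE`).
#' @export
simulate_classifications <- function(cores, scorers, seed = 1L,
                                     assignment = c("by_subimage", "by_user"),
                                     mix_sizes = c(5L, 20L),
                                     mix_probs = c(0.6, 0.4)) {
  assignment <- match.arg(assignment)
  if (is.null(cores) || nrow(cores) == 0L) stop_invalid("no cores supplied")
  if (is.null(scorers) || nrow(scorers) == 0L)
    stop_invalid("no scorers supplied")
  set.seed(seed)
  n_sub <- nrow(cores)
  n_users <- nrow(scorers)

  if (assignment == "by_subimage") {
    targets <- sample(mix_sizes, n_sub, replace = TRUE, prob = mix_probs)
    targets <- pmin(targets, n_users)
    cap <- as.numeric(scorers$n_scores)
    su <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      k <- targets[s]
      prob <- cap + 1e-9   # exhausted users only drafted when no capacity left
      pick <- sample.int(n_users, k, prob = prob)
      cap[pick] <- pmax(cap[pick] - 1, 0)
      su[[s]] <- pick
    }
    sub_idx <- rep(seq_len(n_sub), lengths(su))
    user_idx <- unlist(su)
  } else {
    per_user <- lapply(seq_len(n_users), function(u) {
      k <- min(scorers$n_scores[u], n_sub)
      sample.int(n_sub, k)
    })
    sub_idx <- unlist(per_user)
    user_idx <- rep(seq_len(n_users), lengths(per_user))
    uncovered <- setdiff(seq_len(n_sub), unique(sub_idx))
    if (length(uncovered)) {   # coverage guarantee: one extra event each
      extra_u <- sample.int(n_users, length(uncovered), replace = TRUE)
      sub_idx <- c(sub_idx, uncovered)
      user_idx <- c(user_idx, extra_u)
    }
  }

  truth_cancer <- cores$true_cancer_present[sub_idx]
  p <- scorers$p_detect[user_idx]
  correct <- runif(length(sub_idx)) < p
  ans_cancer <- ifelse(correct, truth_cancer, !truth_cancer)

  nsd <- scorers$ordinal_noise_sd[user_idx]
  noise <- function() as.integer(round(rnorm(length(sub_idx), 0, nsd)))
  cc <- clip(cores$true_cell_count_bin[sub_idx] + noise(), 1L, 4L)
  pp <- clip(cores$true_proportion_bin[sub_idx] + noise(), 0L, 5L)
  ii <- clip(cores$true_intensity_bin[sub_idx] + noise(), 0L, 3L)

  data.frame(
    user_id = scorers$user_id[user_idx],
    sub_image_id = cores$sub_image_id[sub_idx],
    image_id = cores$image_id[sub_idx],
    cancer_present = ans_cancer,
    cell_count_bin = ifelse(ans_cancer, as.integer(cc), NA_integer_),
    proportion_bin = ifelse(ans_cancer, as.integer(pp), NA_integer_),
    intensity_bin = ifelse(ans_cancer, as.integer(ii), NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Select and score an expert reference set
#'
#' Samples `n_sub_images` sub-images stratified across the true sub-image
#' pseudo-Allred range (at least one from every occupied stratum, remaining
#' slots proportional to stratum size) and returns the truth as the expert
#' answers; the expert is treated as correct and carries a fixed UPS of 1.
#'
#' @param cores `true_cores` table.
#' @param n_sub_images reference-set size (default 200).
#' @param seed RNG seed.
#' @return data frame `sub_image_id`, `image_id`, `cancer_present`,
#'   `cell_count_bin`, `proportion_bin`, `intensity_bin`.
#' @export
make_expert_set <- function(cores, n_sub_images = 200L, seed = 1L) {
  n_sub_images <- check_count(n_sub_images, "n_sub_images", min = 1L)
  if (n_sub_images > nrow(cores))
    stop_invalid("n_sub_images (%d) exceeds available sub-images (%d)",
                 n_sub_images, nrow(cores))
  set.seed(seed)
  pa <- ifelse(cores$true_cancer_present,
               cores$true_proportion_bin + cores$true_intensity_bin, 0L)
  strata <- split(seq_len(nrow(cores)), pa)
  n_str <- length(strata)
  alloc <- rep(1L, n_str)
  if (n_sub_images >= n_str) {
    extra <- n_sub_images - n_str
    sizes <- lengths(strata)
    add <- floor(extra * sizes / sum(sizes))
    rem <- extra - sum(add)
    if (rem > 0) {
      o <- order(extra * sizes / sum(sizes) - add, decreasing = TRUE)
      add[o[seq_len(rem)]] <- add[o[seq_len(rem)]] + 1L
    }
    alloc <- pmin(alloc + add, lengths(strata))
    # redistribute anything lost to small strata
    while (sum(alloc) < n_sub_images) {
      room <- which(alloc < lengths(strata))
      if (!length(room)) break
      k <- room[which.max(lengths(strata)[room] - alloc[room])]
      alloc[k] <- alloc[k] + 1L
    }
  } else {
    alloc <- rep(0L, n_str)
    pick_str <- sample.int(n_str, n_sub_images)
    alloc[pick_str] <- 1L
  }
  idx <- unlist(lapply(seq_len(n_str), function(k) {
    s <- strata[[k]]
    if (alloc[k] >= length(s)) s else sample(s, alloc[k])
  }))
  data.frame(
    sub_image_id = cores$sub_image_id[idx],
    image_id = cores$image_id[idx],
    cancer_present = cores$true_cancer_present[idx],
    cell_count_bin = cores$true_cell_count_bin[idx],
    proportion_bin = cores$true_proportion_bin[idx],
    intensity_bin = cores$true_intensity_bin[idx],
    stringsAsFactors = FALSE
  )
}

#' Simulate a tumor-level clinical table
#'
#' One record per patient: study label, true ER status, age at diagnosis,
#' stage (I--IV) and grade (1--3) with configurable missingness (defaults
#' 7.8% and 9.3%). Survival outcomes are added separately by
#' [simulate_survival()].
#'
#' @param n number of patients, or a `true_cores` table (one patient per
#'   core, ER truth taken from the cores).
#' @param n_studies number of contributing studies (stratification factor).
#' @param p_er marginal probability of ER-positive disease when `n` is a
#'   count.
#' @param p_missing_stage,p_missing_grade missingness fractions.
#' @param seed RNG seed.
#' @return data frame `patient_id`, `image_id` (when built from cores),
#'   `study`, `er_true`, `age`, `stage`, `grade`.
#' @export
simulate_tumors <- function(n, n_studies = 10L, p_er = 0.52,
                            p_missing_stage = 0.078,
                            p_missing_grade = 0.093, seed = 1L) {
  set.seed(seed)
  image_id <- NULL
  if (is.data.frame(n)) {
    cores1 <- n[!duplicated(n$image_id), ]
    image_id <- cores1$image_id
    er <- cores1$core_er_positive
    n <- nrow(cores1)
  } else {
    n <- check_count(n, "n", min = 1L)
    er <- runif(n) < p_er
  }
  stage <- factor(sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.35, 0.45, 0.15, 0.05)),
                  levels = c("I", "II", "III", "IV"), ordered = TRUE)
  grade <- factor(sample(1:3, n, replace = TRUE, prob = c(0.2, 0.45, 0.35)),
                  levels = 1:3, ordered = TRUE)
  stage[runif(n) < p_missing_stage] <- NA
  grade[runif(n) < p_missing_grade] <- NA
  out <- data.frame(
    patient_id = sprintf("p%05d", seq_len(n)),
    study = factor(sprintf("study%02d",
                           sample.int(n_studies, n, replace = TRUE))),
    er_true = er,
    age = round(rnorm(n, 58, 10), 1),
    stage = stage,
    grade = grade,
    stringsAsFactors = FALSE
  )
  if (!is.null(image_id)) out$image_id <- image_id
  out
}

#' Mask stage and grade values completely at random
#'
#' Applied after outcome generation so that masking is independent of both
#' covariates and outcomes (MCAR), the regime under which chained-equation
#' imputation is expected to be unbiased.
#'
#' @param tumors tumor table with `stage` and `grade`.
#' @param p_stage,p_grade missingness fractions (defaults 7.8% and 9.3%).
#' @param seed RNG seed.
#' @return the table with `NA`s introduced.
#' @export
mask_stage_grade <- function(tumors, p_stage = 0.078, p_grade = 0.093,
                             seed = 1L) {
  set.seed(seed)
  n <- nrow(tumors)
  tumors$stage[runif(n) < p_stage] <- NA
  tumors$grade[runif(n) < p_grade] <- NA
  tumors
}
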