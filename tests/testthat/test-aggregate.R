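test_that("pseudo-Allred event score is the proportion + intensity sum", {
  expect_identical(pseudo_allred_event(5L, 3L), 8L)
  expect_identical(pseudo_allred_event(0L, 0L), 0L)
  expect_identical(pseudo_allred_event(3L, 2L), 5L)
  expect_identical(pseudo_allred_event(c(1, 4), c(0, 3)), c(1L, 7L))
  expect_error(pseudo_allred_event(6L, 0L), "out of range")
  expect_error(pseudo_allred_event(0L, 4L), "out of range")
})

test_that("weighted median follows the cumulative-weight definition", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(0, 8), c(1, 3)), 8)
  expect_equal(weighted_median(5, 2), 5)
  expect_error(weighted_median(numeric(0), numeric(0)), "empty")
  expect_error(weighted_median(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_median(c(1, 2), c(-1, 2)), "negative")
})

test_that("weighted median with equal weights is the lower median", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    v <- sample(0:8, n, replace = TRUE)
    expect_identical(weighted_median(v, rep(1, n)), lower_median(v))
  }
})

test_that("weighted median agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:500) {
    n <- sample(1:10, 1)
    v <- sample(0:8, n, replace = TRUE)
    w <- round(runif(n, 0, 5), 2)
    if (sum(w) == 0) w[1] <- 1
    expect_identical(weighted_median(v, w), bf_weighted_median(v, w))
  }
})

make_events <- function(user, yes, cc, pp, ii) {
  data.frame(user_id = user, sub_image_id = "s1", cancer_present = yes,
             cell_count_bin = ifelse(yes, cc, NA_integer_),
             proportion_bin = ifelse(yes, pp, NA_integer_),
             intensity_bin = ifelse(yes, ii, NA_integer_),
             stringsAsFactors = FALSE)
}

test_that("unanimous readings give back that reading", {
  ev <- make_events(paste0("u", 1:5), rep(TRUE, 5), 3L, 4L, 2L)
  cs <- consensus_sub_image(ev)
  expect_equal(cs$modal_cancer_prob, 1)
  expect_equal(cs$median_cell_count, 3)
  expect_equal(cs$median_proportion, 4)
  expect_equal(cs$median_intensity, 2)
  expect_equal(cs$median_pseudo_allred, 6)
})

test_that("UPS-weighted consensus with equal weights matches the plain one", {
  set.seed(7)
  ev <- make_events(paste0("u", 1:7), runif(7) < 0.7,
                    sample(1:4, 7, TRUE), sample(0:5, 7, TRUE),
                    sample(0:3, 7, TRUE))
  users <- data.frame(user_id = paste0("u", 1:7), final_ups = rep(0.6, 7),
                      n_scored = rep(10L, 7))
  expect_equal(consensus_sub_image(ev, users, "ups_weighted"),
               consensus_sub_image(ev, variant = "plain"))
})

test_that("min-5 filtering drops casual scorers, with a fallback", {
  ev <- make_events(paste0("u", 1:5), rep(TRUE, 5),
                    c(1L, 1L, 4L, 4L, 4L), c(0L, 0L, 5L, 5L, 5L),
                    c(0L, 0L, 3L, 3L, 3L))
  users <- data.frame(user_id = paste0("u", 1:5),
                      final_ups = rep(0.5, 5),
                      n_scored = c(1L, 2L, 9L, 9L, 9L))
  cs <- consensus_sub_image(ev, users, "min5_filtered")
  # filter-then-median oracle on the three remaining heavy users
  expect_equal(cs$median_pseudo_allred, lower_median(c(8, 8, 8)))
  expect_equal(cs$median_cell_count, 4)
  expect_equal(cs$n_scores, 3)
  # all scorers below the cut: falls back to the plain median of everyone
  users$n_scored <- rep(2L, 5)
  cs2 <- consensus_sub_image(ev, users, "min5_filtered")
  expect_equal(cs2$median_pseudo_allred,
               consensus_sub_image(ev, variant = "plain")$median_pseudo_allred)
})

test_that("readings that answer no cancer contribute zeros, not gaps", {
  ev <- make_events(paste0("u", 1:3), c(FALSE, FALSE, FALSE), 0L, 0L, 0L)
  cs <- consensus_sub_image(ev)
  expect_equal(cs$modal_cancer_prob, 0)
  expect_equal(cs$median_pseudo_allred, 0)
})

test_that("image score sums counts and takes the count-weighted median", {
  base <- data.frame(
    modal_cancer_prob = 0, n_scores = 5L, median_cell_count = 0L,
    median_proportion = 0L, median_intensity = 0L, median_pseudo_allred = 0L)
  empty <- base[rep(1, 12), ]
  empty$image_id <- "i1"
  sc <- image_score(empty)
  expect_equal(sc$cell_count_score, 0)
  expect_equal(sc$pseudo_allred, 0)
  expect_false(sc$er_call)
  expect_false(sc$cancer_present_call)

  one <- empty
  one$median_cell_count[4] <- 4L
  one$median_pseudo_allred[4] <- 7L
  sc1 <- image_score(one)
  expect_equal(sc1$pseudo_allred, 7)
  expect_true(sc1$er_call)

  full <- empty
  full$median_cell_count <- 4L
  expect_equal(image_score(full)$cell_count_score, 48)
  expect_error(image_score(empty[0, ]), "1-16")
})

test_that("cancer-present threshold classification is a simple cut", {
  expect_false(classify_cancer_present(0L, 1L))
  expect_true(classify_cancer_present(10L, 10L))
  expect_false(classify_cancer_present(9L, 10L))
  expect_error(classify_cancer_present(5L, 0L), "integer")
})

test_that("image pseudo-Allred is always an attained sub-image value", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(1:16, 1)
    cons <- data.frame(
      image_id = "i", modal_cancer_prob = 0, n_scores = 5L,
      median_cell_count = sample(0:4, n, TRUE),
      median_proportion = 0L, median_intensity = 0L,
      median_pseudo_allred = sample(0:8, n, TRUE))
    sc <- image_score(cons)
    if (sum(cons$median_cell_count) > 0)
      expect_true(sc$pseudo_allred %in% cons$median_pseudo_allred)
    else
      expect_identical(sc$pseudo_allred, 0L)
  }
})

test_that("grouped consensus equals the single-sub-image operation", {
  cores <- simulate_cores(20, seed = 21)
  crowd <- simulate_crowd(60, seed = 22)
  ev <- simulate_classifications(cores, crowd, seed = 23)
  users <- data.frame(user_id = crowd$user_id,
                      final_ups = runif(nrow(crowd)),
                      n_scored = as.integer(table(
                        factor(ev$user_id, crowd$user_id))))
  for (v in c("plain", "ups_weighted", "min5_filtered")) {
    tab <- consensus_table(ev, users = users, variant = v)
    set.seed(24)
    for (id in sample(tab$sub_image_id, 10)) {
      one <- consensus_sub_image(ev[ev$sub_image_id == id, ],
                                 users = users, variant = v)
      row <- tab[tab$sub_image_id == id, ]
      expect_equal(unlist(one), unlist(row[names(one)]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the three aggregation variants discriminate near-identically", {
  cores <- simulate_cores(2000, seed = 301)
  crowd <- simulate_crowd(4000, seed = 302)
  ev <- simulate_classifications(cores, crowd, seed = 303)
  expert <- make_expert_set(cores, 200, seed = 304)
  fit <- iterate_to_convergence(ev, expert)
  truth <- cores[!duplicated(cores$image_id), ]
  aucs <- sapply(c("plain", "ups_weighted", "min5_filtered"), function(v) {
    cons <- consensus_table(ev, users = fit$users, variant = v)
    img <- score_images(cons)
    idx <- match(img$image_id, truth$image_id)
    cancer <- truth$core_cancer[idx]
    c(cancer = roc_auc(img$cell_count_score, cancer)$auc,
      er = roc_auc(img$pseudo_allred[cancer],
                   truth$core_er_positive[idx][cancer])$auc)
  })
  expect_lt(max(abs(aucs[1, ] - aucs[1, 1])), 0.01)
  expect_lt(max(abs(aucs[2, ] - aucs[2, 1])), 0.01)
})
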