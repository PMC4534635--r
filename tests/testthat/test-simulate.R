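test_that("crowd simulation honors degenerate and default configurations", {
  one <- simulate_crowd(1, perfect_crowd_config(), seed = 1)
  expect_equal(one$p_detect, 1)
  expect_equal(one$ordinal_noise_sd, 0)
  expect_error(simulate_crowd(0), "integer")

  big <- simulate_crowd(10000, seed = 1)
  expect_lte(abs(median(big$n_scores) - 6), 1)   # long-tailed, median near 6
  expect_true(all(big$n_scores >= 1))
  expect_true(all(big$p_detect >= 0 & big$p_detect <= 1))
  expect_gte(quantile(big$n_scores, 0.95), 30)   # heavy upper tail

  expect_identical(simulate_crowd(50, seed = 9), simulate_crowd(50, seed = 9))
})

test_that("ground-truth cores respect the Allred bookkeeping", {
  cores <- simulate_cores(300, seed = 5)
  core1 <- cores[!duplicated(cores$image_id), ]
  expect_true(all(core1$core_allred >= 0 & core1$core_allred <= 8))
  expect_identical(core1$core_er_positive, core1$core_allred > 2)
  # cancer-free sub-images carry all-zero bins
  empt <- cores[!cores$true_cancer_present, ]
  expect_true(all(empt$true_cell_count_bin == 0))
  expect_true(all(empt$true_proportion_bin == 0))
  expect_true(all(empt$true_intensity_bin == 0))
  # cancer-bearing sub-images inherit the core staining truth
  canc <- cores[cores$true_cancer_present, ]
  expect_true(all(canc$true_proportion_bin + canc$true_intensity_bin ==
                    canc$core_allred))
  # every cancer-bearing core keeps at least one cancer-bearing sub-image
  agg <- tapply(cores$true_cancer_present, cores$image_id, any)
  expect_identical(as.vector(agg[core1$image_id]), core1$core_cancer)
})

test_that("a perfect crowd reproduces the truth exactly", {
  cores <- simulate_cores(20, seed = 6)
  crowd <- simulate_crowd(50, perfect_crowd_config(), seed = 7)
  ev <- simulate_classifications(cores, crowd, seed = 8)
  idx <- match(ev$sub_image_id, cores$sub_image_id)
  expect_identical(ev$cancer_present, cores$true_cancer_present[idx])
  yes <- ev$cancer_present
  expect_identical(ev$cell_count_bin[yes],
                   cores$true_cell_count_bin[idx][yes])
  expect_identical(ev$proportion_bin[yes],
                   cores$true_proportion_bin[idx][yes])
  expect_true(all(is.na(ev$cell_count_bin[!yes])))
})

test_that("binary accuracy calibrates to p_detect", {
  cores <- simulate_cores(60, seed = 9)
  crowd <- simulate_crowd(80, crowd_config(p_detect_fixed = 0.5,
                                           noise_fixed = 0), seed = 10)
  ev <- simulate_classifications(cores, crowd, seed = 11)
  truth <- cores$true_cancer_present[match(ev$sub_image_id,
                                           cores$sub_image_id)]
  acc <- mean(ev$cancer_present == truth)
  se <- sqrt(0.25 / nrow(ev))
  expect_lt(abs(acc - 0.5), 3 * se)

  crowd8 <- simulate_crowd(80, crowd_config(p_detect_fixed = 0.8,
                                            noise_fixed = 0), seed = 12)
  ev8 <- simulate_classifications(cores, crowd8, seed = 13)
  truth8 <- cores$true_cancer_present[match(ev8$sub_image_id,
                                            cores$sub_image_id)]
  acc8 <- mean(ev8$cancer_present == truth8)
  expect_lt(abs(acc8 - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(ev8)))
})

test_that("event-table contracts: coverage, counts and determinism", {
  cores <- simulate_cores(25, seed = 14)
  crowd <- simulate_crowd(500, seed = 15)
  ev <- simulate_classifications(cores, crowd, seed = 16)
  expect_setequal(unique(ev$sub_image_id), cores$sub_image_id)
  expect_false(any(duplicated(ev[c("user_id", "sub_image_id")])))
  expect_identical(ev, simulate_classifications(cores, crowd, seed = 16))
  # scores per sub-image follow the requested bimodal mixture
  tab <- table(ev$sub_image_id)
  expect_true(all(tab %in% c(5L, 20L)))

  crowd$n_scores <- 2L           # exact per-user count under by_user
  ev2 <- simulate_classifications(cores, crowd, seed = 17,
                                  assignment = "by_user")
  cnt <- table(ev2$user_id)
  expect_true(all(cnt >= 2L))                         # exactly n_scores each,
  expect_true(mean(cnt == 2L) > 0.95)                 # bar coverage top-ups
  expect_setequal(unique(ev2$sub_image_id), cores$sub_image_id)

  expect_error(simulate_classifications(cores[0, ], crowd), "no cores")
  expect_error(simulate_classifications(cores, crowd[0, ]), "no scorers")
})

test_that("the expert set is stratified across the score range", {
  cores <- simulate_cores(300, seed = 18)
  es <- make_expert_set(cores, 200, seed = 19)
  expect_equal(nrow(es), 200)
  expect_false(any(duplicated(es$sub_image_id)))
  truth_pa <- ifelse(cores$true_cancer_present,
                     cores$true_proportion_bin + cores$true_intensity_bin, 0L)
  picked_pa <- truth_pa[match(es$sub_image_id, cores$sub_image_id)]
  expect_setequal(unique(picked_pa), unique(truth_pa))  # every occupied stratum
  # expert answers are the truth
  idx <- match(es$sub_image_id, cores$sub_image_id)
  expect_identical(es$cancer_present, cores$true_cancer_present[idx])

  all_of_them <- make_expert_set(cores, nrow(cores), seed = 20)
  expect_equal(nrow(all_of_them), nrow(cores))
  expect_error(make_expert_set(cores, nrow(cores) + 1L), "exceeds")
})

test_that("tumor tables carry the configured missingness", {
  tum <- simulate_tumors(20000, seed = 21)
  expect_lt(abs(mean(is.na(tum$stage)) - 0.078), 3 * sqrt(0.078 * 0.922 / 20000))
  expect_lt(abs(mean(is.na(tum$grade)) - 0.093), 3 * sqrt(0.093 * 0.907 / 20000))
  expect_true(all(tum$age > 0))
  cores <- simulate_cores(50, seed = 22)
  tum2 <- simulate_tumors(cores, seed = 23)
  expect_equal(nrow(tum2), 50)
  core1 <- cores[!duplicated(cores$image_id), ]
  expect_identical(tum2$er_true, core1$core_er_positive)
})

test_that("survival generator: null effect, censoring contract, errors", {
  tum <- simulate_tumors(3000, p_missing_stage = 0, p_missing_grade = 0,
                         seed = 24)
  null_t <- simulate_survival(tum, beta1 = 0, beta2 = 0, seed = 25)
  km <- km_fit(null_t, group = "er_true")
  expect_gt(km$p_value, 1e-3)   # ER-positive and negative indistinguishable

  frozen <- simulate_survival(tum, horizon = 0, seed = 26)
  expect_equal(sum(frozen$event), 0)
  expect_true(all(frozen$time == 0))

  expect_error(simulate_survival(tum, horizon = -1), "non-negative")

  s1 <- simulate_survival(tum, seed = 27)
  expect_identical(s1, simulate_survival(tum, seed = 27))
  expect_true(all(s1$time <= 15))
  expect_true(all(s1$time >= 0))
})
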