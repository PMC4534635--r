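test_that("preliminary UPS rewards expert agreement", {
  ev <- data.frame(user_id = c("a", "b"),
                   sub_image_id = c("e1", "s1"),
                   cancer_present = c(TRUE, TRUE))
  expert <- data.frame(sub_image_id = "e1", cancer_present = TRUE)
  u <- assign_preliminary_ups(ev, expert)
  expect_equal(u$preliminary_ups[u$user_id == "a"], 0.7)  # agreed
  expect_equal(u$preliminary_ups[u$user_id == "b"], 0.5)  # no overlap
  expert$cancer_present <- FALSE
  u2 <- assign_preliminary_ups(ev, expert)
  expect_equal(u2$preliminary_ups[u2$user_id == "a"], 0.5)  # disagreed
  expect_error(assign_preliminary_ups(ev[0, ], expert), "empty")
})

test_that("several expert overlaps resolve by strict majority", {
  expert <- data.frame(sub_image_id = c("e1", "e2", "e3"),
                       cancer_present = c(TRUE, TRUE, TRUE))
  ev <- data.frame(user_id = "a", sub_image_id = c("e1", "e2", "e3"),
                   cancer_present = c(TRUE, TRUE, FALSE))  # 2 of 3 agree
  expect_equal(assign_preliminary_ups(ev, expert)$preliminary_ups, 0.7)
  ev$cancer_present <- c(TRUE, FALSE, FALSE)               # 1 of 3
  expect_equal(assign_preliminary_ups(ev, expert)$preliminary_ups, 0.5)
  ev2 <- data.frame(user_id = "a", sub_image_id = c("e1", "e2"),
                    cancer_present = c(TRUE, FALSE))       # tie: stay at 0.5
  expect_equal(assign_preliminary_ups(ev2, expert)$preliminary_ups, 0.5)
})

test_that("modal classification is the weighted average of yes answers", {
  expect_equal(modal_classification(c(TRUE, FALSE), c(0.5, 0.5)), 0.5)
  expect_equal(modal_classification(c(TRUE, FALSE), c(0.7, 0.5)), 0.7 / 1.2)
  expect_equal(modal_classification(rep(TRUE, 4), rep(0.6, 4)), 1)
  expect_equal(modal_classification(c(TRUE, FALSE), c(0, 0)), 0.5)  # fallback
  expect_error(modal_classification(logical(0), numeric(0)), "no answers")
})

test_that("recalculated UPS applies the modal-agreement rules", {
  ev <- data.frame(user_id = c("a", "b", "c"),
                   sub_image_id = c("s1", "s2", "s3"),
                   cancer_present = c(TRUE, TRUE, FALSE))
  modal <- c(s1 = 0.8, s2 = 0.2, s3 = 0.3)
  u <- recalculate_ups(ev, modal)
  expect_equal(u$ups[u$user_id == "a"], 0.8)   # yes, leaning yes: the modal
  expect_equal(u$ups[u$user_id == "b"], 0)     # yes against a no-leaning crowd
  expect_equal(u$ups[u$user_id == "c"], 0.7)   # no, leaning no: 1 - modal
  expect_error(recalculate_ups(ev, c(s1 = 1.2, s2 = 0.2, s3 = 0.3)),
               "outside")
})

test_that("an uninformative consensus of exactly 0.5 scores 0.5 either way", {
  ev <- data.frame(user_id = c("a", "b"), sub_image_id = c("s1", "s1"),
                   cancer_present = c(TRUE, FALSE))
  u <- recalculate_ups(ev, c(s1 = 0.5))
  expect_equal(u$ups, c(0.5, 0.5))
})

test_that("a unanimous crowd is a fixed point reached in two iterations", {
  ev <- data.frame(
    user_id = rep(c("a", "b", "c"), each = 3),
    sub_image_id = rep(c("s1", "s2", "s3"), 3),
    cancer_present = rep(c(TRUE, TRUE, FALSE), 3))
  expert <- data.frame(sub_image_id = "s9", cancer_present = TRUE)
  fit <- iterate_to_convergence(ev, expert)
  expect_lte(fit$n_iterations, 2L)
  expect_true(fit$converged)
  expect_equal(fit$users$final_ups, rep(1, 3))
})

test_that("the iteration matches a step-by-step brute-force execution", {
  fx <- tiny_crowd_fixture()
  fit <- iterate_to_convergence(fx$events, fx$expert)
  oracle <- bf_ups(fx$events, fx$expert)
  expect_equal(fit$users$final_ups,
               unname(oracle$ups[fit$users$user_id]), tolerance = 1e-12)
  expect_equal(fit$n_iterations, oracle$iterations)

  set.seed(31)  # and on random crowds
  for (rep in 1:5) {
    ev <- data.frame(
      user_id = sample(letters[1:6], 30, TRUE),
      sub_image_id = sample(paste0("s", 1:8), 30, TRUE),
      cancer_present = runif(30) < 0.6)
    ev <- ev[!duplicated(ev[c("user_id", "sub_image_id")]), ]
    expert <- data.frame(sub_image_id = c("s1", "s2"),
                         cancer_present = c(TRUE, FALSE))
    fit <- iterate_to_convergence(ev, expert)
    oracle <- bf_ups(ev, expert)
    expect_equal(fit$users$final_ups,
                 unname(oracle$ups[fit$users$user_id]), tolerance = 1e-12)
  }
})

test_that("UPS values stay in [0,1] and no events are dropped", {
  cores <- simulate_cores(30, seed = 32)
  crowd <- simulate_crowd(120, seed = 33)
  ev <- simulate_classifications(cores, crowd, seed = 34)
  expert <- make_expert_set(cores, 60, seed = 35)
  fit <- iterate_to_convergence(ev, expert)
  expect_true(all(fit$users$final_ups >= 0 & fit$users$final_ups <= 1))
  expect_true(all(fit$users$preliminary_ups %in% c(0.5, 0.7)))
  expect_identical(sum(fit$users$n_scored), nrow(ev))
  expect_identical(sum(fit$consensus$n_scores), nrow(ev))
})

test_that("a lone dissenter against a strong consensus ends at UPS zero", {
  # ten reliable scorers agree everywhere; one user scores a single
  # sub-image and contradicts them
  ev <- data.frame(
    user_id = c(rep(paste0("u", 1:10), 2), "loner"),
    sub_image_id = c(rep(c("s1", "s2"), each = 10), "s1"),
    cancer_present = c(rep(TRUE, 20), FALSE))
  expert <- data.frame(sub_image_id = "s2", cancer_present = TRUE)
  fit <- iterate_to_convergence(ev, expert)
  expect_equal(fit$users$final_ups[fit$users$user_id == "loner"], 0)
  expect_true(all(fit$users$final_ups[fit$users$user_id != "loner"] > 0.9))
})

test_that("expert sub-images keep their expert answer as the consensus", {
  fx <- tiny_crowd_fixture()
  fit <- iterate_to_convergence(fx$events, fx$expert)
  expect_equal(
    fit$consensus$modal_cancer_prob[fit$consensus$sub_image_id == "s1"], 1)
  expect_true(fit$consensus$expert_scored[fit$consensus$sub_image_id == "s1"])
})
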