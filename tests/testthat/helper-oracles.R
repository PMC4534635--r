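## Independent oracles, kept deliberately naive: direct definitions and
## explicit loops, sharing no code with the package implementations.

# smallest value whose total weight of items <= value reaches half the total
bf_weighted_median <- function(values, weights) {
  half <- sum(weights) / 2
  for (v in sort(unique(values))) {
    if (sum(weights[values <= v]) >= half) return(v)
  }
  stop("unreachable")
}

# exhaustive positive/negative pair counting, ties worth 1/2
bf_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# literal step-by-step execution of the reliability algorithm with loops
bf_ups <- function(events, expert, tol = 3e-4, max_iter = 100L) {
  users <- unique(events$user_id)
  subs <- unique(events$sub_image_id)
  exp_ans <- setNames(as.numeric(expert$cancer_present), expert$sub_image_id)
  ups <- setNames(rep(0.5, length(users)), users)
  for (u in users) {
    a <- 0L; d <- 0L
    for (i in seq_len(nrow(events))) {
      if (events$user_id[i] != u) next
      s <- events$sub_image_id[i]
      if (!s %in% names(exp_ans)) next
      if (as.numeric(events$cancer_present[i]) == exp_ans[[s]]) a <- a + 1L
      else d <- d + 1L
    }
    if (a > d) ups[[u]] <- 0.7
  }
  it <- 0L
  repeat {
    it <- it + 1L
    modal <- list()
    for (s in subs) {
      if (s %in% names(exp_ans)) next
      num <- 0; den <- 0
      for (i in which(events$sub_image_id == s)) {
        w <- ups[[events$user_id[i]]]
        num <- num + w * as.numeric(events$cancer_present[i])
        den <- den + w
      }
      modal[[s]] <- if (den > 0) num / den else
        mean(as.numeric(events$cancer_present[events$sub_image_id == s]))
    }
    new_ups <- ups
    for (u in users) {
      sc <- c()
      for (i in which(events$user_id == u)) {
        s <- events$sub_image_id[i]
        m <- if (s %in% names(exp_ans)) exp_ans[[s]] else modal[[s]]
        y <- as.numeric(events$cancer_present[i])
        sc <- c(sc, if (m > 0.5) { if (y == 1) m else 0 }
                    else if (m < 0.5) { if (y == 0) 1 - m else 0 }
                    else 0.5)
      }
      new_ups[[u]] <- mean(sc)
    }
    delta <- abs(mean(new_ups) - mean(ups))
    ups <- new_ups
    if (delta < tol || it >= max_iter) break
  }
  list(ups = ups, iterations = it)
}

# tiny deterministic event-table fixture: 3 users, 4 sub-images, one expert
tiny_crowd_fixture <- function() {
  events <- data.frame(
    user_id = c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c"),
    sub_image_id = c("s1", "s2", "s3", "s1", "s2", "s4",
                     "s1", "s2", "s3", "s4"),
    cancer_present = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                       TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expert <- data.frame(sub_image_id = "s1", cancer_present = TRUE,
                       stringsAsFactors = FALSE)
  list(events = events, expert = expert)
}

perfect_crowd_config <- function() {
  crowd_config(p_detect_fixed = 1, noise_fixed = 0)
}
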