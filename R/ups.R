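## Iterative user-performance-score (UPS) estimation.
##
## Reliability of each crowd member is estimated from the binary
## cancer-present question alone: seed weights from agreement with a small
## expert-scored reference set, then alternate between (a) a UPS-weighted
## consensus ("modal classification") per sub-image and (b) re-scoring each
## user against that consensus, until the mean UPS stabilises.

validate_events <- function(events) {
  check_columns(events,
                c("user_id", "sub_image_id", "cancer_present"),
                "event table")
  if (nrow(events) == 0L) stop_invalid("event table is empty")
  if (!is.logical(events$cancer_present))
    stop_invalid("cancer_present must be logical")
  invisible(events)
}

#' Preliminary user performance scores from expert overlap
#'
#' Every crowd member starts at UPS 0.5. A member who scored at least one
#' sub-image in the expert reference set is promoted to 0.7 when they agreed
#' with the expert on the cancer-present question; with several expert
#' overlaps, promotion requires a strict majority of agreements. Experts
#' themselves carry a fixed UPS of 1 and are not part of the event table.
#'
#' @param events event table (`user_id`, `sub_image_id`, `cancer_present`).
#' @param expert reference table (`sub_image_id`, `cancer_present`).
#' @return data frame `user_id`, `n_scored`, `preliminary_ups`.
#' @export
assign_preliminary_ups <- function(events, expert) {
  validate_events(events)
  uf <- factor(events$user_id)
  n_scored <- as.integer(table(uf))
  ans <- expert$cancer_present[match(events$sub_image_id, expert$sub_image_id)]
  on_expert <- !is.na(ans)
  agree <- integer(nlevels(uf)); disagree <- integer(nlevels(uf))
  if (any(on_expert)) {
    ok <- events$cancer_present[on_expert] == ans[on_expert]
    idx <- as.integer(uf)[on_expert]
    agree <- tabulate(idx[ok], nbins = nlevels(uf))
    disagree <- tabulate(idx[!ok], nbins = nlevels(uf))
  }
  data.frame(
    user_id = levels(uf),
    n_scored = n_scored,
    preliminary_ups = ifelse(agree > disagree, 0.7, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Modal classification of one sub-image
#'
#' The UPS-weighted average of the binary cancer-present answers, read as a
#' pseudo-likelihood that the sub-image contains cancer cells. If every
#' weight is zero the unweighted mean is returned (an all-unreliable crowd is
#' treated as uninformative rather than undefined).
#'
#' @param answers logical (or 0/1) cancer-present answers, length >= 1.
#' @param weights current UPS weights, same length.
#' @return value in `[0, 1]`.
#' @export
modal_classification <- function(answers, weights) {
  if (length(answers) == 0L) stop_invalid("modal_classification: no answers")
  if (length(answers) != length(weights))
    stop_invalid("answers and weights differ in length")
  y <- as.numeric(answers)
  if (sum(weights) == 0) return(mean(y))
  sum(weights * y) / sum(weights)
}

## Per-event agreement score against a modal value m in [0,1]:
##   yes & m > 0.5 -> m;  no & m < 0.5 -> 1 - m;  disagreement -> 0;
##   m == 0.5 -> 0.5 (uninformative consensus neither rewards nor punishes).
event_score <- function(y, m) {
  if (any(m < 0 | m > 1)) stop("modal value outside [0,1]", call. = FALSE)
  ifelse(m > 0.5, ifelse(y == 1, m, 0),
         ifelse(m < 0.5, ifelse(y == 0, 1 - m, 0), 0.5))
}

#' Recalculate user performance scores against a consensus
#'
#' Each user's UPS becomes the mean of their per-sub-image agreement scores:
#' the modal value when they answered yes and the consensus leans yes
#' (> 0.5), one minus the modal value when they answered no and it leans no
#' (< 0.5), and 0 when they disagree with the leaning. Expert-scored
#' sub-images use the expert answer as a degenerate modal value of 0 or 1.
#'
#' @param events event table.
#' @param modal named numeric vector of modal values keyed by `sub_image_id`
#'   (expert sub-images may be included at 0/1, or supplied via `expert`).
#' @param expert optional reference table; its answers override `modal`.
#' @return data frame `user_id`, `n_scored`, `ups`.
#' @export
recalculate_ups <- function(events, modal, expert = NULL) {
  validate_events(events)
  m <- unname(modal[events$sub_image_id])
  if (!is.null(expert)) {
    ans <- expert$cancer_present[match(events$sub_image_id,
                                       expert$sub_image_id)]
    m[!is.na(ans)] <- as.numeric(ans[!is.na(ans)])
  }
  if (anyNA(m)) stop_invalid("no modal value for some scored sub-images")
  sc <- event_score(as.numeric(events$cancer_present), m)
  uf <- factor(events$user_id)
  data.frame(
    user_id = levels(uf),
    n_scored = as.integer(table(uf)),
    ups = as.numeric(rowsum(sc, uf) / as.integer(table(uf))),
    stringsAsFactors = FALSE
  )
}

#' Iterate user performance scores to convergence
#'
#' Runs the full reliability-estimation loop: preliminary UPS from expert
#' agreement, then alternating modal classification (over sub-images without
#' an expert answer) and UPS recalculation until the absolute change in the
#' mean UPS drops below `tol`.
#'
#' @param events event table (`user_id`, `sub_image_id`, `cancer_present`;
#'   an `image_id` column, if present, is carried into the consensus table).
#' @param expert expert reference table (`sub_image_id`, `cancer_present`).
#' @param tol convergence tolerance on the change in mean UPS (default 3e-4).
#' @param max_iter iteration cap; reaching it sets `converged = FALSE` with a
#'   warning rather than an error.
#' @return list of class `ups_fit`: `users` (with `preliminary_ups`,
#'   `final_ups`, `n_scored`), `consensus` (per sub-image modal probability
#'   under the final weights plus plain-median ordinal answers),
#'   `n_iterations`, `converged`.
#' @export
iterate_to_convergence <- function(events, expert, tol = 3e-4,
                                   max_iter = 100L) {
  validate_events(events)
  if (!is.numeric(tol) || tol <= 0) stop_invalid("tol must be > 0")
  max_iter <- check_count(max_iter, "max_iter", min = 1L)

  uf <- factor(events$user_id)
  sf <- factor(events$sub_image_id)
  ui <- as.integer(uf)
  y <- as.numeric(events$cancer_present)
  n_user <- tabulate(ui, nbins = nlevels(uf))

  exp_ans <- expert$cancer_present[match(levels(sf), expert$sub_image_id)]
  is_exp_sub <- !is.na(exp_ans)
  si <- as.integer(sf)
  ev_exp <- is_exp_sub[si]
  m_exp_ev <- as.numeric(exp_ans[si])      # NA off the expert set

  prelim <- assign_preliminary_ups(events, expert)
  ups <- prelim$preliminary_ups[match(levels(uf), prelim$user_id)]

  n_sub <- tabulate(si, nbins = nlevels(sf))
  sum_y <- as.numeric(rowsum(y, si))       # per sub-image yes count

  modal_ev <- numeric(length(y))
  n_it <- 0L
  converged <- FALSE
  repeat {
    n_it <- n_it + 1L
    w <- ups[ui]
    den <- as.numeric(rowsum(w, si))
    num <- as.numeric(rowsum(w * y, si))
    m_sub <- ifelse(den > 0, num / den, sum_y / n_sub)
    modal_ev <- ifelse(ev_exp, m_exp_ev, m_sub[si])
    sc <- event_score(y, modal_ev)
    new_ups <- as.numeric(rowsum(sc, ui)) / n_user
    delta <- abs(mean(new_ups) - mean(ups))
    ups <- new_ups
    if (delta < tol) { converged <- TRUE; break }
    if (n_it >= max_iter) {
      warning(sprintf(
        "UPS iteration stopped at max_iter = %d (mean change %.2g >= tol %.2g)",
        max_iter, delta, tol))
      break
    }
  }

  users <- data.frame(
    user_id = levels(uf),
    n_scored = n_user,
    preliminary_ups = prelim$preliminary_ups[match(levels(uf),
                                                   prelim$user_id)],
    final_ups = ups,
    stringsAsFactors = FALSE
  )

  # final-weight modal probability per sub-image (expert answer where fixed),
  # plus plain-median ordinal consensus for downstream scoring
  w <- ups[ui]
  den <- as.numeric(rowsum(w, si))
  num <- as.numeric(rowsum(w * y, si))
  m_sub <- ifelse(den > 0, num / den, sum_y / n_sub)
  m_sub[is_exp_sub] <- as.numeric(exp_ans[is_exp_sub])
  has_ordinals <- all(c("cell_count_bin", "proportion_bin",
                        "intensity_bin") %in% names(events))
  if (has_ordinals) {
    plain <- consensus_table(events, variant = "plain")
    consensus <- plain[match(levels(sf), plain$sub_image_id), , drop = FALSE]
    consensus$variant <- NULL
  } else {
    consensus <- data.frame(sub_image_id = levels(sf), n_scores = n_sub,
                            stringsAsFactors = FALSE)
  }
  consensus$modal_cancer_prob <- m_sub
  consensus$expert_scored <- is_exp_sub
  rownames(consensus) <- NULL

  structure(list(users = users, consensus = consensus,
                 n_iterations = n_it, converged = converged,
                 tol = tol),
            class = "ups_fit")
}

#' @export
print.ups_fit <- function(x, ...) {
  cat(sprintf("UPS fit: %d users, %d sub-images, %d iteration(s)%s\n",
              nrow(x$users), nrow(x$consensus), x$n_iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  mean final UPS %.3f; %d user(s) at zero\n",
              mean(x$users$final_ups), sum(x$users$final_ups == 0)))
  invisible(x)
}
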