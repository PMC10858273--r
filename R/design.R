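# Counterbalanced 16-session schedule for one triad.
#
# Two proposer slots ("P1", "P2") and one responder play 16 sessions of
# 8 trials.  Eight sessions are dyadic (one proposer active per trial,
# alternating every two trials), eight are triadic (a contiguous block
# of 4 simultaneous and a contiguous block of 4 consecutive trials).
# All counterbalancing constraints are aggregate counts, so the concrete
# orderings below are one deterministic schedule satisfying them.

#' Generate the counterbalanced 16-session schedule
#'
#' Builds the full trial plan for one triad: which condition each session
#' is in, which proposer slot sits on the left, which proposer is active
#' on each dyadic trial, the block order of simultaneous vs consecutive
#' trials within triadic sessions, and which proposer offers first on
#' each consecutive trial.
#'
#' The schedule satisfies, by construction: 8 dyadic + 8 triadic sessions
#' alternating from `start_condition`; sides swap every two sessions so
#' each slot sits left in 8 sessions (4 dyadic + 4 triadic from each
#' side); the simultaneous block comes first in exactly 4 of the 8
#' triadic sessions; within every consecutive block each proposer goes
#' first on exactly 2 of 4 trials and each proposer opens the block in 4
#' triadic sessions; on dyadic sessions each proposer makes 4 offers,
#' alternating every two trials, and each opens 4 of the 8 sessions.
#'
#' @param start_condition `"dyadic"` or `"triadic"`: the condition of
#'   session 1 (conditions then alternate).
#' @param first_leader `"P1"` or `"P2"`: the proposer slot that opens the
#'   first consecutive block and the first dyadic session.
#' @param seed Unused (the schedule is deterministic); accepted so that
#'   callers can treat design generation uniformly with stochastic steps.
#' @return A tibble of class `ug_design` with one row per trial slot
#'   (128 rows): `session_index`, `trial_index`, `condition`,
#'   `left_slot`, `right_slot`, `active_slot` (dyadic only),
#'   `first_slot` and `first_side` (consecutive only).
#' @export
#' @examples
#' d <- generate_design("triadic", "P1")
#' verify_design(d)
generate_design <- function(start_condition = c("dyadic", "triadic"),
                            first_leader = c("P1", "P2"),
                            seed = NULL) {
  start_condition <- match.arg(start_condition)
  first_leader <- match.arg(first_leader)
  other <- function(p) if_else(p == "P1", "P2", "P1")

  block <- if (start_condition == "dyadic") c("dyadic", "triadic") else
    c("triadic", "dyadic")
  session_block <- rep(block, 8)

  # sides swap every two sessions; P1 starts on the left
  left_slot_session <- rep(rep(c("P1", "P2"), each = 2), 4)

  # alternate which block type comes first across triadic sessions
  triadic_sessions <- which(session_block == "triadic")
  sim_first <- rep(c(TRUE, FALSE), 4)

  # consecutive-block leader alternates across triadic sessions;
  # within a block the leader pattern is L O O L (leader, other,
  # other, leader), giving each proposer 2 first positions per block
  leaders <- rep(c(first_leader, other(first_leader)), 4)

  # dyadic opener alternates across dyadic sessions
  dyadic_sessions <- which(session_block == "dyadic")
  openers <- rep(c(first_leader, other(first_leader)), 4)

  rows <- vector("list", 16)
  ti_sim <- 0L; ti_dy <- 0L
  for (s in 1:16) {
    left <- left_slot_session[s]
    right <- other(left)
    if (session_block[s] == "dyadic") {
      ti_dy <- ti_dy + 1L
      op <- openers[ti_dy]
      active <- rep(c(op, other(op)), each = 2, times = 2)
      rows[[s]] <- tibble(
        session_index = s, trial_index = 1:8, condition = "dyadic",
        left_slot = left, right_slot = right, active_slot = active,
        first_slot = NA_character_, first_side = NA_character_)
    } else {
      ti_sim <- ti_sim + 1L
      lead <- leaders[ti_sim]
      cons_first <- c(lead, other(lead), other(lead), lead)
      cond4 <- if (sim_first[ti_sim]) {
        c(rep("triadic_simultaneous", 4), rep("triadic_consecutive", 4))
      } else {
        c(rep("triadic_consecutive", 4), rep("triadic_simultaneous", 4))
      }
      first_slot <- rep(NA_character_, 8)
      first_slot[cond4 == "triadic_consecutive"] <- cons_first
      rows[[s]] <- tibble(
        session_index = s, trial_index = 1:8, condition = cond4,
        left_slot = left, right_slot = right,
        active_slot = NA_character_, first_slot = first_slot,
        first_side = if_else(is.na(first_slot), NA_character_,
                             if_else(first_slot == left, "left", "right")))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("ug_design", class(out))
  out
}

#' Check every counterbalance constraint of a schedule
#'
#' Recounts each aggregate constraint the schedule must satisfy and
#' reports them one by one, so that a hand-edited or imported schedule
#' can be audited.
#'
#' @param design `ug_design` tibble (or any data frame with its columns).
#' @return Tibble with columns `constraint`, `observed`, `expected`,
#'   `pass`.
#' @export
verify_design <- function(design) {
  design <- as_tibble(design)
  sess <- design %>%
    group_by(.data$session_index) %>%
    summarise(
      block = if_else(all(.data$condition == "dyadic"), "dyadic",
                      "triadic"),
      left_slot = first(.data$left_slot),
      sim_first = first(.data$condition) == "triadic_simultaneous",
      opener = first(.data$active_slot),
      block_leader = first(stats::na.omit(c(.data$first_slot,
                                            NA_character_))),
      .groups = "drop")

  res <- list()
  chk <- function(constraint, observed, expected) {
    res[[length(res) + 1L]] <<- tibble(
      constraint = constraint,
      observed = paste(observed, collapse = ","),
      expected = paste(expected, collapse = ","),
      pass = isTRUE(all(observed == expected)))
  }

  chk("16 sessions of 8 trials (128 slots)", nrow(design), 128L)
  chk("8 dyadic sessions", sum(sess$block == "dyadic"), 8L)
  chk("8 triadic sessions", sum(sess$block == "triadic"), 8L)
  chk("conditions alternate between sessions",
      sum(sess$block[-1] != sess$block[-nrow(sess)]),
      max(nrow(sess) - 1L, 0L))

  tri <- design %>% filter(.data$condition != "dyadic")
  tri_sess <- sess %>% filter(.data$block == "triadic")
  chk("triadic sessions: 4 simultaneous + 4 consecutive trials each",
      tri %>% count(.data$session_index,
                    sim = .data$condition == "triadic_simultaneous") %>%
        pull(n) %>% unique(),
      4L)
  contiguous <- tri %>%
    group_by(.data$session_index) %>%
    summarise(ok = length(rle(.data$condition)$values) == 2L,
              .groups = "drop")
  chk("simultaneous/consecutive form two contiguous blocks",
      sum(contiguous$ok), nrow(contiguous))
  chk("simultaneous block first in exactly 4 triadic sessions",
      sum(tri_sess$sim_first), 4L)

  cons <- design %>% filter(.data$condition == "triadic_consecutive")
  per_sess_first <- cons %>%
    count(.data$session_index, .data$first_slot)
  chk("each proposer first on exactly 2 of 4 consecutive trials",
      if (nrow(per_sess_first) > 0) unique(per_sess_first$n) else integer(),
      2L)
  leader_counts <- table(factor(tri_sess$block_leader,
                                levels = c("P1", "P2")))
  chk("each proposer leads the consecutive block in 4 sessions",
      as.integer(leader_counts), c(4L, 4L))

  dyad <- design %>% filter(.data$condition == "dyadic")
  offers_per <- dyad %>% count(.data$session_index, .data$active_slot)
  chk("each proposer makes 4 offers per dyadic session",
      if (nrow(offers_per) > 0) unique(offers_per$n) else integer(), 4L)
  alt_ok <- dyad %>%
    group_by(.data$session_index) %>%
    summarise(ok = all(rle(.data$active_slot)$lengths == 2L),
              .groups = "drop")
  chk("dyadic proposers alternate every two trials",
      sum(alt_ok$ok), nrow(alt_ok))
  opener_counts <- table(factor(sess$opener[sess$block == "dyadic"],
                                levels = c("P1", "P2")))
  chk("each proposer opens 4 of 8 dyadic sessions",
      as.integer(opener_counts), c(4L, 4L))

  left_counts <- table(factor(sess$left_slot, levels = c("P1", "P2")))
  chk("each proposer sits left in 8 sessions",
      as.integer(left_counts), c(8L, 8L))
  swap_ok <- nrow(sess) == 16L &&
    all(tapply(sess$left_slot, ceiling(sess$session_index / 2),
               function(x) length(unique(x)) == 1L)) &&
    all(rle(sess$left_slot)$lengths == 2L)
  chk("sides swap every two sessions", isTRUE(swap_ok), TRUE)
  side_cond <- sess %>% count(.data$left_slot, .data$block)
  chk("from each side: 4 dyadic and 4 triadic sessions",
      if (nrow(side_cond) > 0) unique(side_cond$n) else integer(), 4L)

  bind_rows(res)
}

#' Export a schedule as a blank trial table
#'
#' Renders a design as canonical trial rows with offers and acceptance
#' left blank, ready to be filled by the game engine or by hand-coded
#' observations.
#'
#' @param design `ug_design` tibble.
#' @param triad_id Triad identifier used for the `triad_id` column and to
#'   derive proposer/responder names (`<triad>_P1`, `<triad>_P2`,
#'   `<triad>_R`).
#' @return Tibble in canonical trial-column order (not validated: offers
#'   are missing).
#' @export
design_to_trials <- function(design, triad_id = "T1") {
  ids <- setNames(paste0(triad_id, "_", c("P1", "P2")), c("P1", "P2"))
  as_tibble(design) %>%
    mutate(
      triad_id = triad_id,
      left_proposer = unname(ids[.data$left_slot]),
      right_proposer = unname(ids[.data$right_slot]),
      responder = paste0(triad_id, "_R"),
      offer_left = NA_integer_, offer_right = NA_integer_,
      accepted_side = NA_character_) %>%
    select(all_of(ug_trial_columns()))
}
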