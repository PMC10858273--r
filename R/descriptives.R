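# Descriptive statistics over a trial table.
#
# All helpers treat offer 0 as "no sent offer" and return NaN (flagged
# undefined) when no qualifying trials exist, rather than erroring, so
# reports can be produced from partial datasets.

sent <- function(x) !is.na(x) & x >= 1L

session_condition <- function(condition) {
  if_else(condition == "dyadic", "dyadic", "triadic")
}

#' Mean first offer per session condition
#'
#' The mean of each session's first-trial sent offers, split by whether
#' the session is dyadic or triadic.  On triadic first trials both
#' proposers' offers enter the mean; dyadic first trials contribute the
#' single active proposer's offer.
#'
#' @param trials `ug_trials` tibble.
#' @return Named numeric vector `c(dyadic = , triadic = )` (NaN when a
#'   condition has no qualifying first offers).
#' @export
mean_first_offers <- function(trials) {
  trials <- as_ug_trials(trials)
  firsts <- trials %>%
    filter(.data$trial_index == 1L) %>%
    mutate(cond = session_condition(.data$condition)) %>%
    tidyr::pivot_longer(c("offer_left", "offer_right"),
                        values_to = "offer") %>%
    filter(sent(.data$offer))
  out <- c(dyadic = NaN, triadic = NaN)
  if (nrow(firsts) > 0) {
    m <- tapply(firsts$offer, firsts$cond, mean)
    out[names(m)] <- m
  }
  out
}

#' Responder accuracy: acceptance rate of the highest offer
#'
#' Among triadic trials where both proposers sent offers and the offers
#' differ, the share in which the responder accepted the larger one.
#' Equal-offer trials are excluded ("highest" is undefined on ties).
#'
#' @param trials `ug_trials` tibble.
#' @return Proportion in \[0, 1\], or NaN if no qualifying trials.
#' @export
highest_offer_acceptance_rate <- function(trials) {
  q <- triadic_two_offer(trials) %>%
    filter(.data$offer_left != .data$offer_right,
           .data$accepted_side %in% c("left", "right"))
  if (nrow(q) == 0) return(NaN)
  mean(if_else(q$offer_left > q$offer_right, "left", "right") ==
         q$accepted_side)
}

triadic_two_offer <- function(trials) {
  as_ug_trials(trials) %>%
    filter(.data$condition != "dyadic",
           sent(.data$offer_left), sent(.data$offer_right))
}

#' Mean offer ratio on discrimination errors
#'
#' Over triadic trials where the responder accepted the *lower* of two
#' unequal sent offers, the mean of `min(offer) / max(offer)`: the
#' closer this ratio is to 1, the harder the discrimination that failed.
#'
#' @param trials `ug_trials` tibble.
#' @return Mean ratio, or NaN if the responder never erred.
#' @export
mean_error_ratio <- function(trials) {
  q <- triadic_two_offer(trials) %>%
    filter(.data$offer_left != .data$offer_right,
           .data$accepted_side %in% c("left", "right")) %>%
    filter(if_else(.data$offer_left > .data$offer_right, "left",
                   "right") != .data$accepted_side)
  if (nrow(q) == 0) return(NaN)
  mean(pmin(q$offer_left, q$offer_right) /
         pmax(q$offer_left, q$offer_right))
}

#' Responder side-choice rates on consecutive trials
#'
#' Conditional probabilities of accepting the side the first offer came
#' from: P(accept left | first offer left) and P(accept right | first
#' offer right), over consecutive triadic trials with a recorded
#' acceptance.
#'
#' @param trials `ug_trials` tibble.
#' @return Named numeric vector
#'   `c(left_given_first_left = , right_given_first_right = )`.
#' @export
side_choice_rates <- function(trials) {
  q <- as_ug_trials(trials) %>%
    filter(.data$condition == "triadic_consecutive",
           !is.na(.data$first_side),
           .data$accepted_side %in% c("left", "right"))
  rate <- function(side) {
    qq <- q[q$first_side == side, ]
    if (nrow(qq) == 0) return(NaN)
    mean(qq$accepted_side == side)
  }
  c(left_given_first_left = rate("left"),
    right_given_first_right = rate("right"))
}

#' Total proportional offer per proposer-session
#'
#' For every proposer and session, the grapes that proposer sent summed
#' over the chosen trial subset, divided by the maximum they could have
#' sent (8 grapes times the number of trials in the subset on which that
#' proposer had the opportunity to offer).  With the default per-proposer
#' denominator a full triadic session has maximum 64 and a full dyadic
#' session 32 (each proposer acts on 4 of the 8 trials); first-half
#' subsets halve these to 32 and 16.  `denominator = "session"` instead
#' divides by the session-level maximum (64 full / 32 half) regardless of
#' opportunity.
#'
#' @param trials `ug_trials` tibble.
#' @param subset `"full"` (all 8 trials) or `"first_half"` (trials 1-4).
#' @param denominator `"proposer"` (default) or `"session"`.
#' @return Tibble with one row per proposer-session: `triad_id`,
#'   `proposer_id`, `session_index`, `condition` (session block, and for
#'   first-half triadic sessions the block type of trials 1-4), `total`,
#'   `max_possible`, `prop`.
#' @export
total_proportional_offer <- function(trials,
                                     subset = c("full", "first_half"),
                                     denominator = c("proposer",
                                                     "session")) {
  subset <- match.arg(subset)
  denominator <- match.arg(denominator)
  trials <- as_ug_trials(trials)
  if (subset == "first_half") {
    trials <- filter(trials, .data$trial_index <= 4L)
  }
  half_condition <- trials %>%
    as_tibble() %>%
    group_by(.data$triad_id, .data$session_index) %>%
    summarise(block_condition = .data$condition[1], .groups = "drop")

  long <- bind_rows(
    trials %>% mutate(proposer_id = .data$left_proposer,
                      offer = .data$offer_left),
    trials %>% mutate(proposer_id = .data$right_proposer,
                      offer = .data$offer_right)) %>%
    mutate(opportunity = .data$condition != "dyadic" |
             !is.na(.data$offer)) %>%
    filter(.data$opportunity)

  n_session_trials <- if (subset == "full") 8L else 4L
  long %>%
    group_by(.data$triad_id, .data$proposer_id, .data$session_index) %>%
    summarise(
      total = sum(.data$offer[sent(.data$offer)]),
      n_opportunities = dplyr::n(),
      .groups = "drop") %>%
    left_join(half_condition, by = c("triad_id", "session_index")) %>%
    mutate(
      condition = if (subset == "full") {
        session_condition(.data$block_condition)
      } else {
        .data$block_condition
      },
      max_possible = if (denominator == "proposer") {
        8L * .data$n_opportunities
      } else {
        8L * n_session_trials
      },
      prop = .data$total / .data$max_possible) %>%
    select("triad_id", "proposer_id", "session_index", "condition",
           "total", "max_possible", "prop")
}

#' Full descriptive report
#'
#' Bundles the printed descriptive statistics: mean first offers per
#' condition, the responder's highest-offer acceptance rate, the mean
#' offer ratio on discrimination errors, side-choice rates, and
#' per-condition trial counts.
#'
#' @param trials `ug_trials` tibble.
#' @return A list of class `ug_descriptives`.
#' @export
descriptive_report <- function(trials) {
  trials <- as_ug_trials(trials)
  out <- list(
    mean_first_offer = mean_first_offers(trials),
    highest_offer_acceptance_rate = highest_offer_acceptance_rate(trials),
    mean_error_ratio = mean_error_ratio(trials),
    side_choice = side_choice_rates(trials),
    n_trials = table(trials$condition),
    n_triads = length(unique(trials$triad_id)))
  class(out) <- "ug_descriptives"
  out
}

#' @export
print.ug_descriptives <- function(x, ...) {
  cat("Ultimatum-game descriptive report\n")
  cat(sprintf("  triads: %d; trials: %d (%s)\n", x$n_triads,
              sum(x$n_trials),
              paste(names(x$n_trials), as.integer(x$n_trials),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  mean first offer: dyadic %.2f, triadic %.2f grapes\n",
              x$mean_first_offer[["dyadic"]],
              x$mean_first_offer[["triadic"]]))
  cat(sprintf("  highest-offer acceptance rate: %.3f\n",
              x$highest_offer_acceptance_rate))
  cat(sprintf("  mean offer ratio on errors: %.3f\n",
              x$mean_error_ratio))
  cat(sprintf("  P(accept left | first left) = %.2f, P(accept right | first right) = %.2f\n",
              x$side_choice[["left_given_first_left"]],
              x$side_choice[["right_given_first_right"]]))
  invisible(x)
}
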