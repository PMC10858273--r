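# Strategy zoo and game engine.
#
# A proposer strategy is a function(state) -> integer offer in 1..8 (or
# 0L for "no offer").  `state` is a list with the proposer's memory:
#   last_own_offer, last_own_accepted  -- previous sent offer this
#     session (NA on the session's first offering trial),
#   first_offer_seen -- the standing first offer when acting second on a
#     consecutive trial, otherwise NA,
#   condition, session_index, trial_index -- current trial context.
# Strategies draw randomness from the R RNG, which the game engine seeds.
# A responder strategy is a function(offer_left, offer_right) ->
# "left"/"right"/"none".

new_state <- function() {
  list(last_own_offer = NA_integer_, last_own_accepted = NA,
       first_offer_seen = NA_integer_,
       condition = NA_character_, session_index = NA_integer_,
       trial_index = NA_integer_)
}

#' Minimal-offer rule
#'
#' Always offers 1 grape, the smallest sendable amount: the rational
#' proposer of the classical dyadic ultimatum game.
#'
#' @param state Proposer state list (ignored).
#' @return Offer of 1.
#' @export
propose_minimal <- function(state) 1L

#' Reluctantly increasing proposer rule
#'
#' Starts at `start`; after a rejection raises the previous offer by
#' `step_up` (never above `cap`); after an acceptance repeats the
#' previous offer, or with probability `p_decrease_after_accept` lowers
#' it by 1 (never below `floor`).  This is the proposer archetype used
#' in the power analysis: generosity rises only when forced to.
#'
#' @param state Proposer state list.
#' @param start First offer of a session (default 1).
#' @param step_up Increment applied after a rejection (default 1).
#' @param p_decrease_after_accept Probability of decreasing by 1 after an
#'   acceptance (default 0.25).
#' @param floor,cap Offer bounds (defaults 1 and 8).
#' @return Integer offer.
#' @export
propose_reluctant_increase <- function(state, start = 1L, step_up = 1L,
                                       p_decrease_after_accept = 0.25,
                                       floor = 1L, cap = 8L) {
  stopifnot(start >= floor, start <= cap, step_up >= 0,
            p_decrease_after_accept >= 0, p_decrease_after_accept <= 1)
  last <- state$last_own_offer
  if (is.na(last)) return(as.integer(start))
  if (isTRUE(state$last_own_accepted)) {
    if (runif(1) < p_decrease_after_accept) {
      return(as.integer(max(last - 1L, floor)))
    }
    return(as.integer(last))
  }
  as.integer(min(last + step_up, cap))
}

#' Threshold outbidder rule
#'
#' When acting second on a consecutive trial with a visible first offer
#' `f`, outbids with `f + 1` whenever the proposer's own residual share
#' `8 - (f + 1)` would still be at least `share_threshold`; otherwise
#' (and on all other trials) delegates to `fallback`.  At the default
#' threshold of 4 this outbids exactly first offers of 0..3: the
#' motivational threshold where outbidding stops paying more than the
#' responder gets.
#'
#' @param state Proposer state list.
#' @param share_threshold Minimum own share (grapes kept) required to
#'   outbid (default 4).
#' @param fallback Strategy function used when not outbidding (default
#'   [propose_minimal]).
#' @return Integer offer.
#' @export
propose_outbidder <- function(state, share_threshold = 4L,
                              fallback = propose_minimal) {
  f <- state$first_offer_seen
  if (!is.na(f) && 8L - (f + 1L) >= share_threshold) {
    return(as.integer(min(f + 1L, 8L)))
  }
  fallback(state)
}

#' Reward-maximizing responder with ratio-dependent error
#'
#' Accepts the larger of the two standing offers, with a discrimination
#' error that grows as the ratio between the offers approaches one
#' (Weber-like numerical discrimination): the smaller offer is taken with
#' probability `0.5 * exp(-(1 - r) / weber_w)` where `r = min/max`.
#' `weber_w = 0` gives an exact maximizer.  Equal offers are broken by
#' `side_bias` (probability of choosing LEFT).  A lone sent offer is
#' always accepted; if neither side holds a sent offer the outcome is
#' `"none"`.
#'
#' @param offer_left,offer_right Integer offers (NA or 0 = no sent offer).
#' @param weber_w Non-negative width of the discrimination error.
#' @param side_bias Probability of choosing LEFT on exactly equal offers.
#' @return `"left"`, `"right"` or `"none"`.
#' @export
respond_maximizer <- function(offer_left, offer_right, weber_w = 0,
                              side_bias = 0.5) {
  stopifnot(weber_w >= 0, side_bias >= 0, side_bias <= 1)
  l_ok <- !is.na(offer_left) && offer_left >= 1L
  r_ok <- !is.na(offer_right) && offer_right >= 1L
  if (!l_ok && !r_ok) return("none")
  if (l_ok && !r_ok) return("left")
  if (r_ok && !l_ok) return("right")
  if (offer_left == offer_right) {
    return(if (runif(1) < side_bias) "left" else "right")
  }
  r <- min(offer_left, offer_right) / max(offer_left, offer_right)
  eps <- if (weber_w == 0) 0 else 0.5 * exp(-(1 - r) / weber_w)
  larger <- if (offer_left > offer_right) "left" else "right"
  smaller <- if (larger == "left") "right" else "left"
  if (runif(1) < eps) smaller else larger
}

# --- strategy constructors -------------------------------------------------

#' Strategy constructors
#'
#' Convenience constructors binding parameters into strategy functions
#' for [simulate_experiment()].  `strategy_fixed(k)` always offers `k`;
#' `strategy_by_condition()` dispatches on the current trial's condition
#' block (dyadic vs triadic), which power scenarios use to give agents
#' different behaviour in the two game types.
#'
#' @param p_decrease_after_accept,start,step_up Passed to
#'   [propose_reluctant_increase()].
#' @param share_threshold,fallback Passed to [propose_outbidder()].
#' @param offer Fixed offer for `strategy_fixed` and
#'   `strategy_noisy_fixed`.
#' @param jitter_p Probability that `strategy_noisy_fixed` deviates one
#'   grape up or down (clamped to 1..8); behavioural noise that keeps
#'   within-condition offer variance positive.
#' @param dyadic,triadic Strategy functions for `strategy_by_condition`.
#' @param weber_w,side_bias Passed to [respond_maximizer()].
#' @return A strategy function.
#' @name strategies
NULL

#' @rdname strategies
#' @export
strategy_minimal <- function() propose_minimal

#' @rdname strategies
#' @export
strategy_fixed <- function(offer) {
  stopifnot(offer >= 1, offer <= 8)
  force(offer)
  function(state) as.integer(offer)
}

#' @rdname strategies
#' @export
strategy_noisy_fixed <- function(offer, jitter_p = 0.2) {
  stopifnot(offer >= 1, offer <= 8, jitter_p >= 0, jitter_p <= 1)
  function(state) {
    o <- as.integer(offer)
    if (runif(1) < jitter_p) {
      o <- o + sample(c(-1L, 1L), 1)
    }
    max(1L, min(8L, o))
  }
}

#' @rdname strategies
#' @export
strategy_reluctant <- function(start = 1L, step_up = 1L,
                               p_decrease_after_accept = 0.25) {
  function(state) {
    propose_reluctant_increase(state, start = start, step_up = step_up,
                               p_decrease_after_accept =
                                 p_decrease_after_accept)
  }
}

#' @rdname strategies
#' @export
strategy_outbidder <- function(share_threshold = 4L,
                               fallback = NULL) {
  if (is.null(fallback)) fallback <- strategy_reluctant()
  function(state) {
    propose_outbidder(state, share_threshold = share_threshold,
                      fallback = fallback)
  }
}

#' @rdname strategies
#' @export
strategy_by_condition <- function(dyadic, triadic) {
  function(state) {
    if (identical(state$condition, "dyadic")) dyadic(state)
    else triadic(state)
  }
}

#' @rdname strategies
#' @export
responder_maximizer <- function(weber_w = 0, side_bias = 0.5) {
  function(offer_left, offer_right) {
    respond_maximizer(offer_left, offer_right, weber_w = weber_w,
                      side_bias = side_bias)
  }
}

#' Look up a strategy by name
#'
#' Resolves the strategy zoo entries used in YAML configuration files.
#'
#' @param spec Either a strategy function (returned unchanged), a string
#'   naming a zoo entry (`"minimal"`, `"fixed"`, `"reluctant"`,
#'   `"outbidder"`), or a list with elements `name` and optional
#'   parameters.
#' @return A strategy function.
#' @export
resolve_strategy <- function(spec) {
  if (is.function(spec)) return(spec)
  if (is.character(spec)) spec <- list(name = spec)
  name <- spec$name
  pars <- spec[setdiff(names(spec), "name")]
  ctor <- switch(name,
    minimal = strategy_minimal,
    fixed = strategy_fixed,
    noisy_fixed = strategy_noisy_fixed,
    reluctant = strategy_reluctant,
    outbidder = strategy_outbidder,
    abort(paste0("unknown strategy: ", name), class = "ug_config_error"))
  do.call(ctor, pars)
}

# --- game engine -----------------------------------------------------------

#' Play a schedule into a trial dataset
#'
#' Runs the game engine over a design: on simultaneous trials both
#' proposers offer without seeing each other; on consecutive trials the
#' scheduled first proposer offers, the second proposer sees that offer
#' before offering; on dyadic trials only the scheduled proposer acts.
#' The responder then accepts one side (always accepting a lone sent
#' offer).  Proposer memory resets at session boundaries by default, so
#' the first trial of each session is predecessor-free, matching the
#' structure the escalation models assume.
#'
#' @param design `ug_design` schedule from [generate_design()].
#' @param proposer1,proposer2 Strategy functions for slots P1 and P2.
#' @param responder Responder function, e.g. [responder_maximizer()].
#' @param triad_id Triad identifier.
#' @param seed Integer seed; the run is reproducible given identical
#'   arguments and seed.
#' @param reset_each_session Reset proposer memory at session boundaries
#'   (default TRUE).
#' @param p_no_offer Probability that a proposer fails to send an offer
#'   within the time limit (recorded as offer 0; default 0).
#' @return Validated `ug_trials` tibble of 128 trials.
#' @export
simulate_experiment <- function(design, proposer1, proposer2, responder,
                                triad_id = "T1", seed = NULL,
                                reset_each_session = TRUE,
                                p_no_offer = 0) {
  stopifnot(p_no_offer >= 0, p_no_offer < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  proposer1 <- resolve_strategy(proposer1)
  proposer2 <- resolve_strategy(proposer2)
  strategies <- list(P1 = proposer1, P2 = proposer2)
  states <- list(P1 = new_state(), P2 = new_state())

  skeleton <- design_to_trials(design, triad_id = triad_id)
  design <- as_tibble(design)
  offers_l <- offers_r <- rep(NA_integer_, nrow(design))
  accepted <- rep(NA_character_, nrow(design))

  get_offer <- function(slot, row, first_offer_seen) {
    st <- states[[slot]]
    st$first_offer_seen <- first_offer_seen
    st$condition <- row$condition
    st$session_index <- row$session_index
    st$trial_index <- row$trial_index
    if (p_no_offer > 0 && runif(1) < p_no_offer) return(0L)
    off <- as.integer(strategies[[slot]](st))
    stopifnot(off >= 0L, off <= 8L)
    off
  }
  update_state <- function(slot, offer, side, acc_side) {
    if (is.na(offer) || offer < 1L) return(invisible())
    states[[slot]]$last_own_offer <<- offer
    states[[slot]]$last_own_accepted <<- identical(acc_side, side)
    invisible()
  }

  current_session <- design$session_index[1]
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    if (reset_each_session && row$session_index != current_session) {
      states <- list(P1 = new_state(), P2 = new_state())
      current_session <- row$session_index
    }
    slot_of_side <- c(left = row$left_slot, right = row$right_slot)
    if (row$condition == "dyadic") {
      side <- if (row$active_slot == row$left_slot) "left" else "right"
      off <- get_offer(row$active_slot, row, NA_integer_)
      if (side == "left") offers_l[i] <- off else offers_r[i] <- off
    } else if (row$condition == "triadic_simultaneous") {
      offers_l[i] <- get_offer(slot_of_side[["left"]], row, NA_integer_)
      offers_r[i] <- get_offer(slot_of_side[["right"]], row, NA_integer_)
    } else {
      first_side <- row$first_side
      second_side <- if (first_side == "left") "right" else "left"
      f <- get_offer(slot_of_side[[first_side]], row, NA_integer_)
      s2 <- get_offer(slot_of_side[[second_side]], row,
                      if (f >= 1L) f else NA_integer_)
      if (first_side == "left") {
        offers_l[i] <- f; offers_r[i] <- s2
      } else {
        offers_r[i] <- f; offers_l[i] <- s2
      }
    }
    acc <- responder(offers_l[i], offers_r[i])
    accepted[i] <- acc
    update_state(slot_of_side[["left"]], offers_l[i], "left", acc)
    update_state(slot_of_side[["right"]], offers_r[i], "right", acc)
  }

  skeleton$offer_left <- offers_l
  skeleton$offer_right <- offers_r
  skeleton$accepted_side <- accepted
  as_ug_trials(skeleton)
}

#' Simulate a multi-triad study
#'
#' Plays one schedule per triad, cycling design start conditions across
#' triads the way the study counterbalanced them (with 7 triads: 4 start
#' triadic, 3 start dyadic) and alternating the first consecutive-block
#' leader.
#'
#' @param n_triads Number of triads.
#' @param proposer1,proposer2,responder Strategies shared by all triads.
#' @param seed Integer seed; each triad gets a distinct derived seed.
#' @param ... Passed on to [simulate_experiment()].
#' @return Validated `ug_trials` tibble of `128 * n_triads` trials.
#' @export
simulate_study <- function(n_triads = 7, proposer1 = strategy_reluctant(),
                           proposer2 = strategy_outbidder(),
                           responder = responder_maximizer(weber_w = 0.25),
                           seed = NULL, ...) {
  starts <- rep(c("triadic", "dyadic"), length.out = n_triads)
  leaders <- rep(c("P1", "P2"), length.out = n_triads)
  purrr::map(seq_len(n_triads), function(k) {
    simulate_experiment(
      generate_design(starts[k], leaders[k]),
      proposer1, proposer2, responder,
      triad_id = sprintf("T%02d", k),
      seed = if (is.null(seed)) NULL else as.integer(seed) + 1000L * k,
      ...)
  }) %>%
    bind_rows() %>%
    as_ug_trials()
}
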