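# Baseline outbidding probabilities under an independence null.
#
# If neither proposer reacted to the other, both offers on a
# consecutive trial would be independent draws from a common
# offer-preference distribution.  That distribution is estimated from
# observed *first* offers only (second offers may already be strategic),
# down-weighting trials late in a session and late sessions, where even
# first offers are contaminated by the history of play.  The baseline
# probability of outbidding a first offer of k is then the chance that
# an independent draw exceeds k.

#' Estimate the offer-preference distribution
#'
#' Weighted empirical distribution of first offers over the categories
#' 0..8, with exponential decay in trial and session position: the
#' weight of an offer made on trial t of session s is
#' `exp(-lambda_trial (t - 1)) * exp(-lambda_session (s - 1))`.
#' Zero decay gives the plain empirical frequencies.
#'
#' @param first_offers Data frame with columns `offer` (0..8),
#'   `trial_index`, `session_index`; typically the first offers of
#'   consecutive trials.
#' @param lambda_trial,lambda_session Non-negative decay rates per trial
#'   and per session (defaults 0.2 each).
#' @return List of class `ug_pref`: `p` (named probability vector over
#'   offers 0..8), the decay parameters, and `ess` (Kish effective
#'   sample size of the weights).
#' @export
#' @examples
#' fo <- data.frame(offer = c(1, 5), trial_index = c(1, 5),
#'                  session_index = 1)
#' estimate_preference_distribution(fo, lambda_trial = log(2),
#'                                  lambda_session = 0)$p
estimate_preference_distribution <- function(first_offers,
                                             lambda_trial = 0.2,
                                             lambda_session = 0.2) {
  stopifnot(lambda_trial >= 0, lambda_session >= 0)
  if (nrow(first_offers) == 0) {
    abort("no first offers to estimate a preference distribution from")
  }
  stopifnot(all(first_offers$offer %in% 0:8))
  w <- exp(-lambda_trial * (first_offers$trial_index - 1)) *
    exp(-lambda_session * (first_offers$session_index - 1))
  p <- vapply(0:8, function(k) sum(w[first_offers$offer == k]),
              numeric(1))
  p <- p / sum(p)
  structure(list(p = setNames(p, 0:8),
                 lambda_trial = lambda_trial,
                 lambda_session = lambda_session,
                 ess = sum(w)^2 / sum(w^2)),
            class = "ug_pref")
}

#' First offers of consecutive trials
#'
#' Extracts the (offer, trial_index, session_index) records that feed
#' [estimate_preference_distribution()] from a trial table.
#'
#' @param trials `ug_trials` tibble.
#' @return Tibble with columns `offer`, `trial_index`, `session_index`.
#' @export
consecutive_first_offers <- function(trials) {
  as_ug_trials(trials) %>%
    as_tibble() %>%
    filter(.data$condition == "triadic_consecutive",
           !is.na(.data$first_side)) %>%
    mutate(offer = if_else(.data$first_side == "left",
                           .data$offer_left, .data$offer_right)) %>%
    filter(!is.na(.data$offer)) %>%
    select("offer", "trial_index", "session_index")
}

new_baseline <- function(first_offer, prob, mc_se, n, n_pairs) {
  structure(tibble(first_offer = first_offer, prob = prob,
                   mc_se = mc_se, n = n),
            n_pairs = n_pairs,
            class = c("ug_baseline", class(tibble())))
}

#' Exact baseline outbidding probabilities
#'
#' Under the independence null the probability that a second offer
#' exceeds a first offer of k is simply the upper tail of the
#' preference distribution: `B_k = sum_{j > k} p_j`.  This is the
#' production path; [simulate_baseline()] reproduces it by Monte Carlo.
#' `B_k` is non-increasing in k and `B_8 = 0` for every preference
#' vector.
#'
#' @param pref `ug_pref` from [estimate_preference_distribution()], or a
#'   bare probability vector over offers 0..8.
#' @return `ug_baseline` tibble: `first_offer` 0..8, `prob`, `mc_se`
#'   (zero: exact), `n` (NA).
#' @export
baseline_closed_form <- function(pref) {
  p <- if (inherits(pref, "ug_pref")) pref$p else pref
  stopifnot(length(p) == 9, all(p >= 0),
            abs(sum(p) - 1) < 1e-12)
  b <- rev(cumsum(rev(p)))   # upper tails including k
  b <- c(b[-1], 0)           # strictly greater than k
  new_baseline(0:8, unname(b), rep(0, 9), rep(NA_integer_, 9),
               n_pairs = NA_integer_)
}

#' Simulated baseline outbidding probabilities
#'
#' Simulates consecutive sessions (4 consecutive trials each) in which
#' both offers are drawn independently from the preference
#' distribution, then tabulates, for each possible first offer, the
#' proportion of trials where the second offer was higher.  Converges to
#' [baseline_closed_form()]; retained for Monte-Carlo error reporting
#' and as a direct implementation of the resampling procedure.
#'
#' @param pref `ug_pref` or probability vector over 0..8.
#' @param n_sessions Number of simulated sessions (4 pairs each).
#' @param seed Integer seed.
#' @return `ug_baseline` tibble with binomial `mc_se` and per-category
#'   pair counts `n`; categories never drawn as first offer have `prob`
#'   `NA` (flagged by zero `n`).
#' @export
simulate_baseline <- function(pref, n_sessions = 250000, seed = 1) {
  p <- if (inherits(pref, "ug_pref")) pref$p else pref
  stopifnot(length(p) == 9, all(p >= 0), n_sessions >= 1)
  n_pairs <- 4L * as.integer(n_sessions)
  with_seed(seed, {
    first <- sample(0:8, n_pairs, replace = TRUE, prob = p)
    second <- sample(0:8, n_pairs, replace = TRUE, prob = p)
  })
  out <- vapply(0:8, function(k) {
    idx <- first == k
    nk <- sum(idx)
    if (nk == 0) return(c(NA_real_, NA_real_, 0))
    bk <- mean(second[idx] > k)
    c(bk, sqrt(bk * (1 - bk) / nk), nk)
  }, numeric(3))
  new_baseline(0:8, out[1, ], out[2, ], as.integer(out[3, ]),
               n_pairs = n_pairs)
}

#' Estimate the baseline table from a trial dataset
#'
#' Convenience wrapper: extract consecutive first offers, estimate the
#' weighted preference distribution, and return the exact baseline
#' table.
#'
#' @param trials `ug_trials` tibble.
#' @param lambda_trial,lambda_session Decay rates (defaults 0.2).
#' @return `ug_baseline` tibble.
#' @export
baseline_from_trials <- function(trials, lambda_trial = 0.2,
                                 lambda_session = 0.2) {
  pref <- estimate_preference_distribution(
    consecutive_first_offers(trials),
    lambda_trial = lambda_trial, lambda_session = lambda_session)
  baseline_closed_form(pref)
}
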