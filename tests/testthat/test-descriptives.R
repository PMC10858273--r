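dyadic_session <- function(offers, opener = "left",
                           session_index = 1L, triad_id = "T1") {
  # 8-trial dyadic session, proposers alternating every two trials
  sides <- rep(if (opener == "left") c("left", "right") else
                 c("right", "left"), each = 2, times = 2)
  tibble::tibble(
    triad_id = triad_id, session_index = as.integer(session_index),
    trial_index = 1:8, condition = "dyadic",
    left_proposer = paste0(triad_id, "_P1"),
    right_proposer = paste0(triad_id, "_P2"),
    responder = paste0(triad_id, "_R"),
    first_side = NA_character_,
    offer_left = ifelse(sides == "left", as.integer(offers), NA),
    offer_right = ifelse(sides == "right", as.integer(offers), NA),
    accepted_side = sides)
}

test_that("mean first offers split by session condition", {
  d <- dyadic_session(c(3, 5, 1, 1, 2, 2, 1, 1))
  expect_equal(mean_first_offers(d)[["dyadic"]], 3)
  expect_true(is.nan(mean_first_offers(d)[["triadic"]]))
  # triadic first trials contribute both proposers' offers
  s <- make_session(offers_left = c(2, 1, 1, 1),
                    offers_right = c(6, 1, 1, 1),
                    accepted = c("right", "left", "left", "left"),
                    condition = "triadic_simultaneous",
                    first_side = NA_character_,
                    session_index = 2L)
  both <- dplyr::bind_rows(d, s)
  expect_equal(mean_first_offers(both)[["triadic"]], 4)
  expect_equal(mean_first_offers(both)[["dyadic"]], 3)
})

test_that("highest-offer acceptance rate counts unequal triadic trials only", {
  tr <- dplyr::bind_rows(
    make_trial(offer_left = 5L, offer_right = 1L,
               accepted_side = "left"),
    make_trial(trial_index = 2L, offer_left = 2L, offer_right = 6L,
               accepted_side = "right"),
    make_trial(trial_index = 3L, offer_left = 4L, offer_right = 4L,
               accepted_side = "left"))
  expect_equal(highest_offer_acceptance_rate(tr), 1.0)
  miss <- make_trial(offer_left = 5L, offer_right = 1L,
                     accepted_side = "right")
  expect_equal(highest_offer_acceptance_rate(miss), 0.0)
  # no unequal two-offer trials: undefined
  ties <- make_trial(offer_left = 4L, offer_right = 4L,
                     accepted_side = "left")
  expect_true(is.nan(highest_offer_acceptance_rate(ties)))
})

test_that("the error ratio averages min/max over failed discriminations", {
  one <- make_trial(offer_left = 3L, offer_right = 6L,
                    accepted_side = "left")
  expect_equal(mean_error_ratio(one), 0.5)
  two <- dplyr::bind_rows(
    make_trial(offer_left = 1L, offer_right = 2L,
               accepted_side = "left"),
    make_trial(trial_index = 2L, offer_left = 3L, offer_right = 4L,
               accepted_side = "left"))
  expect_equal(mean_error_ratio(two), (0.5 + 0.75) / 2)
  perfect <- make_trial(offer_left = 3L, offer_right = 6L,
                        accepted_side = "right")
  expect_true(is.nan(mean_error_ratio(perfect)))
})

test_that("side-choice rates condition on the first-offer side", {
  tr <- dplyr::bind_rows(
    make_session(offers_left = c(2, 2), offers_right = c(3, 1),
                 accepted = c("left", "right"), first_side = "left"),
    make_session(offers_left = c(2, 2), offers_right = c(3, 3),
                 accepted = c("right", "right"), first_side = "right",
                 session_index = 2L))
  r <- side_choice_rates(tr)
  expect_equal(r[["left_given_first_left"]], 0.5)
  expect_equal(r[["right_given_first_right"]], 1.0)
  # empty cells are flagged undefined
  r2 <- side_choice_rates(tr[tr$first_side == "left", ])
  expect_true(is.nan(r2[["right_given_first_right"]]))
})

test_that("exact responders never choose the lower offer in simulation", {
  d <- small_study(n_triads = 2, seed = 13,
                   responder = responder_maximizer(weber_w = 0))
  expect_equal(highest_offer_acceptance_rate(d), 1.0)
})

test_that("total proportional offer uses per-proposer opportunity denominators", {
  # triadic proposer offering 1 on all 8 trials: 8/64
  s <- make_session(offers_left = rep(1, 8), offers_right = rep(2, 8),
                    accepted = rep("right", 8),
                    condition = "triadic_simultaneous",
                    first_side = NA_character_)
  tpo <- total_proportional_offer(s)
  expect_equal(tpo$prop[tpo$proposer_id == "T1_P1"], 8 / 64)
  expect_equal(tpo$max_possible, c(64L, 64L))
  # dyadic proposer offering 8 on all 4 of their trials: 1.0
  d <- dyadic_session(rep(8, 8))
  tpd <- total_proportional_offer(d)
  expect_equal(tpd$prop, c(1, 1))
  expect_equal(tpd$max_possible, c(32L, 32L))
  # first-half subset: triadic denominator 32, dyadic 16
  s2 <- make_session(offers_left = c(2, 2, 2, 2, 8, 8, 8, 8),
                     offers_right = rep(1, 8),
                     accepted = rep("left", 8),
                     condition = "triadic_consecutive",
                     first_side = "left")
  tph <- total_proportional_offer(s2, subset = "first_half")
  expect_equal(tph$prop[tph$proposer_id == "T1_P1"], 8 / 32)
  expect_equal(tph$max_possible[1], 32L)
  tdh <- total_proportional_offer(d, subset = "first_half")
  expect_equal(tdh$max_possible, c(16L, 16L))
  # session-level denominator switch
  tps <- total_proportional_offer(d, denominator = "session")
  expect_equal(tps$max_possible, c(64L, 64L))
})

test_that("descriptive rates are invariant to row order and round trips", {
  d <- small_study(n_triads = 2, seed = 23)
  rep1 <- descriptive_report(d)
  shuffled <- d[sample(nrow(d)), ]
  rep2 <- descriptive_report(shuffled)
  expect_equal(rep1$mean_first_offer, rep2$mean_first_offer)
  expect_equal(rep1$highest_offer_acceptance_rate,
               rep2$highest_offer_acceptance_rate)
  expect_equal(rep1$side_choice, rep2$side_choice)
  f <- tempfile(fileext = ".csv")
  write_trials(d, f)
  rep3 <- descriptive_report(load_trials(f))
  expect_equal(rep1$mean_error_ratio, rep3$mean_error_ratio)
  expect_equal(rep1$mean_first_offer, rep3$mean_first_offer)
})

test_that("a brute-force recount agrees on a random small dataset", {
  d <- small_study(n_triads = 1, seed = 31,
                   responder = responder_maximizer(weber_w = 0.4))
  tri <- d[d$condition != "dyadic" & !is.na(d$offer_left) &
             !is.na(d$offer_right) & d$offer_left >= 1 &
             d$offer_right >= 1, ]
  uneq <- tri[tri$offer_left != tri$offer_right &
                tri$accepted_side != "none", ]
  hi <- ifelse(uneq$offer_left > uneq$offer_right, "left", "right")
  expect_equal(highest_offer_acceptance_rate(d), mean(hi == uneq$accepted_side))
  err <- uneq[hi != uneq$accepted_side, ]
  expect_equal(mean_error_ratio(d),
               mean(pmin(err$offer_left, err$offer_right) /
                      pmax(err$offer_left, err$offer_right)))
})
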