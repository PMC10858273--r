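blank_state <- function(...) {
  st <- triadug:::new_state()
  over <- list(...)
  st[names(over)] <- over
  st
}

test_that("the minimal proposer always offers 1", {
  expect_equal(propose_minimal(blank_state()), 1L)
  expect_equal(propose_minimal(blank_state(last_own_offer = 5L,
                                           last_own_accepted = FALSE)), 1L)
  expect_equal(propose_minimal(blank_state(first_offer_seen = 5L)), 1L)
})

test_that("the reluctant proposer follows its update rule", {
  # first offer of a session is the start value
  expect_equal(propose_reluctant_increase(blank_state(), start = 2L), 2L)
  # rejection: step up, capped at 8
  expect_equal(propose_reluctant_increase(
    blank_state(last_own_offer = 3L, last_own_accepted = FALSE)), 4L)
  expect_equal(propose_reluctant_increase(
    blank_state(last_own_offer = 8L, last_own_accepted = FALSE)), 8L)
  # acceptance with p_decrease = 0: always repeat
  expect_equal(propose_reluctant_increase(
    blank_state(last_own_offer = 5L, last_own_accepted = TRUE),
    p_decrease_after_accept = 0), 5L)
  # acceptance at the floor never goes below it
  set.seed(1)
  offs <- replicate(50, propose_reluctant_increase(
    blank_state(last_own_offer = 1L, last_own_accepted = TRUE),
    p_decrease_after_accept = 1))
  expect_true(all(offs == 1L))
})

test_that("after acceptance the reluctant proposer decreases at the configured rate", {
  set.seed(99)
  offs <- replicate(1000, propose_reluctant_increase(
    blank_state(last_own_offer = 4L, last_own_accepted = TRUE),
    p_decrease_after_accept = 0.5))
  expect_true(abs(mean(offs == 3L) - 0.5) < 0.05)
  expect_true(all(offs %in% c(3L, 4L)))
})

test_that("the outbidder outbids exactly while its residual share clears the threshold", {
  # sweep all first offers at threshold 4: outbid iff f <= 3
  outbids <- vapply(0:8, function(f) {
    propose_outbidder(blank_state(first_offer_seen = as.integer(f)),
                      share_threshold = 4L)
  }, integer(1))
  expect_equal(outbids[1:4], as.integer(0:3 + 1L))
  expect_equal(outbids[5:9], rep(1L, 5))  # falls back to minimal
  # no visible first offer: falls back
  expect_equal(propose_outbidder(blank_state()), 1L)
})

test_that("the maximizing responder is exact at zero discrimination noise", {
  expect_equal(respond_maximizer(5L, 1L, weber_w = 0), "left")
  expect_equal(respond_maximizer(1L, 5L, weber_w = 0), "right")
  # lone valid offer is always accepted; no valid offer means no choice
  expect_equal(respond_maximizer(3L, NA, weber_w = 0), "left")
  expect_equal(respond_maximizer(0L, 2L, weber_w = 0), "right")
  expect_equal(respond_maximizer(0L, NA, weber_w = 0), "none")
  # property: argmax on 10^4 random unequal pairs
  set.seed(11)
  for (i in 1:10000) {
    a <- sample(1:8, 1); b <- sample(setdiff(1:8, a), 1)
    expect_identical(respond_maximizer(a, b, weber_w = 0),
                     if (a > b) "left" else "right")
  }
})

test_that("equal offers are broken by the side bias", {
  set.seed(21)
  sides <- replicate(4000, respond_maximizer(4L, 4L, side_bias = 0.5))
  expect_true(abs(mean(sides == "left") - 0.5) < 0.03)
  biased <- replicate(2000, respond_maximizer(4L, 4L, side_bias = 0.9))
  expect_true(abs(mean(biased == "left") - 0.9) < 0.03)
})

test_that("discrimination errors match the closed-form rate", {
  # offers 7 vs 8: ratio 7/8, error rate 0.5 * exp(-(1/8) / w)
  w <- 0.3
  expected <- 0.5 * exp(-(1 - 7 / 8) / w)
  set.seed(31)
  picks <- replicate(10000, respond_maximizer(7L, 8L, weber_w = w))
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_true(abs(mean(picks == "left") - expected) < 4 * se)
})

test_that("the engine is reproducible and respects information structure", {
  d <- generate_design("triadic", "P1")
  a <- simulate_experiment(d, strategy_reluctant(), strategy_outbidder(),
                           responder_maximizer(weber_w = 0.2), seed = 8)
  b <- simulate_experiment(d, strategy_reluctant(), strategy_outbidder(),
                           responder_maximizer(weber_w = 0.2), seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # minimal proposers, exact responder: all triadic offers are 1
  m <- simulate_experiment(d, strategy_minimal(), strategy_minimal(),
                           responder_maximizer(), seed = 1)
  tri <- m[m$condition != "dyadic", ]
  expect_true(all(tri$offer_left == 1L & tri$offer_right == 1L))
  expect_true(all(tri$accepted_side %in% c("left", "right")))
})

test_that("an outbidder acting second always wins against a minimal first proposer", {
  d <- generate_design("triadic", "P1")
  tr <- simulate_experiment(d, strategy_minimal(),
                            strategy_outbidder(share_threshold = 4L,
                                               fallback = strategy_minimal()),
                            responder_maximizer(weber_w = 0), seed = 2)
  v <- proposer_views(tr)
  second <- v[v$acted_second & !is.na(v$first_offer_seen), ]
  # P2 outbids the minimal offer 1 with 2 and is accepted every time
  p2 <- second[grepl("P2", second$proposer_id), ]
  expect_true(all(p2$own_offer == 2L))
  expect_true(all(p2$own_accepted))
})

test_that("simulated datasets always validate, with and without timeouts", {
  for (s in 1:3) {
    d <- simulate_experiment(
      generate_design("dyadic", "P2"), strategy_reluctant(),
      strategy_reluctant(p_decrease_after_accept = 0.5),
      responder_maximizer(weber_w = 0.4), seed = s, p_no_offer = 0.1)
    expect_equal(nrow(validate_ug_trials(d)), 0L)
  }
})

test_that("reluctant agents always escalate after rejection and obey the acceptance bound", {
  st <- simulate_study(n_triads = 2, proposer1 = strategy_reluctant(),
                       proposer2 = strategy_minimal(),
                       responder = responder_maximizer(weber_w = 0.3),
                       seed = 77)
  v <- proposer_views(st)
  rel <- v[grepl("P1$", v$proposer_id) & v$condition != "dyadic" &
             !is.na(v$previous_own_offer), ]
  after_rej <- rel[!rel$previous_own_accepted, ]
  after_rej <- after_rej[after_rej$previous_own_offer < 8L, ]
  expect_true(all(after_rej$own_offer > after_rej$previous_own_offer))
  after_acc <- rel[rel$previous_own_accepted, ]
  expect_true(all(after_acc$own_offer <= after_acc$previous_own_offer))
})

test_that("strategy zoo specs resolve by name", {
  f <- resolve_strategy(list(name = "fixed", offer = 6))
  expect_equal(f(blank_state()), 6L)
  expect_equal(resolve_strategy("minimal")(blank_state()), 1L)
  expect_error(resolve_strategy("nope"), class = "ug_config_error")
  byc <- strategy_by_condition(dyadic = strategy_fixed(2),
                               triadic = strategy_fixed(7))
  expect_equal(byc(blank_state(condition = "dyadic")), 2L)
  expect_equal(byc(blank_state(condition = "triadic_consecutive")), 7L)
})
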