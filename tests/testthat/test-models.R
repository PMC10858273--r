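# Structural and qualitative checks of the model suite; calibration
# (interval coverage against each model's own generative process) lives
# in test-acceptance.R.

study <- small_study(n_triads = 2, seed = 301)

test_that("fits are reproducible given the seed", {
  a <- fit_quick(fit_outbid_simple, study, seed = 5)
  b <- fit_quick(fit_outbid_simple, study, seed = 5)
  expect_identical(a$draws$draws, b$draws$draws)
  expect_identical(a$summary$session_table, b$summary$session_table)
})

test_that("derived summaries are invariant to shifting session labels", {
  shifted <- study
  shifted$session_index <- shifted$session_index + 5L
  a <- fit_quick(fit_outbid_simple, study, seed = 3)
  b <- fit_quick(fit_outbid_simple, shifted, seed = 3)
  expect_equal(a$summary$session_table$p_mean,
               b$summary$session_table$p_mean, tolerance = 1e-10)
  expect_equal(a$summary$p_session_slope_positive,
               b$summary$p_session_slope_positive)
})

test_that("the total-offer model reports no signal when conditions are identical", {
  # same fixed strategy in both conditions: any difference is noise
  d <- small_study(n_triads = 3, seed = 311,
                   proposer1 = strategy_fixed(3),
                   proposer2 = strategy_fixed(3))
  f <- fit_quick(fit_total_offer_model, d)
  expect_true(f$summary$diff_hpd$lower < 0 & f$summary$diff_hpd$upper > 0)
  # responses pinned at one value put the predictive means together
  expect_lt(abs(f$summary$pp_mean[["dyadic"]] -
                  f$summary$pp_mean[["triadic"]]), 0.1)
})

test_that("the first-half model carries the simultaneous/consecutive contrast", {
  f <- fit_quick(fit_total_offer_model, study, subset = "first_half")
  expect_named(f$summary$pp_mean, c("simultaneous", "consecutive"))
  expect_true("bx" %in% f$draws$diagnostics$parameter)
  expect_true(is.finite(f$summary$p_mean_diff_positive))
})

test_that("the Beta model rejects responses outside the unit interval", {
  bad <- total_proportional_offer(study)
  bad$prop[1] <- 1.5
  expect_error(
    triadug:::fit_total_offer_resp(bad, FALSE, "x", 2, 100, 100, 1),
    "outside")
})

test_that("escalating agents separate the last-vs-first conditions", {
  # reluctant agents escalate under triadic rejection pressure but stay
  # flat in always-accepted dyadic games
  d <- small_study(n_triads = 3, seed = 321)
  f <- fit_quick(fit_last_vs_first_model, d)
  expect_gt(f$summary$marginal[["triadic"]],
            f$summary$marginal[["dyadic"]])
  expect_equal(nrow(f$summary$session_table), 16L)
  # marginals are probabilities with ordered HPD bounds
  for (h in f$summary$marginal_hpd) {
    expect_true(h$lower <= h$upper && h$lower >= 0 && h$upper <= 1)
  }
})

test_that("proposer-sessions with a single offer are dropped with a warning", {
  d <- dplyr::bind_rows(
    make_session(offers_left = c(2, 3, 4, 5),
                 offers_right = c(1, 1, 1, 1),
                 accepted = rep("left", 4),
                 condition = "triadic_simultaneous",
                 first_side = NA_character_),
    make_session(offers_left = c(4, NA, NA, NA),
                 offers_right = c(0, 2, 2, 2),
                 accepted = c("left", "right", "right", "right"),
                 condition = "triadic_simultaneous",
                 first_side = NA_character_, session_index = 2L))
  expect_warning(
    suppressWarnings(
      fit_last_vs_first_model(d, chains = 2, draws = 100, warmup = 100),
      classes = "ug_convergence_warning"),
    "single offer")
})

test_that("reluctant simulated agents drive increase-after-rejection", {
  f <- fit_quick(fit_increase_after_outcome_model, study)
  expect_gt(f$summary$p_rejected, 0.9)
  expect_gt(f$summary$p_rejected_gt_accepted, 0.95)
  expect_true(f$summary$hpd_rejected$lower <=
                f$summary$hpd_rejected$upper)
})

test_that("match-the-winner splits by winner identity and finds copycats", {
  # both proposers always offer (at least) the previous winning offer
  s <- make_session(offers_left = c(4, 5, 5, 5, 5, 5, 5, 5),
                    offers_right = c(5, 5, 5, 5, 5, 5, 5, 5),
                    accepted = rep("right", 8),
                    condition = "triadic_simultaneous",
                    first_side = NA_character_)
  s2 <- s; s2$session_index <- 2L
  s3 <- s; s3$session_index <- 3L
  f <- fit_quick(fit_match_winner_model, dplyr::bind_rows(s, s2, s3))
  expect_gt(f$summary$p_own_winner, 0.8)
  expect_gt(f$summary$p_other_winner, 0.8)
})

test_that("outbidder agents dominate the simple outbid model", {
  d <- simulate_experiment(
    generate_design("triadic", "P1"), strategy_minimal(),
    strategy_outbidder(fallback = strategy_minimal()),
    responder_maximizer(), triad_id = "T1", seed = 31)
  d2 <- simulate_experiment(
    generate_design("dyadic", "P2"), strategy_minimal(),
    strategy_outbidder(fallback = strategy_minimal()),
    responder_maximizer(), triad_id = "T2", seed = 32)
  f <- fit_quick(fit_outbid_simple, dplyr::bind_rows(d, d2))
  # P2 outbids minimal offers whenever second; P1 (minimal) never
  # outbids when second: marginal outbid rate is driven toward the
  # half of trials where the outbidder acts second
  obs <- triadug:::outbid_rows(as_ug_trials(dplyr::bind_rows(d, d2)))
  expect_equal(mean(obs$y), 0.5)
  expect_lt(abs(f$summary$marginal - 0.5), 0.12)
})

test_that("independent identical offer distributions put outbidding below half", {
  # both roles draw iid offers; ties count against outbidding, so the
  # outbid probability must sit below 0.5 (enumeration over the
  # realized trials gives the exact empirical rate)
  set.seed(41)
  d <- small_study(n_triads = 3, seed = 331,
                   proposer1 = function(state) sample(1:8, 1),
                   proposer2 = function(state) sample(1:8, 1))
  obs <- triadug:::outbid_rows(d)
  expect_lt(mean(obs$y), 0.5)
  f <- fit_quick(fit_outbid_simple, d)
  expect_lt(f$summary$marginal, 0.5)
})

test_that("the stratified model is monotone in the first offer for every draw", {
  f <- fit_quick(fit_outbid_stratified, study)
  m <- f$draws$draws
  zeta <- m[, paste0("zeta[", 1:8, "]")]
  expect_true(all(zeta >= 0))
  expect_true(all(abs(rowSums(zeta) - 1) < 1e-9))
  expect_true(all(m[, "b"] >= 0))
  # predicted probability non-increasing in first-offer category for
  # every posterior draw (fixed previous outcome and session)
  Z <- cbind(0, t(apply(zeta, 1, cumsum)))
  eta <- sapply(0:8, function(k) {
    m[, "a0"] + m[, "a_prev"] - m[, "b"] * Z[, k + 1]
  })
  expect_true(all(apply(eta, 1, function(r) all(diff(r) <= 1e-12))))
  # summary table flags unobserved first-offer categories
  tab <- f$summary$table
  expect_true(all(tab$extrapolated[!tab$first_offer %in%
                                     f$summary$observed_first_offers]))
})

test_that("threshold agents produce the sharp motivational drop", {
  d <- small_study(n_triads = 3, seed = 341,
                   proposer1 = strategy_outbidder(share_threshold = 4),
                   proposer2 = strategy_outbidder(share_threshold = 4),
                   responder = responder_maximizer(weber_w = 0.25))
  bl <- baseline_from_trials(d)
  f <- fit_quick(fit_outbid_stratified, d, baseline = bl)
  tab <- f$summary$table
  final <- tab[tab$session_index == max(tab$session_index) &
                 tab$previous_outcome == "rejected", ]
  low <- final$p_mean[final$first_offer <= 3]
  high <- final$p_mean[final$first_offer >= 5]
  expect_gt(min(low), max(high))
  expect_true(all(is.finite(final$p_gt_baseline)))
})

test_that("the model dispatcher reaches all six fits and rejects unknowns", {
  expect_error(fit_model(study, "not_a_model"),
               class = "ug_config_error")
  f <- fit_quick(fit_model, study, model = "increase_after_outcome")
  expect_equal(f$model, "increase_after_outcome")
})

test_that("fit artifacts serialize to draws CSV and summary JSON", {
  f <- fit_quick(fit_outbid_simple, study, seed = 2)
  dir <- tempfile()
  paths <- write_fit(f, dir)
  expect_true(all(file.exists(paths)))
  s <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
  expect_equal(s$model, "outbid_simple")
  expect_true(is.numeric(s$summary$p_session_slope_positive))
})
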