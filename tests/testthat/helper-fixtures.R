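# Fixture builders shared across test files.  All fixtures are
# generated in code; nothing is read from disk except files the tests
# themselves write.

# A single canonical trial row with overridable fields.
make_trial <- function(...) {
  row <- list(
    triad_id = "T1", session_index = 1L, trial_index = 1L,
    condition = "triadic_simultaneous",
    left_proposer = "T1_P1", right_proposer = "T1_P2",
    responder = "T1_R",
    first_side = NA_character_, offer_left = 5L, offer_right = 1L,
    accepted_side = "left")
  over <- list(...)
  row[names(over)] <- over
  tibble::as_tibble(row)
}

# Hand-built triadic session: one triad, one session, consecutive
# trials with fully specified offers and acceptances.
make_session <- function(offers_left, offers_right, accepted,
                         condition = "triadic_consecutive",
                         first_side = "left", session_index = 1L,
                         triad_id = "T1") {
  n <- length(offers_left)
  fs <- if (condition == "triadic_consecutive") first_side
        else NA_character_
  tibble::tibble(
    triad_id = triad_id, session_index = as.integer(session_index),
    trial_index = seq_len(n),
    condition = condition,
    left_proposer = paste0(triad_id, "_P1"),
    right_proposer = paste0(triad_id, "_P2"),
    responder = paste0(triad_id, "_R"),
    first_side = fs,
    offer_left = as.integer(offers_left),
    offer_right = as.integer(offers_right),
    accepted_side = accepted)
}

# Small simulated study reused by several files.
small_study <- function(n_triads = 2, seed = 101, ...) {
  simulate_study(n_triads = n_triads, seed = seed, ...)
}

# Reduced sampler settings for tests.
test_sampler <- list(chains = 2, draws = 400, warmup = 400)

fit_quick <- function(fn, ..., seed = 1) {
  suppressWarnings(fn(..., chains = test_sampler$chains,
                      draws = test_sampler$draws,
                      warmup = test_sampler$warmup, seed = seed))
}

# Exhaustive-search oracle for the shortest interval containing
# ceiling(mass * n) sorted draws; independent of hpd_interval().
hpd_oracle <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    if (x[i + m - 1L] - x[i] < best[2] - best[1]) {
      best <- c(x[i], x[i + m - 1L])
    }
  }
  best
}
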