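# Generative simulators for calibration checks: each function draws a
# dataset from one model's own probability model at study scale
# (7 triads x 16 sessions), on exactly the covariate scale the fitter
# uses (sessions standardized within the fitted data).  True parameter
# values are fixed here, once, at plausible magnitudes.

study_sessions <- function(n_triads = 7) {
  tidyr::expand_grid(triad = seq_len(n_triads), session_index = 1:16) %>%
    dplyr::mutate(tri = as.integer(session_index %% 2 == (triad %% 2)))
}

std_within <- function(s) (s - mean(s)) / stats::sd(s)

truth_total_offer <- list(
  beta0 = c(qlogis(0.30), qlogis(0.40)), beta1 = c(0.10, 0.30),
  gamma0 = c(log(12), log(12)), sigma_mu = 0.3, sigma_phi = 0.3)

sim_total_offer <- function(seed, n_triads = 7) {
  tt <- truth_total_offer
  set.seed(seed)
  grid <- study_sessions(n_triads) %>%
    tidyr::expand_grid(prop = 1:2)
  u_mu <- rnorm(n_triads, 0, tt$sigma_mu)
  u_phi <- rnorm(n_triads, 0, tt$sigma_phi)
  cond <- grid$tri + 1L
  s <- std_within(grid$session_index)
  mu <- plogis(tt$beta0[cond] + tt$beta1[cond] * s + u_mu[grid$triad])
  phi <- exp(tt$gamma0[cond] + u_phi[grid$triad])
  tibble::tibble(
    triad_id = paste0("T", grid$triad),
    proposer_id = paste0("T", grid$triad, "_P", grid$prop),
    session_index = grid$session_index,
    condition = ifelse(grid$tri == 1L, "triadic", "dyadic"),
    prop = rbeta(nrow(grid), mu * phi, (1 - mu) * phi))
}

truth_last_first <- list(a0 = qlogis(0.35), a_cond = 0.9,
                         a_s = 0.15, a_cs = 0.15, sigma_u = 0.5)

sim_last_first <- function(seed, n_triads = 7) {
  tt <- truth_last_first
  set.seed(seed)
  grid <- study_sessions(n_triads) %>%
    tidyr::expand_grid(prop = 1:2) %>%
    dplyr::mutate(proposer_id = paste0("T", triad, "_P", prop))
  u <- rnorm(dplyr::n_distinct(grid$proposer_id), 0, tt$sigma_u)
  pid <- as.integer(factor(grid$proposer_id))
  s <- std_within(grid$session_index)
  p <- plogis(tt$a0 + tt$a_cond * grid$tri +
                (tt$a_s + tt$a_cs * grid$tri) * s + u[pid])
  tibble::tibble(y = rbinom(nrow(grid), 1, p), tri = grid$tri,
                 session_index = grid$session_index,
                 proposer_id = grid$proposer_id)
}

# shared generative form for the two previous-outcome models
sim_prev_outcome <- function(seed, truth, n_triads = 7) {
  set.seed(seed)
  grid <- study_sessions(n_triads) %>%
    dplyr::filter(tri == 1L) %>%
    tidyr::expand_grid(prop = 1:2, trial = 2:8) %>%
    dplyr::mutate(proposer_id = paste0("T", triad, "_P", prop),
                  prev = rbinom(dplyr::n(), 1, 0.5))
  u <- rnorm(dplyr::n_distinct(grid$proposer_id), 0, truth$sigma_u)
  pid <- as.integer(factor(grid$proposer_id))
  s <- std_within(grid$session_index)
  p <- plogis(truth$a0 + truth$a_prev * grid$prev +
                (truth$a_s + truth$a_ps * grid$prev) * s + u[pid])
  tibble::tibble(y = rbinom(nrow(grid), 1, p), prev = grid$prev,
                 session_index = grid$session_index,
                 proposer_id = grid$proposer_id,
                 triad_id = paste0("T", grid$triad))
}

truth_increase <- list(a0 = qlogis(0.29), a_prev = 0.95,
                       a_s = 0.10, a_ps = 0.10, sigma_u = 0.5)
truth_match <- list(a0 = qlogis(0.36), a_prev = 0.40,
                    a_s = -0.10, a_ps = 0.15, sigma_u = 0.5)

truth_outbid_simple <- list(a0 = -0.3, a_s = 0.25, sigma_u = 0.5)

sim_outbid_simple <- function(seed, n_triads = 7) {
  tt <- truth_outbid_simple
  set.seed(seed)
  grid <- study_sessions(n_triads) %>%
    dplyr::filter(tri == 1L) %>%
    tidyr::expand_grid(trial = 1:4) %>%
    dplyr::mutate(prop = ifelse(trial %% 2 == 0, 1L, 2L),
                  proposer_id = paste0("T", triad, "_P", prop))
  u <- rnorm(dplyr::n_distinct(grid$proposer_id), 0, tt$sigma_u)
  pid <- as.integer(factor(grid$proposer_id))
  s <- std_within(grid$session_index)
  p <- plogis(tt$a0 + tt$a_s * s + u[pid])
  tibble::tibble(y = rbinom(nrow(grid), 1, p),
                 session_index = grid$session_index,
                 proposer_id = grid$proposer_id)
}

truth_outbid_strat <- list(
  a0 = 1.2, a_prev = 0.8, a_s = 0.2, a_ps = 0.2, b = 3,
  zeta = c(0.05, 0.10, 0.15, 0.20, 0.20, 0.15, 0.10, 0.05),
  sigma_u = 0.5,
  pref = c(0.02, 0.30, 0.22, 0.16, 0.12, 0.08, 0.05, 0.03, 0.02))

sim_outbid_strat <- function(seed, n_triads = 7) {
  tt <- truth_outbid_strat
  set.seed(seed)
  grid <- study_sessions(n_triads) %>%
    dplyr::filter(tri == 1L) %>%
    tidyr::expand_grid(trial = 2:4) %>%
    dplyr::mutate(prop = ifelse(trial %% 2 == 0, 1L, 2L),
                  proposer_id = paste0("T", triad, "_P", prop),
                  responder = paste0("T", triad, "_R"),
                  prev = rbinom(dplyr::n(), 1, 0.5),
                  first_offer_seen = sample(0:8, dplyr::n(),
                                            replace = TRUE,
                                            prob = tt$pref))
  u <- rnorm(dplyr::n_distinct(grid$proposer_id), 0, tt$sigma_u)
  pid <- as.integer(factor(paste(grid$proposer_id, grid$responder)))
  s <- std_within(grid$session_index)
  Z <- c(0, cumsum(tt$zeta))
  p <- plogis(tt$a0 + tt$a_prev * grid$prev +
                (tt$a_s + tt$a_ps * grid$prev) * s -
                tt$b * Z[grid$first_offer_seen + 1] + u[pid])
  grid %>%
    dplyr::transmute(y = rbinom(dplyr::n(), 1, p), prev,
                     session_index, first_offer_seen, proposer_id,
                     responder)
}

# True stratified outbid probability at prev = 1 and standardized
# session 0 for each first-offer category (population level, u = 0).
true_strat_curve <- function() {
  tt <- truth_outbid_strat
  Z <- c(0, cumsum(tt$zeta))
  plogis(tt$a0 + tt$a_prev - tt$b * Z)
}

# One replicate of a coverage check: fit, then test whether each true
# fixed effect lies inside its 95% HPD interval.
covered <- function(fit, truths) {
  vapply(names(truths), function(nm) {
    h <- hpd_interval(posterior_vector(fit, nm), 0.95)
    truths[[nm]] >= h$lower && truths[[nm]] <= h$upper
  }, logical(1))
}

recovery_sampler <- list(chains = 2, draws = 400, warmup = 400)

quick_core <- function(fn, ..., seed) {
  suppressWarnings(fn(..., chains = recovery_sampler$chains,
                      draws = recovery_sampler$draws,
                      warmup = recovery_sampler$warmup, seed = seed))
}
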