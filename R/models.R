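# The full model suite.
#
# Six hierarchical Bayesian models, all sampled through
# sample_posterior():
#   1. Beta regression of the total proportional offer per
#      proposer-session, mean and precision varying by condition, mean
#      shifting linearly with session, triad random effects on both
#      parameters (full data: dyadic vs triadic; first-half data: plus a
#      simultaneous/consecutive contrast).
#   2. Bernoulli model of "final offer of a session higher than the
#      first" with session x game-type interaction.
#   3. Bernoulli model of "offer higher than own previous offer" with
#      previous-outcome x session interaction.
#   4. As 3 but "offer matches or exceeds the previously accepted
#      (winning) offer", split by whether that winner was the
#      proposer's own offer.
#   5. Bernoulli model of the second proposer outbidding the first on
#      consecutive trials, session effect only.
#   6. As 5, stratified by the first offer through a monotonic ordinal
#      effect (non-negative magnitude times a simplex over offer
#      increments), plus previous-outcome x session effects.
#
# Priors (logged in every fit): Normal(0, 2.5) on fixed effects on the
# logit/log scale, half-Normal(1) on random-effect scales, half-Normal(2)
# on the monotonic magnitude, flat Dirichlet on the simplex.

PRIOR_NOTE <- paste(
  "fixed effects ~ Normal(0, 2.5) on link scale;",
  "random-effect scales ~ half-Normal(1);",
  "monotonic magnitude b ~ half-Normal(2); zeta ~ Dirichlet(1,...,1)")

new_ug_fit <- function(model, draws, data, summary, sampler) {
  structure(list(model = model, draws = draws, data = data,
                 summary = summary, sampler = sampler,
                 priors = PRIOR_NOTE),
            class = "ug_fit")
}

#' @export
print.ug_fit <- function(x, ...) {
  cat(sprintf("ug_fit: %s (%d rows, %d chains x %d draws, seed %d)\n",
              x$model, nrow(x$data), x$draws$chains, x$draws$n_draws,
              x$sampler$seed))
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    if (is.numeric(v) && length(v) <= 4) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(signif(v, 3), collapse = ", ")))
    }
  }
  invisible(x)
}

sampler_config <- function(chains, draws, warmup, seed) {
  list(chains = chains, draws = draws, warmup = warmup,
       seed = as.integer(seed))
}

re_block <- function(n_groups_sym, u = "u", sigma = "sigma_u") {
  sprintf("
  for (g in 1:%s) { %s[g] ~ dnorm(0, tau_%s) }
  %s ~ dnorm(0, 1) T(0,)
  tau_%s <- 1 / (%s * %s)
", n_groups_sym, u, u, sigma, u, sigma, sigma)
}

# ---------------------------------------------------------------------------
# Model 1: total proportional offer (Beta, modelled precision)

total_offer_jags <- function(with_contrast) {
  paste0("
model {
  for (i in 1:N) {
    logit(mu[i]) <- beta0[cond[i]] + beta1[cond[i]] * s[i]",
    if (with_contrast) " + bx * x[i]" else "", " + u_mu[triad[i]]
    log(phi[i]) <- gamma0[cond[i]] + u_phi[triad[i]]
    y[i] ~ dbeta(mu[i] * phi[i], (1 - mu[i]) * phi[i])
  }
  for (c in 1:2) {
    beta0[c] ~ dnorm(0, 0.16)
    beta1[c] ~ dnorm(0, 0.16)
    gamma0[c] ~ dnorm(0, 0.16) T(-8, 8)
  }",
    if (with_contrast) "\n  bx ~ dnorm(0, 0.16)" else "", "
  for (t in 1:Tn) {
    u_mu[t] ~ dnorm(0, tau_mu)
    u_phi[t] ~ dnorm(0, tau_phi) T(-8, 8)
  }
  sigma_mu ~ dnorm(0, 1) T(0,)
  sigma_phi ~ dnorm(0, 1) T(0,)
  tau_mu <- 1 / (sigma_mu * sigma_mu)
  tau_phi <- 1 / (sigma_phi * sigma_phi)
}
")
}

#' Fit the total-proportional-offer Beta model
#'
#' Models each proposer-session's total proportional offer (grapes sent
#' over the session divided by the maximum possible, see
#' [total_proportional_offer()]) with a Beta likelihood whose mean and
#' precision both differ between dyadic and triadic sessions and vary
#' randomly across triads, and whose mean shifts linearly with
#' (standardized) session number with a separate slope per condition.
#' With `subset = "first_half"` only trials 1-4 enter the response and a
#' contrast covariate (0 dyadic, -0.5 simultaneous, +0.5 consecutive)
#' captures the simultaneous/consecutive difference within triadic
#' sessions.
#'
#' Responses are compressed into (0, 1) via `(y (n - 1) + 0.5) / n`
#' before fitting.  The returned summary holds posterior-predictive
#' means and 95% HPD intervals per condition (new triad, session drawn
#' uniformly from those observed) and the HPD of the between-condition
#' predictive difference.
#'
#' @param trials `ug_trials` tibble.
#' @param subset `"full"` or `"first_half"`.
#' @param denominator Passed to [total_proportional_offer()].
#' @param chains,draws,warmup,seed Sampler settings (see
#'   [sample_posterior()]).
#' @return `ug_fit` with summary elements `pp_mean` (named per
#'   condition), `pp_hpd`, `diff_hpd` (triadic - dyadic, or consecutive -
#'   simultaneous for the first-half model), `p_mean_diff_positive`, and
#'   the session-slope draws summary.
#' @export
fit_total_offer_model <- function(trials, subset = c("full", "first_half"),
                                  denominator = "proposer",
                                  chains = 4, draws = 1000,
                                  warmup = 1000, seed = 1) {
  subset <- match.arg(subset)
  resp <- total_proportional_offer(trials, subset = subset,
                                   denominator = denominator)
  if (length(unique(resp$triad_id)) < 2) {
    warn("fewer than 2 triads: triad random-effect scales are weakly identified")
  }
  fit_total_offer_resp(resp, with_contrast = subset == "first_half",
                       model_name = paste0("total_offer_", subset),
                       chains = chains, draws = draws, warmup = warmup,
                       seed = seed)
}

# Core fitter over a prepared response table (one row per
# proposer-session with columns triad_id, session_index, condition,
# prop); used directly by simulation-based calibration checks.
fit_total_offer_resp <- function(resp, with_contrast, model_name,
                                 chains, draws, warmup, seed) {
  resp <- resp %>%
    mutate(
      cond2 = if_else(.data$condition == "dyadic", 1L, 2L),
      x = dplyr::case_when(
        .data$condition == "dyadic" ~ 0,
        .data$condition == "triadic_simultaneous" ~ -0.5,
        .data$condition == "triadic_consecutive" ~ 0.5,
        TRUE ~ 0))
  if (any(resp$prop < 0 | resp$prop > 1)) {
    abort("total proportional offers outside [0, 1]")
  }
  ss <- std_session(resp$session_index)
  y <- compress_unit(resp$prop, nrow(resp))
  triad <- as.integer(factor(resp$triad_id))

  data <- list(N = nrow(resp), y = y, cond = resp$cond2, s = ss$x,
               triad = triad, Tn = max(triad))
  if (with_contrast) data$x <- resp$x
  params <- c("beta0", "beta1", "gamma0", "sigma_mu", "sigma_phi",
              if (with_contrast) "bx")
  pd <- sample_posterior(total_offer_jags(with_contrast), data, params,
                         chains = chains, draws = draws, warmup = warmup,
                         seed = seed)
  m <- pd$draws
  nd <- nrow(m)

  predictive <- function(cond_idx, x_val = 0) {
    with_seed(derive_seed(seed, 17 + cond_idx + round(10 * x_val)), {
      s_std <- sample(ss$grid_std, nd, replace = TRUE)
      u_mu <- rnorm(nd, 0, m[, "sigma_mu"])
      u_phi <- rnorm(nd, 0, m[, "sigma_phi"])
      eta <- m[, paste0("beta0[", cond_idx, "]")] +
        m[, paste0("beta1[", cond_idx, "]")] * s_std + u_mu
      if (with_contrast) eta <- eta + m[, "bx"] * x_val
      mu <- plogis(eta)
      phi <- exp(m[, paste0("gamma0[", cond_idx, "]")] + u_phi)
      list(y = rbeta(nd, mu * phi, (1 - mu) * phi), mu = mu)
    })
  }

  if (!with_contrast) {
    p_dy <- predictive(1); p_tri <- predictive(2)
    summary <- list(
      pp_mean = c(dyadic = mean(p_dy$y), triadic = mean(p_tri$y)),
      pp_hpd = list(dyadic = hpd_interval(p_dy$y),
                    triadic = hpd_interval(p_tri$y)),
      diff_hpd = hpd_interval(p_tri$y - p_dy$y),
      p_mean_diff_positive = prob_direction(p_tri$mu - p_dy$mu),
      slope = c(dyadic = mean(m[, "beta1[1]"]),
                triadic = mean(m[, "beta1[2]"])))
  } else {
    p_sim <- predictive(2, -0.5); p_con <- predictive(2, 0.5)
    summary <- list(
      pp_mean = c(simultaneous = mean(p_sim$y),
                  consecutive = mean(p_con$y)),
      pp_hpd = list(simultaneous = hpd_interval(p_sim$y),
                    consecutive = hpd_interval(p_con$y)),
      diff_hpd = hpd_interval(p_con$y - p_sim$y),
      p_mean_diff_positive = prob_direction(p_con$mu - p_sim$mu),
      contrast_mean = mean(m[, "bx"]))
  }
  new_ug_fit(model_name, pd, resp, summary,
             sampler_config(chains, draws, warmup, seed))
}

# ---------------------------------------------------------------------------
# Model 2: last offer of a session higher than the first

last_first_jags <- paste0("
model {
  for (i in 1:N) {
    logit(p[i]) <- a0 + a_cond * tri[i] + (a_s + a_cs * tri[i]) * s[i] +
      u[prop[i]]
    y[i] ~ dbern(p[i])
  }
  a0 ~ dnorm(0, 0.16)
  a_cond ~ dnorm(0, 0.16)
  a_s ~ dnorm(0, 0.16)
  a_cs ~ dnorm(0, 0.16)
", re_block("P"), "}
")

#' Fit the last-vs-first offer escalation model
#'
#' For every proposer-session with at least two sent offers, models
#' whether the proposer's final offer exceeded their first offer of that
#' session (Bernoulli), with interacting fixed effects of standardized
#' session number and game type (dyadic vs triadic) and random
#' intercepts of proposer.
#'
#' @inheritParams fit_total_offer_model
#' @return `ug_fit`; summary holds `marginal` (session-averaged
#'   probability per condition with HPDs), `session_table` (per-session
#'   posterior mean and HPD of the triadic - dyadic difference plus
#'   per-condition means), `n_sessions_diff_excl_zero`, and first/last
#'   session probabilities per condition.
#' @export
fit_last_vs_first_model <- function(trials, chains = 4, draws = 1000,
                                    warmup = 1000, seed = 1) {
  views <- proposer_views(trials)
  ps <- views %>%
    group_by(.data$triad_id, .data$proposer_id, .data$session_index) %>%
    summarise(
      first_offer = first(.data$own_offer),
      last_offer = last(.data$own_offer),
      n_offers = dplyr::n(),
      condition = session_condition(first(.data$condition)),
      .groups = "drop")
  dropped <- sum(ps$n_offers < 2)
  if (dropped > 0) {
    warn(sprintf("dropping %d proposer-session(s) with a single offer",
                 dropped))
    ps <- filter(ps, .data$n_offers >= 2)
  }
  ps <- mutate(ps, y = as.integer(.data$last_offer > .data$first_offer),
               tri = as.integer(.data$condition == "triadic"))
  fit_last_first_rows(ps, chains = chains, draws = draws,
                      warmup = warmup, seed = seed)
}

# Core fitter over prepared proposer-session rows (columns y, tri,
# session_index, proposer_id).
fit_last_first_rows <- function(ps, chains, draws, warmup, seed) {
  ss <- std_session(ps$session_index)
  prop <- as.integer(factor(ps$proposer_id))
  pd <- sample_posterior(
    last_first_jags,
    list(N = nrow(ps), y = ps$y, tri = ps$tri, s = ss$x, prop = prop,
         P = max(prop)),
    c("a0", "a_cond", "a_s", "a_cs", "sigma_u"),
    chains = chains, draws = draws, warmup = warmup, seed = seed)
  m <- pd$draws

  p_dy <- sapply(ss$grid_std, function(s) {
    plogis(m[, "a0"] + m[, "a_s"] * s)
  })
  p_tri <- sapply(ss$grid_std, function(s) {
    plogis(m[, "a0"] + m[, "a_cond"] + (m[, "a_s"] + m[, "a_cs"]) * s)
  })
  diff <- p_tri - p_dy
  session_table <- tibble(
    session_index = ss$grid,
    p_dyadic = colMeans(p_dy),
    p_triadic = colMeans(p_tri),
    diff_mean = colMeans(diff),
    diff_lower = apply(diff, 2, function(d) hpd_interval(d)$lower),
    diff_upper = apply(diff, 2, function(d) hpd_interval(d)$upper))
  marg_dy <- rowMeans(p_dy)
  marg_tri <- rowMeans(p_tri)
  summary <- list(
    marginal = c(dyadic = mean(marg_dy), triadic = mean(marg_tri)),
    marginal_hpd = list(dyadic = hpd_interval(marg_dy),
                        triadic = hpd_interval(marg_tri)),
    session_table = session_table,
    n_sessions_diff_excl_zero = sum(session_table$diff_lower > 0 |
                                      session_table$diff_upper < 0),
    first_last_session = c(
      dyadic_first = session_table$p_dyadic[1],
      dyadic_last = session_table$p_dyadic[nrow(session_table)],
      triadic_first = session_table$p_triadic[1],
      triadic_last = session_table$p_triadic[nrow(session_table)]))
  new_ug_fit("last_vs_first", pd, ps, summary,
             sampler_config(chains, draws, warmup, seed))
}

# ---------------------------------------------------------------------------
# Models 3-4: trial-level escalation after acceptance vs rejection

prev_outcome_jags <- paste0("
model {
  for (i in 1:N) {
    logit(p[i]) <- a0 + a_prev * prev[i] + (a_s + a_ps * prev[i]) * s[i] +
      u[grp[i]]
    y[i] ~ dbern(p[i])
  }
  a0 ~ dnorm(0, 0.16)
  a_prev ~ dnorm(0, 0.16)
  a_s ~ dnorm(0, 0.16)
  a_ps ~ dnorm(0, 0.16)
", re_block("G"), "}
")

# label1 names the prev = 1 stratum, label0 the prev = 0 stratum.
fit_prev_outcome <- function(rows, model_name, label1, label0, chains,
                             draws, warmup, seed,
                             random = c("proposer", "pair")) {
  random <- match.arg(random)
  if (nrow(rows) == 0) abort("no qualifying trials")
  grp <- if (random == "proposer") {
    as.integer(factor(rows$proposer_id))
  } else {
    as.integer(factor(paste(rows$proposer_id, rows$triad_id)))
  }
  ss <- std_session(rows$session_index)
  pd <- sample_posterior(
    prev_outcome_jags,
    list(N = nrow(rows), y = rows$y, prev = rows$prev, s = ss$x,
         grp = grp, G = max(grp)),
    c("a0", "a_prev", "a_s", "a_ps", "sigma_u"),
    chains = chains, draws = draws, warmup = warmup, seed = seed)
  m <- pd$draws
  p_at <- function(prev) {
    sapply(ss$grid_std, function(s) {
      plogis(m[, "a0"] + m[, "a_prev"] * prev +
               (m[, "a_s"] + m[, "a_ps"] * prev) * s)
    })
  }
  p0 <- p_at(0); p1 <- p_at(1)
  marg0 <- rowMeans(p0)
  marg1 <- rowMeans(p1)
  session_table <- tibble(session_index = ss$grid)
  session_table[[paste0("p_", label1)]] <- colMeans(p1)
  session_table[[paste0("p_", label0)]] <- colMeans(p0)
  summary <- setNames(
    list(mean(marg1), mean(marg0), hpd_interval(marg1),
         hpd_interval(marg0), prob_direction(marg1 - marg0),
         session_table),
    c(paste0("p_", label1), paste0("p_", label0),
      paste0("hpd_", label1), paste0("hpd_", label0),
      paste0("p_", label1, "_gt_", label0),
      "session_table"))
  new_ug_fit(model_name, pd, rows, summary,
             sampler_config(chains, draws, warmup, seed))
}

#' Fit the increase-after-outcome model
#'
#' For every triadic trial with a same-session predecessor by the same
#' proposer, models whether the proposer offered *more* than their own
#' previous offer, as a function of whether that previous offer was
#' accepted or rejected, interacting with standardized session number,
#' with random intercepts of proposer (or proposer-within-triad pairs).
#'
#' @inheritParams fit_total_offer_model
#' @param random `"proposer"` (default) or `"pair"` (proposer x triad).
#' @return `ug_fit`; summary holds `p_accepted`, `p_rejected` (marginal
#'   over sessions), their HPDs, `p_rejected_gt_accepted`, and a
#'   per-session table.
#' @export
fit_increase_after_outcome_model <- function(trials, chains = 4,
                                             draws = 1000, warmup = 1000,
                                             seed = 1,
                                             random = "proposer") {
  rows <- proposer_views(trials) %>%
    filter(.data$condition != "dyadic",
           !is.na(.data$previous_own_offer)) %>%
    mutate(y = as.integer(.data$own_offer > .data$previous_own_offer),
           prev = as.integer(!.data$previous_own_accepted))
  # prev = 1 codes "previous offer rejected"
  fit_prev_outcome(rows, "increase_after_outcome",
                   label1 = "rejected", label0 = "accepted",
                   chains = chains, draws = draws, warmup = warmup,
                   seed = seed, random = random)
}

#' Fit the match-the-winner model
#'
#' For every triadic trial whose immediately preceding trial in the
#' session ended with an accepted offer, models whether the proposer
#' matched or exceeded that winning offer, split by whether the winner
#' was the proposer's own previous offer, interacting with session.
#'
#' @inheritParams fit_increase_after_outcome_model
#' @return `ug_fit`; summary holds `p_own_winner`, `p_other_winner`,
#'   HPDs, `p_own_winner_gt_other_winner`, and a per-session table.
#' @export
fit_match_winner_model <- function(trials, chains = 4, draws = 1000,
                                   warmup = 1000, seed = 1,
                                   random = "proposer") {
  rows <- proposer_views(trials) %>%
    filter(.data$condition != "dyadic",
           !is.na(.data$previous_winning_offer)) %>%
    mutate(y = as.integer(.data$own_offer >=
                            .data$previous_winning_offer),
           prev = as.integer(.data$previous_winner_own))
  # prev = 1 codes "previous winning offer was the proposer's own"
  fit_prev_outcome(rows, "match_winner",
                   label1 = "own_winner", label0 = "other_winner",
                   chains = chains, draws = draws, warmup = warmup,
                   seed = seed, random = random)
}

# ---------------------------------------------------------------------------
# Model 5: simple outbidding

outbid_simple_jags <- paste0("
model {
  for (i in 1:N) {
    logit(p[i]) <- a0 + a_s * s[i] + u[prop[i]]
    y[i] ~ dbern(p[i])
  }
  a0 ~ dnorm(0, 0.16)
  a_s ~ dnorm(0, 0.16)
", re_block("P"), "}
")

outbid_rows <- function(trials, require_prev = FALSE) {
  rows <- proposer_views(trials) %>%
    filter(.data$acted_second, !is.na(.data$first_offer_seen)) %>%
    mutate(y = as.integer(.data$own_offer > .data$first_offer_seen))
  if (require_prev) {
    rows <- rows %>%
      filter(!is.na(.data$previous_own_accepted)) %>%
      mutate(prev = as.integer(!.data$previous_own_accepted))
  }
  rows
}

#' Fit the simple outbidding model
#'
#' On consecutive triadic trials, models whether the second proposer
#' strictly outbid the visible first offer, with a fixed effect of
#' standardized session number and random intercepts of the second
#' proposer.
#'
#' @inheritParams fit_total_offer_model
#' @return `ug_fit`; summary holds `p_session_slope_positive`, a
#'   per-session table of outbid probability with HPD, and the
#'   final-session probability and HPD.
#' @export
fit_outbid_simple <- function(trials, chains = 4, draws = 1000,
                              warmup = 1000, seed = 1) {
  rows <- outbid_rows(trials)
  if (nrow(rows) == 0) abort("no consecutive trials with both offers")
  fit_outbid_simple_rows(rows, chains = chains, draws = draws,
                         warmup = warmup, seed = seed)
}

# Core fitter over prepared consecutive-trial rows (columns y,
# session_index, proposer_id).
fit_outbid_simple_rows <- function(rows, chains, draws, warmup, seed) {
  ss <- std_session(rows$session_index)
  prop <- as.integer(factor(rows$proposer_id))
  pd <- sample_posterior(
    outbid_simple_jags,
    list(N = nrow(rows), y = rows$y, s = ss$x, prop = prop,
         P = max(prop)),
    c("a0", "a_s", "sigma_u"),
    chains = chains, draws = draws, warmup = warmup, seed = seed)
  m <- pd$draws
  p <- sapply(ss$grid_std, function(s) plogis(m[, "a0"] + m[, "a_s"] * s))
  session_table <- tibble(
    session_index = ss$grid,
    p_mean = colMeans(p),
    p_lower = apply(p, 2, function(d) hpd_interval(d)$lower),
    p_upper = apply(p, 2, function(d) hpd_interval(d)$upper))
  last_row <- session_table[nrow(session_table), ]
  summary <- list(
    p_session_slope_positive = prob_direction(m[, "a_s"]),
    session_table = session_table,
    final_session = c(mean = last_row$p_mean, lower = last_row$p_lower,
                      upper = last_row$p_upper),
    marginal = mean(p))
  new_ug_fit("outbid_simple", pd, rows, summary,
             sampler_config(chains, draws, warmup, seed))
}

# ---------------------------------------------------------------------------
# Model 6: outbidding stratified by the first offer (monotonic ordinal)

outbid_strat_jags <- paste0("
model {
  for (i in 1:N) {
    logit(p[i]) <- a0 + a_prev * prev[i] +
      (a_s + a_ps * prev[i]) * s[i] - b * Z[K[i] + 1] + u[grp[i]]
    y[i] ~ dbern(p[i])
  }
  Z[1] <- 0
  for (k in 1:8) { Z[k + 1] <- Z[k] + zeta[k] }
  zeta[1:8] ~ ddirch(alpha[])
  b ~ dnorm(0, 0.25) T(0,)
  a0 ~ dnorm(0, 0.16)
  a_prev ~ dnorm(0, 0.16)
  a_s ~ dnorm(0, 0.16)
  a_ps ~ dnorm(0, 0.16)
", re_block("G"), "}
")

#' Fit the stratified outbidding model
#'
#' Extends [fit_outbid_simple()] in two ways, on consecutive trials where
#' the second proposer also has a previous-trial outcome (the first
#' trial of each session is discarded): the value of the first offer
#' enters as a *monotonic ordinal* effect — a non-negative magnitude `b`
#' times the cumulative sum of a simplex `zeta` over offer increments
#' 0..8, so the outbid probability is constrained to be non-increasing
#' in the first offer while the per-step drops are free — and the
#' outcome of the second proposer's previous offer (accepted vs
#' rejected) enters interacting with session.  Random intercepts are on
#' second-proposer-by-responder pairs by default, since outbidding
#' varies with both identities.
#'
#' @inheritParams fit_increase_after_outcome_model
#' @param baseline Optional `ug_baseline` table (see
#'   [baseline_closed_form()]); when supplied, the summary reports
#'   exceedance probabilities of each outbid probability over the
#'   baseline as well as over chance (0.5).
#' @param random `"pair"` (default: second proposer x responder) or
#'   `"proposer"`.
#' @return `ug_fit`; summary holds `table` (one row per first offer 0-8
#'   x previous outcome x session: posterior mean, HPD, P(> 0.5),
#'   P(> baseline), extrapolation flag), `p_slope_positive_rejected`,
#'   `p_slope_positive_accepted`.
#' @export
fit_outbid_stratified <- function(trials, baseline = NULL, chains = 4,
                                  draws = 1000, warmup = 1000, seed = 1,
                                  random = c("pair", "proposer")) {
  random <- match.arg(random)
  rows <- outbid_rows(trials, require_prev = TRUE)
  if (nrow(rows) == 0) abort("no qualifying consecutive trials")
  roster <- as_ug_trials(trials) %>%
    as_tibble() %>%
    distinct(.data$triad_id, .data$responder)
  rows <- left_join(rows, roster, by = "triad_id")
  fit_outbid_strat_rows(rows, baseline = baseline, chains = chains,
                        draws = draws, warmup = warmup, seed = seed,
                        random = random)
}

# Core fitter over prepared rows (columns y, prev, session_index,
# first_offer_seen, proposer_id, responder).
fit_outbid_strat_rows <- function(rows, baseline, chains, draws, warmup,
                                  seed, random = "pair") {
  grp <- if (random == "pair") {
    as.integer(factor(paste(rows$proposer_id, rows$responder)))
  } else {
    as.integer(factor(rows$proposer_id))
  }
  ss <- std_session(rows$session_index)
  pd <- sample_posterior(
    outbid_strat_jags,
    list(N = nrow(rows), y = rows$y, prev = rows$prev, s = ss$x,
         K = rows$first_offer_seen, grp = grp, G = max(grp),
         alpha = rep(1, 8)),
    c("a0", "a_prev", "a_s", "a_ps", "b", "zeta", "sigma_u"),
    chains = chains, draws = draws, warmup = warmup, seed = seed)
  m <- pd$draws
  zeta <- m[, paste0("zeta[", 1:8, "]")]
  Z <- cbind(0, t(apply(zeta, 1, cumsum)))  # draws x 9, offers 0..8
  observed_k <- sort(unique(rows$first_offer_seen))

  outbid_p_draws <- function(k, prev, s_std) {
    plogis(m[, "a0"] + m[, "a_prev"] * prev +
             (m[, "a_s"] + m[, "a_ps"] * prev) * s_std -
             m[, "b"] * Z[, k + 1])
  }
  grid <- tidyr::expand_grid(first_offer = 0:8, prev = c(0L, 1L),
                             session_index = ss$grid)
  grid_std <- (grid$session_index - ss$center) / ss$scale
  tab <- purrr::pmap(
    list(grid$first_offer, grid$prev, grid_std),
    function(k, prev, s) {
      pdraws <- outbid_p_draws(k, prev, s)
      h <- hpd_interval(pdraws)
      base <- if (!is.null(baseline)) {
        baseline$prob[baseline$first_offer == k]
      } else NA_real_
      tibble(p_mean = mean(pdraws), p_lower = h$lower,
             p_upper = h$upper,
             p_gt_chance = prob_direction(pdraws, 0.5),
             p_gt_baseline = if (length(base) == 1 && !is.na(base)) {
               prob_direction(pdraws, base)
             } else NA_real_)
    }) %>% bind_rows()
  tab <- bind_cols(grid, tab) %>%
    mutate(previous_outcome = if_else(.data$prev == 1L, "rejected",
                                      "accepted"),
           extrapolated = !.data$first_offer %in% observed_k) %>%
    select("first_offer", "previous_outcome", "session_index",
           "p_mean", "p_lower", "p_upper", "p_gt_chance",
           "p_gt_baseline", "extrapolated")
  summary <- list(
    table = tab,
    p_slope_positive_rejected = prob_direction(m[, "a_s"] + m[, "a_ps"]),
    p_slope_positive_accepted = prob_direction(m[, "a_s"]),
    b_mean = mean(m[, "b"]),
    observed_first_offers = observed_k)
  new_ug_fit("outbid_stratified", pd, rows, summary,
             sampler_config(chains, draws, warmup, seed))
}

# ---------------------------------------------------------------------------

#' Fit a model by name
#'
#' Dispatcher over the six model operations, used by the command-line
#' pipeline.
#'
#' @param trials `ug_trials` tibble.
#' @param model One of `"total_offer"`, `"total_offer_half"`,
#'   `"last_vs_first"`, `"increase_after_outcome"`, `"match_winner"`,
#'   `"outbid_simple"`, `"outbid_stratified"`.
#' @param ... Passed to the model function.
#' @return `ug_fit`.
#' @export
fit_model <- function(trials, model, ...) {
  switch(model,
    total_offer = fit_total_offer_model(trials, subset = "full", ...),
    total_offer_half = fit_total_offer_model(trials,
                                             subset = "first_half", ...),
    last_vs_first = fit_last_vs_first_model(trials, ...),
    increase_after_outcome =
      fit_increase_after_outcome_model(trials, ...),
    match_winner = fit_match_winner_model(trials, ...),
    outbid_simple = fit_outbid_simple(trials, ...),
    outbid_stratified = fit_outbid_stratified(trials, ...),
    abort(paste0("unknown model: ", model), class = "ug_config_error"))
}

#' Serialize a fit
#'
#' Writes the posterior draws as CSV (with chain ids and a JSON metadata
#' sidecar) and the derived summaries as JSON.
#'
#' @param fit `ug_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  draws_path <- file.path(dir, paste0(fit$model, "_draws.csv"))
  write_draws(fit$draws, draws_path)
  summary_path <- file.path(dir, paste0(fit$model, "_summary.json"))
  unclass_hpd <- function(v) {
    if (inherits(v, "hpd")) return(unclass(v))
    if (is.list(v) && !is.data.frame(v)) return(lapply(v, unclass_hpd))
    v
  }
  clean <- unclass_hpd(fit$summary)
  jsonlite::write_json(
    list(model = fit$model, sampler = fit$sampler, priors = fit$priors,
         summary = clean),
    summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    na = "null")
  invisible(c(draws = draws_path, summary = summary_path))
}
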