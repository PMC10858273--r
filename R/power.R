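# Simulation-based power analysis.
#
# A scenario fixes the design (number of triads, 16 sessions each), the
# agent strategies per condition, and a detection rule on one of the
# fitted models.  Each replicate simulates the whole study, fits the
# target model at reduced sampler settings, and applies the rule; power
# is the detection fraction with its exact binomial interval.

#' Define a power scenario
#'
#' @param n_triads Number of triads per replicate (default 7).
#' @param n_replicates Number of simulated studies (default 20).
#' @param proposer1,proposer2 Strategies (or zoo specs, see
#'   [resolve_strategy()]); use [strategy_by_condition()] to make
#'   behaviour differ between dyadic and triadic games — the effect the
#'   default detection rule looks for.
#' @param responder Responder function.
#' @param model Target model name for [fit_model()] (default
#'   `"total_offer"`).
#' @param detect Function `ug_fit -> logical`; the default returns TRUE
#'   when the 95% HPD of the between-condition difference excludes zero.
#' @param chains,draws,warmup Reduced sampler settings used inside the
#'   replicate loop (defaults 2 chains x 500 draws).
#' @return List of class `ug_power_scenario`.
#' @export
power_scenario <- function(n_triads = 7, n_replicates = 20,
                           proposer1 = strategy_reluctant(),
                           proposer2 = strategy_reluctant(),
                           responder = responder_maximizer(weber_w = 0.25),
                           model = "total_offer",
                           detect = detect_difference_excludes_zero,
                           chains = 2, draws = 500, warmup = 500) {
  structure(list(n_triads = n_triads, n_replicates = n_replicates,
                 proposer1 = proposer1, proposer2 = proposer2,
                 responder = responder, model = model, detect = detect,
                 chains = chains, draws = draws, warmup = warmup),
            class = "ug_power_scenario")
}

#' Default detection rule: condition-difference HPD excludes zero
#'
#' @param fit `ug_fit` with a `diff_hpd` summary element.
#' @return Logical.
#' @export
detect_difference_excludes_zero <- function(fit) {
  h <- fit$summary$diff_hpd
  isTRUE(h$lower > 0 || h$upper < 0)
}

#' Run a simulation-based power analysis
#'
#' @param scenario `ug_power_scenario`.
#' @param seed Integer seed; every replicate derives its own simulation
#'   and sampler seeds from it.
#' @return List of class `ug_power`: `power` (detection fraction over
#'   completed replicates), `ci` (exact 95% binomial interval),
#'   `n_completed`, `n_failed`, and `replicates` (per-replicate log with
#'   seeds, detection flags and any fit error message).
#' @export
run_power_analysis <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "ug_power_scenario"),
            scenario$n_replicates >= 1)
  reps <- purrr::map(seq_len(scenario$n_replicates), function(r) {
    sim_seed <- derive_seed(seed, 2 * r)
    fit_seed <- derive_seed(seed, 2 * r + 1)
    res <- tryCatch({
      d <- simulate_study(
        n_triads = scenario$n_triads,
        proposer1 = scenario$proposer1,
        proposer2 = scenario$proposer2,
        responder = scenario$responder,
        seed = sim_seed)
      fit <- suppressWarnings(fit_model(
        d, scenario$model, chains = scenario$chains,
        draws = scenario$draws, warmup = scenario$warmup,
        seed = fit_seed))
      list(detected = scenario$detect(fit), error = NA_character_)
    }, error = function(e) {
      list(detected = NA, error = conditionMessage(e))
    })
    tibble(replicate = r, sim_seed = sim_seed, fit_seed = fit_seed,
           detected = res$detected, error = res$error)
  }) %>% bind_rows()

  done <- reps %>% filter(!is.na(.data$detected))
  n_det <- sum(done$detected)
  ci <- if (nrow(done) > 0) {
    as.numeric(binom.test(n_det, nrow(done))$conf.int)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(power = if (nrow(done) > 0) n_det / nrow(done)
                 else NA_real_,
                 ci = ci, n_completed = nrow(done),
                 n_failed = sum(is.na(reps$detected)),
                 replicates = reps, seed = as.integer(seed)),
            class = "ug_power")
}

#' @export
print.ug_power <- function(x, ...) {
  cat(sprintf(
    "Power: %.2f [%.2f, %.2f] over %d replicate(s) (%d failed)\n",
    x$power, x$ci[1], x$ci[2], x$n_completed, x$n_failed))
  invisible(x)
}
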