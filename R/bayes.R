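# Posterior machinery shared by all models: the sampling contract
# (JAGS backend), highest-posterior-density intervals, directional
# probabilities, and convergence diagnostics.

#' Highest-posterior-density interval
#'
#' The shortest contiguous window over the sorted draws containing at
#' least `mass` of them: for unimodal posteriors this is the usual HPD
#' interval; for strongly multimodal draws it is the shortest single
#' interval of that mass (the HPD *region* may be disjoint).
#'
#' @param draws Numeric vector of posterior draws (at least 2 finite).
#' @param mass Probability mass to contain (default 0.95).
#' @return List of class `hpd` with `lower`, `upper`, `mass`.
#' @export
#' @examples
#' hpd_interval(rnorm(4000), 0.95)
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) abort("hpd_interval needs at least 2 finite draws")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) {
    out <- list(lower = x[1], upper = x[n], mass = mass)
  } else {
    starts <- seq_len(n - m + 1L)
    widths <- x[starts + m - 1L] - x[starts]
    i <- which.min(widths)
    out <- list(lower = x[i], upper = x[i + m - 1L], mass = mass)
  }
  class(out) <- "hpd"
  out
}

#' @export
print.hpd <- function(x, ...) {
  cat(sprintf("%.0f%% HPD [%.4g, %.4g]\n", 100 * x$mass, x$lower,
              x$upper))
  invisible(x)
}

#' Posterior probability of exceeding a threshold
#'
#' Fraction of draws strictly greater than `threshold`; the posterior
#' probability that the quantity is positive when `threshold = 0`.
#'
#' @param draws Numeric vector of draws (at least 1).
#' @param threshold Reference value (default 0).
#' @return Probability in \[0, 1\].
#' @export
prob_direction <- function(draws, threshold = 0) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 1) abort("prob_direction needs at least 1 draw")
  mean(draws > threshold)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half, so that within-chain trends register as apparent
#' non-convergence.
#'
#' @param chains List of numeric vectors, one per chain (equal length).
#' @return Scalar split-R-hat (NA for constant draws).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[(length(x) - h + 1L):length(x)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Draw from a posterior via MCMC
#'
#' The sampling contract behind every model in the package: takes a
#' model definition in the JAGS dialect of the BUGS language, runs
#' `chains` adaptive-MCMC chains with reproducible per-chain RNG seeds
#' derived from `seed`, and returns the monitored draws together with
#' convergence diagnostics (split-R-hat and effective sample size per
#' parameter).  A warning — never a silent pass — is raised when any
#' monitored parameter has split-R-hat above `rhat_max` or effective
#' sample size below `ess_min`.
#'
#' @param model JAGS model string.
#' @param data Named list of data values.
#' @param params Character vector of parameters to monitor.
#' @param chains Number of chains (default 4).
#' @param draws Post-warmup draws per chain (default 1000).
#' @param warmup Adaptation plus burn-in iterations (default 1000, split
#'   evenly).
#' @param seed Integer seed for the chain RNGs.
#' @param rhat_max,ess_min Diagnostic thresholds (defaults 1.01 and 400).
#' @param inits Optional list of initial values shared by all chains.
#' @return List of class `ug_draws`: `draws` (matrix, one column per
#'   scalar parameter, chains stacked), `chain` (chain index per row),
#'   `diagnostics` (tibble of `parameter`, `rhat`, `ess`), `chains`,
#'   `n_draws`, `seed`.
#' @export
sample_posterior <- function(model, data, params, chains = 4,
                             draws = 1000, warmup = 1000, seed = 1,
                             rhat_max = 1.01, ess_min = 400,
                             inits = NULL) {
  stopifnot(chains >= 1, draws >= 1, warmup >= 2)
  seed <- as.integer(seed)
  init_list <- lapply(seq_len(chains), function(k) {
    c(inits,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (seed * 7L + k) %% .Machine$integer.max))
  })
  n_adapt <- max(100L, floor(warmup / 2))
  n_burn <- max(1L, warmup - n_adapt)
  jm <- tryCatch(
    rjags::jags.model(textConnection(model), data = data,
                      n.chains = chains, n.adapt = n_adapt,
                      inits = init_list, quiet = TRUE),
    error = function(e) {
      abort(paste0("model initialization failed: ",
                   conditionMessage(e)),
            class = "ug_sampler_error")
    })
  update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, variable.names = params, n.iter = draws,
                            progress.bar = "none")

  mat <- do.call(rbind, lapply(sm, as.matrix))
  chain_id <- rep(seq_len(chains), each = draws)
  par_names <- colnames(mat)
  ess_all <- coda::effectiveSize(sm)
  diag <- tibble(
    parameter = par_names,
    rhat = vapply(par_names, function(p) {
      split_rhat(lapply(sm, function(ch) as.numeric(ch[, p])))
    }, numeric(1)),
    ess = as.numeric(ess_all[par_names]))
  bad <- diag %>%
    filter((is.finite(.data$rhat) & .data$rhat > rhat_max) |
             .data$ess < ess_min)
  if (nrow(bad) > 0) {
    warn(paste0("possible non-convergence for ",
                paste(bad$parameter, collapse = ", "),
                " (split-Rhat > ", rhat_max, " or ESS < ", ess_min, ")"),
         class = "ug_convergence_warning")
  }
  structure(list(draws = mat, chain = chain_id, diagnostics = diag,
                 chains = chains, n_draws = draws, seed = seed),
            class = "ug_draws")
}

#' @export
print.ug_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chains x %d draws, %d parameters\n",
              x$chains, x$n_draws, ncol(x$draws)))
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Extract a parameter's draws
#'
#' @param fit `ug_draws` object (or `ug_fit`, whose draws are used).
#' @param parameter Column name, e.g. `"beta0[1]"`.
#' @return Numeric vector of draws.
#' @export
posterior_vector <- function(fit, parameter) {
  if (inherits(fit, "ug_fit")) fit <- fit$draws
  if (!parameter %in% colnames(fit$draws)) {
    abort(paste0("no such parameter: ", parameter))
  }
  as.numeric(fit$draws[, parameter])
}

#' Write draws and metadata to disk
#'
#' Serializes a draws object as a CSV of the monitored draws plus a JSON
#' sidecar with chain layout, seed and diagnostics.
#'
#' @param x `ug_draws` object.
#' @param path Output CSV path; the sidecar is `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(x, path) {
  df <- as_tibble(as.data.frame(x$draws))
  df$.chain <- x$chain
  readr::write_csv(df, path, progress = FALSE)
  meta <- list(chains = x$chains, n_draws = x$n_draws, seed = x$seed,
               diagnostics = x$diagnostics)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
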