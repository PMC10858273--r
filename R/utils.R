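# Small internal helpers.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards so derived-quantity randomness never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds below 2^31.
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * k) %% 2147483647
}

# Standardize the session covariate within the fitted data; returns the
# standardized values plus the transform, and an evaluation grid over
# the observed sessions on both scales.
std_session <- function(session_index) {
  center <- mean(session_index)
  scale <- sd(session_index)
  if (!is.finite(scale) || scale == 0) scale <- 1
  grid <- sort(unique(session_index))
  list(x = (session_index - center) / scale,
       center = center, scale = scale,
       grid = grid, grid_std = (grid - center) / scale)
}

# Compress responses on [0,1] into the open interval required by a Beta
# likelihood: y -> (y * (n - 1) + 0.5) / n.
compress_unit <- function(y, n) {
  (y * (n - 1) + 0.5) / n
}
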