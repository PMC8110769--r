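# shared fixtures, all generated in code

# observer with a single bias component switched on; everything else off
one_bias_observer <- function(which = c("none", "adapt", "sd", "rm"),
                              amplitude = -3, noise_sd = 6, ...) {
  which <- match.arg(which)
  observer_params(
    a_adapt = if (which == "adapt") amplitude else 0,
    a_sd = if (which == "sd") amplitude else 0,
    rm_shift = if (which == "rm") amplitude else 0,
    noise_sd = noise_sd, lapse_rate = 0, ...)
}

# small clean table for inference unit tests
small_clean <- function(n_participants = 6, seed = 42,
                        params = observer_params(noise_sd = 8, lapse_rate = 0)) {
  spec <- design_spec("E1", n_blocks = 2L, trials_per_block = 36L)
  preprocess_trials(simulate_dataset(spec, n_participants, params, seed = seed))
}

# independent brute-force oracle for the signed acute orientation difference:
# the minimiser of |a - b + 180 k| over integers k, tie broken to +90
acute_diff_oracle <- function(a, b) {
  cand <- (a - b) + 180 * (-2:2)
  best <- cand[which.min(abs(cand))]
  if (abs(abs(best) - 90) < 1e-9) 90 else best
}

# dense grid-search oracle for the DoG least-squares fit
grid_fit_oracle <- function(d, e, alpha_bounds = c(-30, 30),
                            w_bounds = c(0.005, 0.20), n = 201) {
  alphas <- seq(alpha_bounds[1], alpha_bounds[2], length.out = n)
  ws <- exp(seq(log(w_bounds[1]), log(w_bounds[2]), length.out = n))
  best <- Inf
  for (w in ws) {
    g <- dog(d, 1, w)
    # sse(alpha) is quadratic: evaluate on the alpha grid in closed form
    sse <- sum(e * e) - 2 * alphas * sum(e * g) + alphas^2 * sum(g * g)
    m <- min(sse)
    if (m < best) best <- m
  }
  best
}
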