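# Synthetic observer: a generative stand-in for the human participant that
# responds to generated trial sequences with configurable amounts of the
# three history biases the analyses are designed to separate:
#   * repulsive adaptation away from the preceding stimulus (DoG-shaped),
#   * forward displacement along an implied rotation (representational
#     momentum, a constant shift on non-control Rotational trials),
#   * attractive serial dependence toward the previous trial's *reported*
#     orientation (DoG-shaped),
# plus wrapped Gaussian motor noise and a uniform lapse rate. Running the
# full pipeline on its output and recovering the generative parameters is
# how every analysis stage is validated.

#' Parameters of the synthetic observer
#'
#' @param a_adapt amplitude in degrees of the DoG bias relative to the
#'   preceding stimulus; negative = repulsion (adaptation), positive =
#'   attraction.
#' @param w_adapt inverse width (1/degrees) of the adaptation DoG. The
#'   default places the peak at 24 degrees.
#' @param a_sd amplitude in degrees of the DoG bias toward the previous
#'   trial's reported orientation (serial dependence); positive =
#'   attraction.
#' @param w_sd inverse width of the serial-dependence DoG; default peak at
#'   28.3 degrees.
#' @param rm_shift forward displacement in degrees applied on non-control
#'   Rotational trials, in the direction of rotation (i.e. away from the
#'   previous orientation, so it registers as a repulsive contribution).
#' @param noise_sd wrapped Gaussian response noise, degrees; may be 0 for
#'   noiseless checks.
#' @param lapse_rate probability of a uniform random report.
#' @param adapt_scope `"last"`: adaptation acts on the immediately
#'   preceding stimulus only (default); `"all"`: DoG contributions from
#'   every preceding stimulus in the sequence are summed, emulating
#'   adaptor stacking.
#' @param rt_meanlog,rt_sdlog lognormal reaction-time parameters (seconds);
#'   the default median is about 1.6 s.
#' @return an object of class `observer_params`.
#' @examples
#' observer_params(a_adapt = -2.16, a_sd = 1.24, noise_sd = 9)
#' @export
observer_params <- function(a_adapt = -2.16,
                            w_adapt = 1 / (24 * sqrt(2)),
                            a_sd = 1.24,
                            w_sd = 1 / (28.3 * sqrt(2)),
                            rm_shift = 3,
                            noise_sd = 9,
                            lapse_rate = 0.02,
                            adapt_scope = c("last", "all"),
                            rt_meanlog = log(1.6),
                            rt_sdlog = 0.25) {
  adapt_scope <- match.arg(adapt_scope)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (lapse_rate < 0 || lapse_rate > 1) stop("`lapse_rate` must lie in [0, 1]")
  if (w_adapt <= 0 || w_sd <= 0) stop("inverse widths must be positive")
  structure(
    list(a_adapt = a_adapt, w_adapt = w_adapt,
         a_sd = a_sd, w_sd = w_sd,
         rm_shift = rm_shift, noise_sd = noise_sd, lapse_rate = lapse_rate,
         adapt_scope = adapt_scope,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Observer: a_adapt %+.2f (peak %.1f deg), a_sd %+.2f (peak %.1f deg), rm %.1f, noise %.1f, lapse %.2f, adapt on %s\n",
    x$a_adapt, dog_peak_delta(x$w_adapt), x$a_sd, dog_peak_delta(x$w_sd),
    x$rm_shift, x$noise_sd, x$lapse_rate, x$adapt_scope))
  invisible(x)
}

# stimulus-driven part of the bias: adaptation + momentum; does not depend
# on the response history so it can be precomputed per trial
.trial_bias_det <- function(trial, params) {
  ors <- trial$orientations
  n <- length(ors)
  target <- ors[n]
  bias <- 0
  if (n >= 2) {
    if (params$adapt_scope == "last") {
      bias <- bias + dog(acute_diff(ors[n - 1L], target),
                         params$a_adapt, params$w_adapt)
    } else {
      bias <- bias + sum(dog(acute_diff(ors[seq_len(n - 1L)], target),
                             params$a_adapt, params$w_adapt))
    }
  }
  if (trial$condition == "Rotational" && !trial$is_early_control &&
      !trial$is_rotation_break_control && !is.na(trial$rotation_delta)) {
    bias <- bias - sign(trial$rotation_delta) * params$rm_shift
  }
  bias
}

#' Simulate one adjustment response
#'
#' The report is the target orientation plus the stimulus-history bias
#' (DoG adaptation toward/away from the preceding stimulus, plus the
#' constant forward displacement on non-control Rotational trials), plus a
#' DoG serial-dependence pull toward `prev_report` when available, plus
#' wrapped Gaussian noise; with probability `lapse_rate` the report is
#' uniform on `[0, 180)` instead. Uses the current RNG state.
#'
#' @param trial a `trial_sequence`.
#' @param prev_report previous trial's reported orientation in degrees, or
#'   `NULL`/`NA` on the first trial of a block (the serial-dependence term
#'   is then omitted).
#' @param params an [observer_params()].
#' @return reported orientation in degrees, in `[0, 180)`.
#' @export
simulate_response <- function(trial, prev_report = NULL,
                              params = observer_params()) {
  stopifnot(inherits(trial, "trial_sequence"), inherits(params, "observer_params"))
  if (trial$n_stimuli < 1) stop("trial must contain at least one stimulus")
  target <- trial$orientations[trial$n_stimuli]
  if (params$lapse_rate > 0 && stats::runif(1) < params$lapse_rate) {
    return(stats::runif(1, 0, 180))
  }
  bias <- .trial_bias_det(trial, params)
  if (!is.null(prev_report) && !is.na(prev_report)) {
    bias <- bias + dog(acute_diff(prev_report, target), params$a_sd, params$w_sd)
  }
  wrap_orientation(target + bias + stats::rnorm(1, 0, params$noise_sd))
}

#' Simulate a multi-participant dataset
#'
#' Generates one session per participant with [make_session()] and
#' simulates responses sequentially within each block, so that the
#' serial-dependence term chains through the actual (noisy, lapsing)
#' reports. The previous-report memory is reset at block boundaries.
#' Reaction times are drawn from the observer's lognormal.
#'
#' @param spec a [design_spec()] or an experiment label (`"E1"`, `"E2"`,
#'   `"E3"`).
#' @param n_participants number of simulated participants.
#' @param params an [observer_params()].
#' @param seed optional integer seed for exact reproducibility.
#' @return a trial table (`data.frame`, one row per trial) in the package's
#'   CSV schema: participant, experiment, block, trial, condition,
#'   n_stimuli, rotation_delta, control flags, semicolon-joined
#'   `orientations`, `target`, `reported`, `rt`.
#' @examples
#' tab <- simulate_dataset("E1", n_participants = 2, seed = 1)
#' nrow(tab)  # 2 * 288
#' @export
simulate_dataset <- function(spec, n_participants,
                             params = observer_params(), seed = NULL) {
  if (is.character(spec)) spec <- design_spec(spec)
  stopifnot(inherits(spec, "design_spec"), n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)

  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    session <- make_session(spec)
    n <- length(session)
    target <- vapply(session, function(tr) tr$orientations[tr$n_stimuli],
                     numeric(1))
    block <- vapply(session, function(tr) tr$block, integer(1))
    det <- vapply(session, .trial_bias_det, numeric(1), params = params)
    noise <- stats::rnorm(n, 0, params$noise_sd)
    lap_u <- stats::runif(n)
    lap_v <- stats::runif(n, 0, 180)
    rt <- stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)

    a_sd <- params$a_sd; w_sd <- params$w_sd
    report <- numeric(n)
    prev_rep <- NA_real_
    prev_block <- -1L
    for (i in seq_len(n)) {
      if (block[i] != prev_block) {
        prev_rep <- NA_real_
        prev_block <- block[i]
      }
      if (lap_u[i] < params$lapse_rate) {
        r <- lap_v[i]
      } else {
        b <- det[i]
        if (!is.na(prev_rep)) {
          dd <- 90 - ((90 - (prev_rep - target[i])) %% 180)
          b <- b + dd * a_sd * w_sd * dog_constant * exp(-(w_sd * dd)^2)
        }
        r <- (target[i] + b + noise[i]) %% 180
      }
      report[i] <- r
      prev_rep <- r
    }

    out[[p]] <- data.frame(
      participant = p,
      experiment = spec$experiment,
      block = block,
      trial = stats::ave(seq_len(n), block, FUN = seq_along),
      condition = vapply(session, `[[`, character(1), "condition"),
      n_stimuli = vapply(session, `[[`, integer(1), "n_stimuli"),
      rotation_delta = vapply(session, `[[`, numeric(1), "rotation_delta"),
      is_early_control = vapply(session, `[[`, logical(1), "is_early_control"),
      is_rotation_break_control =
        vapply(session, `[[`, logical(1), "is_rotation_break_control"),
      orientations = vapply(session, function(tr) {
        paste(tr$orientations, collapse = ";")
      }, character(1)),
      target = target,
      reported = report,
      rt = rt,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
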