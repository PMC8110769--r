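# Stimulus-sequence generators for the three blocked adjustment experiments.
#
# Every trial shows a sequence of Gabor orientations and the observer
# reproduces the last one. In Rotational trials consecutive orientations
# step by a fixed Delta (previous minus present), mimicking constant
# rotation; Random trials are order-shuffled versions of rotational
# sequences whose final pair (and hence the analysed final Delta) is
# preserved, so the two conditions are matched on the designed Delta counts.

ORIENT_GRID <- seq(0, 160, by = 20)

#' Design specification for one session
#'
#' Encodes the blocked design of one experiment: number of blocks, trials
#' per block, the set of signed rotation steps (Delta, degrees), sequence
#' lengths, and the control-trial proportions. Defaults follow the three
#' experiments: E1/E2 run 4 blocks of 72 six-stimulus trials with
#' `delta_set` \eqn{\pm\{20,40,60\}}; E3 runs 4 blocks of 80 trials of 4-12
#' stimuli with `delta_set` \eqn{\pm\{20,40\}}. In all designs 20% of trials
#' are early-terminating controls and 16% of Rotational trials are
#' rotation-break controls whose last orientation is drawn at random.
#'
#' @param experiment `"E1"`, `"E2"` or `"E3"`.
#' @param n_blocks number of blocks (alternating condition).
#' @param trials_per_block trials in each block.
#' @param p_early_control proportion of early-terminating control trials.
#' @param p_rotation_break_control proportion of Rotational trials whose
#'   last orientation breaks the expected rotation.
#' @param delta_set signed rotation steps in degrees; 0 is not allowed.
#' @param seq_len_range integer(2), inclusive range of sequence lengths.
#' @return an object of class `design_spec`.
#' @examples
#' design_spec("E1")
#' design_spec("E3")
#' @export
design_spec <- function(experiment = c("E1", "E2", "E3"),
                        n_blocks = 4L,
                        trials_per_block = NULL,
                        p_early_control = 0.20,
                        p_rotation_break_control = 0.16,
                        delta_set = NULL,
                        seq_len_range = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(trials_per_block)) {
    trials_per_block <- if (experiment == "E3") 80L else 72L
  }
  if (is.null(delta_set)) {
    delta_set <- if (experiment == "E3") {
      c(-40, -20, 20, 40)
    } else {
      c(-60, -40, -20, 20, 40, 60)
    }
  }
  if (is.null(seq_len_range)) {
    seq_len_range <- if (experiment == "E3") c(4L, 12L) else c(6L, 6L)
  }
  if (any(delta_set == 0)) {
    stop("`delta_set` must not contain 0: a zero step is incompatible with ",
         "constant rotational motion")
  }
  if (p_early_control < 0 || p_early_control > 1 ||
      p_rotation_break_control < 0 || p_rotation_break_control > 1) {
    stop("control proportions must lie in [0, 1]")
  }
  if (n_blocks %% 2 != 0) stop("`n_blocks` must be even (conditions alternate)")
  structure(
    list(experiment = experiment,
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         p_early_control = p_early_control,
         p_rotation_break_control = p_rotation_break_control,
         delta_set = delta_set,
         seq_len_range = as.integer(seq_len_range)),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design %s: %d blocks x %d trials, Delta in {%s}, lengths %d-%d\n",
              x$experiment, x$n_blocks, x$trials_per_block,
              paste(x$delta_set, collapse = ", "),
              x$seq_len_range[1], x$seq_len_range[2]))
  cat(sprintf("  early controls %.0f%%, rotation-break controls %.0f%%\n",
              100 * x$p_early_control, 100 * x$p_rotation_break_control))
  invisible(x)
}

new_trial_sequence <- function(orientations, condition, experiment,
                               rotation_delta = NA_real_,
                               is_early_control = FALSE,
                               is_rotation_break_control = FALSE,
                               locations = NULL) {
  structure(
    list(orientations = wrap_orientation(orientations),
         condition = condition,
         experiment = experiment,
         n_stimuli = length(orientations),
         rotation_delta = rotation_delta,
         is_early_control = is_early_control,
         is_rotation_break_control = is_rotation_break_control,
         locations = locations),
    class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("%s %s trial (%d stimuli%s): %s\n",
              x$experiment, x$condition, x$n_stimuli,
              if (x$is_early_control) ", early control"
              else if (x$is_rotation_break_control) ", rotation-break control"
              else "",
              paste(round(x$orientations, 1), collapse = " ")))
  invisible(x)
}

#' Build a rotational trial sequence
#'
#' Steps the orientation by a fixed Delta per stimulus, with Delta defined
#' as previous minus present: orientation k equals
#' `(first_orientation - k * delta) mod 180`, so every consecutive acute
#' difference (previous minus present) equals `delta`.
#'
#' @param first_orientation starting orientation in degrees, on the
#'   20-degree grid `{0, 20, ..., 160}`.
#' @param delta signed rotation step in degrees; 0 is rejected.
#' @param n_stimuli sequence length, at least 2.
#' @param experiment experiment label.
#' @return a `trial_sequence` with `condition = "Rotational"`.
#' @examples
#' make_rotational_trial(0, 20, 6)$orientations    # 0 160 140 120 100 80
#' @export
make_rotational_trial <- function(first_orientation, delta, n_stimuli,
                                  experiment = "E1") {
  if (!isTRUE(min(abs(first_orientation - ORIENT_GRID)) < 1e-9)) {
    stop("`first_orientation` must lie on the 20-degree grid 0, 20, ..., 160")
  }
  if (delta == 0) stop("`delta` = 0 is not a rotation")
  if (n_stimuli < 2) stop("`n_stimuli` must be at least 2")
  k <- seq_len(n_stimuli) - 1L
  new_trial_sequence(wrap_orientation(first_orientation - k * delta),
                     condition = "Rotational", experiment = experiment,
                     rotation_delta = delta)
}

# shuffle all but the final two stimuli, rejecting permutations that are
# still a constant rotation (all consecutive acute differences equal)
.shuffle_keep_final <- function(ors, max_tries = 100L) {
  n <- length(ors)
  head_idx <- seq_len(n - 2L)
  for (i in seq_len(max_tries)) {
    cand <- c(ors[head_idx][sample.int(n - 2L)], ors[n - 1L], ors[n])
    d <- acute_diff(cand[-n], cand[-1L])
    if (length(unique(round(d, 9))) > 1L) return(cand)
  }
  stop("could not find a non-rotational permutation in ", max_tries, " tries")
}

#' Derive a Random trial from a rotational one
#'
#' Shuffles the order of all stimuli except the final two, which are left
#' in place so that the final-pair Delta -- the quantity entering the bias
#' analyses -- is preserved and the per-Delta trial counts remain matched
#' across conditions. Permutations whose consecutive differences are all
#' equal (i.e. that are still a rotation) are rejected and redrawn, up to
#' `max_tries` times.
#'
#' @param rotational a non-control Rotational `trial_sequence` with at
#'   least 4 stimuli.
#' @param max_tries resampling cap for the structure-removal rejection.
#' @return a `trial_sequence` with `condition = "Random"` over the same
#'   orientation multiset.
#' @export
make_random_trial <- function(rotational, max_tries = 100L) {
  stopifnot(inherits(rotational, "trial_sequence"))
  if (rotational$condition != "Rotational" || rotational$is_early_control ||
      rotational$is_rotation_break_control) {
    stop("`rotational` must be a non-control Rotational trial")
  }
  if (rotational$n_stimuli < 4L) {
    stop("sequences with fewer than 4 stimuli cannot be shuffled meaningfully")
  }
  new_trial_sequence(.shuffle_keep_final(rotational$orientations, max_tries),
                     condition = "Random",
                     experiment = rotational$experiment,
                     rotation_delta = rotational$rotation_delta,
                     locations = rotational$locations)
}

#' Derive an adaptor-stacked Random trial (Experiment 3 rule)
#'
#' Starting from a shuffled sequence with the final pair preserved, every
#' non-target stimulus whose acute difference to the target exceeds
#' 40 degrees in absolute value is replaced by an orientation 20 or 40
#' degrees from the target on the same side as the trial's rotation step.
#' The resulting Random sequence therefore contains at least as many
#' within-`\eqn{\pm}`40-degree adaptors as its rotational source, stacking the
#' designed adaptation asymmetry against the Rotational condition.
#'
#' @inheritParams make_random_trial
#' @return a `trial_sequence` with `condition = "Random"`.
#' @export
make_exp3_random_trial <- function(rotational, max_tries = 100L) {
  stopifnot(inherits(rotational, "trial_sequence"))
  if (rotational$condition != "Rotational" || rotational$is_early_control ||
      rotational$is_rotation_break_control) {
    stop("`rotational` must be a non-control Rotational trial")
  }
  if (rotational$n_stimuli < 4L) {
    stop("sequences with fewer than 4 stimuli cannot be shuffled meaningfully")
  }
  n <- rotational$n_stimuli
  side <- sign(rotational$rotation_delta)
  for (i in seq_len(max_tries)) {
    ors <- .shuffle_keep_final(rotational$orientations, max_tries)
    target <- ors[n]
    rel <- acute_diff(ors, target)
    repl <- abs(rel) > 40 & seq_len(n) < n - 1L  # final pair untouched
    if (any(repl)) {
      ors[repl] <- wrap_orientation(
        target + side * sample(c(20, 40), sum(repl), replace = TRUE))
    }
    d <- acute_diff(ors[-n], ors[-1L])
    if (length(unique(round(d, 9))) > 1L) {
      return(new_trial_sequence(ors, condition = "Random",
                                experiment = rotational$experiment,
                                rotation_delta = rotational$rotation_delta,
                                locations = rotational$locations))
    }
  }
  stop("could not build a non-rotational adaptor-stacked sequence")
}

# cumulative (largest-remainder) integer allocation: group g of size `unit`
# receives round(p*g*unit) - round(p*(g-1)*unit) items, so session totals
# track p as closely as integer counts allow
.alloc_counts <- function(unit, p, n_groups) {
  cum <- round(p * unit * seq_len(n_groups))
  as.integer(diff(c(0L, cum)))
}

.truncate_trial <- function(x, len) {
  x$orientations <- x$orientations[seq_len(len)]
  x$n_stimuli <- len
  x$is_early_control <- TRUE
  if (!is.null(x$locations)) x$locations <- x$locations[seq_len(len), , drop = FALSE]
  x
}

.sample_locations <- function(n, radius = 3) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Generate a full session of trial sequences
#'
#' Builds `n_blocks` alternating-condition blocks of `trials_per_block`
#' trials. Blocks come in Rotational/Random pairs: the Random block of each
#' pair is derived trial by trial from the rotational prototypes of its
#' paired block (same rotation step, same early-control status), so the
#' designed per-Delta allocation is identical across conditions. Within a
#' pair, rotation steps are allocated in equal numbers over `delta_set` and
#' control counts follow cumulative rounding of the stated proportions;
#' trial order is then shuffled within block. Condition order of the first
#' block is counterbalanced by the random stream.
#'
#' Early-terminating control trials keep only the first 1 to
#' `n_stimuli - 1` stimuli (1-5 for the six-stimulus designs);
#' rotation-break controls (Rotational condition only) replace the last
#' orientation with a different random grid orientation.
#'
#' @param spec a [design_spec()].
#' @param seed optional integer seed; with the same seed the session is
#'   reproduced exactly.
#' @return list of `trial_sequence` objects, each carrying a `$block`
#'   index, in presentation order.
#' @examples
#' length(make_session(design_spec("E1"), seed = 1))  # 288
#' @export
make_session <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.null(seed)) set.seed(seed)
  tpb <- spec$trials_per_block
  n_pairs <- spec$n_blocks %/% 2L
  cond_order <- sample(c("Rotational", "Random"))
  early_counts <- .alloc_counts(tpb, spec$p_early_control, n_pairs)
  rotbrk_counts <- .alloc_counts(tpb, spec$p_rotation_break_control, n_pairs)

  if (length(spec$delta_set) > 0 && tpb %% length(spec$delta_set) != 0) {
    deltas_base <- NULL  # sampled instead of balanced
  } else {
    deltas_base <- rep(spec$delta_set, tpb / length(spec$delta_set))
  }

  session <- list()
  block_id <- 0L
  for (p in seq_len(n_pairs)) {
    deltas <- if (is.null(deltas_base)) {
      sample(spec$delta_set, tpb, replace = TRUE)
    } else {
      sample(deltas_base)
    }
    lens <- if (spec$seq_len_range[1] == spec$seq_len_range[2]) {
      rep(spec$seq_len_range[1], tpb)
    } else {
      sample(seq(spec$seq_len_range[1], spec$seq_len_range[2]), tpb,
             replace = TRUE)
    }
    firsts <- sample(ORIENT_GRID, tpb, replace = TRUE)
    protos <- lapply(seq_len(tpb), function(i) {
      tr <- make_rotational_trial(firsts[i], deltas[i], lens[i],
                                  experiment = spec$experiment)
      if (spec$experiment == "E2") tr$locations <- .sample_locations(lens[i])
      tr
    })
    early_idx <- if (early_counts[p] > 0) sample(tpb, early_counts[p]) else integer()
    trunc_len <- vapply(early_idx, function(i) {
      sample.int(lens[i] - 1L, 1L)
    }, integer(1))

    # Rotational block: prototypes, truncated or rotation-broken
    rot <- protos
    for (j in seq_along(early_idx)) {
      rot[[early_idx[j]]] <- .truncate_trial(rot[[early_idx[j]]], trunc_len[j])
    }
    full_idx <- setdiff(seq_len(tpb), early_idx)
    brk_idx <- if (rotbrk_counts[p] > 0) {
      sample(full_idx, min(rotbrk_counts[p], length(full_idx)))
    } else integer()
    for (i in brk_idx) {
      n <- rot[[i]]$n_stimuli
      old <- rot[[i]]$orientations[n]
      rot[[i]]$orientations[n] <- sample(setdiff(ORIENT_GRID, old), 1L)
      rot[[i]]$is_rotation_break_control <- TRUE
    }

    # Random block: derived 1:1 from the (unbroken) prototypes
    rnd <- lapply(seq_len(tpb), function(i) {
      shuffler <- if (spec$experiment == "E3") make_exp3_random_trial else make_random_trial
      tr <- shuffler(protos[[i]])
      if (spec$experiment == "E2") tr$locations <- .sample_locations(tr$n_stimuli)
      tr
    })
    for (j in seq_along(early_idx)) {
      rnd[[early_idx[j]]] <- .truncate_trial(rnd[[early_idx[j]]], trunc_len[j])
    }

    for (cond in cond_order) {
      block_id <- block_id + 1L
      blk <- if (cond == "Rotational") rot else rnd
      blk <- blk[sample.int(tpb)]
      for (i in seq_along(blk)) blk[[i]]$block <- block_id
      session <- c(session, blk)
    }
  }
  session
}
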