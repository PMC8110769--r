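test_that("rotational sequences step by -Delta with constant acute differences", {
  tr <- make_rotational_trial(0, 20, 6)
  expect_equal(tr$orientations, c(0, 160, 140, 120, 100, 80))
  d <- acute_diff(tr$orientations[-6], tr$orientations[-1])
  expect_equal(d, rep(20, 5))

  tr2 <- make_rotational_trial(100, -20, 2)
  expect_equal(tr2$orientations[2], 120)
  expect_equal(acute_diff(100, 120), -20)

  # large step with mod-180 wrap: exhaustive check of every consecutive pair
  tr3 <- make_rotational_trial(160, 60, 6)
  expect_true(all(tr3$orientations >= 0 & tr3$orientations < 180))
  d3 <- acute_diff(tr3$orientations[-6], tr3$orientations[-1])
  expect_equal(d3, rep(60, 5))

  expect_error(make_rotational_trial(0, 0, 6), "rotation")
  expect_error(make_rotational_trial(0, 20, 1), "at least 2")
  expect_error(make_rotational_trial(15, 20, 6), "grid")
})

test_that("random trials preserve the multiset and the final pair, not the structure", {
  set.seed(10)
  for (r in 1:20) {
    rot <- make_rotational_trial(sample(seq(0, 160, 20), 1),
                                 sample(c(-60, -40, -20, 20, 40, 60), 1), 6)
    rnd <- make_random_trial(rot)
    expect_equal(sort(rnd$orientations), sort(rot$orientations))
    expect_equal(rnd$orientations[5:6], rot$orientations[5:6])
    d <- acute_diff(rnd$orientations[-6], rnd$orientations[-1])
    expect_gt(length(unique(round(d, 9))), 1)  # temporal structure removed
    expect_equal(d[5], rot$rotation_delta)
  }
  short <- make_rotational_trial(0, 20, 3)
  expect_error(make_random_trial(short), "fewer than 4")
})

test_that("random derivation preserves the final-pair Delta histogram", {
  set.seed(11)
  deltas <- sample(c(-60, -40, -20, 20, 40, 60), 1000, replace = TRUE)
  rots <- lapply(deltas, function(dl) {
    make_rotational_trial(sample(seq(0, 160, 20), 1), dl, 6)
  })
  rnds <- lapply(rots, make_random_trial)
  last_delta <- function(tr) {
    n <- tr$n_stimuli
    acute_diff(tr$orientations[n - 1], tr$orientations[n])
  }
  expect_equal(table(vapply(rnds, last_delta, numeric(1))),
               table(vapply(rots, last_delta, numeric(1))))
})

test_that("adaptor-stacked E3 random trials increase same-side adaptors", {
  set.seed(12)
  adaptor_counts <- function(tr) {
    n <- tr$n_stimuli
    rel <- acute_diff(tr$orientations[-n], tr$orientations[n])
    c(within = sum(abs(rel) <= 40),
      same_side = sum(abs(rel) <= 40 & sign(rel) == sign(tr$rotation_delta)))
  }
  n_rot <- n_rnd <- numeric(400)
  for (r in 1:400) {
    rot <- make_rotational_trial(sample(seq(0, 160, 20), 1),
                                 sample(c(-40, -20, 20, 40), 1),
                                 sample(4:12, 1), experiment = "E3")
    rnd <- make_exp3_random_trial(rot)
    cr <- adaptor_counts(rot); cn <- adaptor_counts(rnd)
    expect_gte(cn["within"], cr["within"])
    # after replacement every non-target stimulus lies within +/-40 degrees
    reln <- acute_diff(rnd$orientations[-rnd$n_stimuli],
                       rnd$orientations[rnd$n_stimuli])
    expect_true(all(abs(reln) <= 40))
    # stimuli already within +/-40 degrees of the target are never altered
    rel0 <- acute_diff(rot$orientations, rot$orientations[rot$n_stimuli])
    kept <- rot$orientations[abs(rel0) <= 40]
    expect_true(all(kept %in% rnd$orientations))
    n_rot[r] <- cr["same_side"]; n_rnd[r] <- cn["same_side"]
  }
  expect_gt(mean(n_rnd), mean(n_rot))  # the designed adaptation asymmetry
})

test_that("sessions realise the blocked design and its control proportions", {
  s1 <- make_session(design_spec("E1"), seed = 21)
  expect_length(s1, 288)
  full <- vapply(s1, function(t) !t$is_early_control, logical(1))
  expect_equal(sum(full), 230)  # closest integer realisation of 80%
  conds <- vapply(s1, `[[`, character(1), "condition")
  blocks <- vapply(s1, `[[`, integer(1), "block")
  expect_equal(length(unique(blocks)), 4)
  expect_true(all(tapply(conds, blocks, function(x) length(unique(x))) == 1))
  rot <- conds == "Rotational"
  brk <- vapply(s1, `[[`, logical(1), "is_rotation_break_control")
  expect_equal(sum(brk[rot]), 23)  # closest realisation of 16% of 144
  expect_false(any(brk[!rot]))
  ors <- unlist(lapply(s1, `[[`, "orientations"))
  expect_true(all(ors >= 0 & ors < 180))

  s3 <- make_session(design_spec("E3"), seed = 22)
  expect_length(s3, 320)
  lens <- vapply(s3, `[[`, integer(1), "n_stimuli")
  expect_true(all(lens >= 1 & lens <= 12))

  s0 <- make_session(design_spec("E1", p_early_control = 0), seed = 23)
  expect_true(all(vapply(s0, `[[`, integer(1), "n_stimuli") == 6))
})

test_that("the designed per-Delta allocation is identical across conditions", {
  s <- make_session(design_spec("E1"), seed = 24)
  conds <- vapply(s, `[[`, character(1), "condition")
  deltas <- vapply(s, `[[`, numeric(1), "rotation_delta")
  expect_equal(table(deltas[conds == "Rotational"]),
               table(deltas[conds == "Random"]))
  # each Delta appears equally often: 288 / 6 per condition pair
  expect_true(all(table(deltas) == 48))
  # and the realised final-pair Delta equals the designed one on every
  # full-length non-control trial, in both conditions
  ok <- vapply(s, function(t) !t$is_early_control && !t$is_rotation_break_control,
               logical(1))
  realised <- vapply(s[ok], function(t) {
    acute_diff(t$orientations[t$n_stimuli - 1], t$orientations[t$n_stimuli])
  }, numeric(1))
  expect_equal(realised, deltas[ok])
})

test_that("session generation is reproducible given a seed", {
  a <- make_session(design_spec("E2"), seed = 31)
  b <- make_session(design_spec("E2"), seed = 31)
  expect_identical(a, b)
  expect_true(all(vapply(a, function(t) !is.null(t$locations), logical(1))))
  r <- vapply(a, function(t) max(sqrt(rowSums(t$locations^2))), numeric(1))
  expect_true(all(r <= 3))  # E2 locations stay within the 3-degree disc
})
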