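test_that("errors and history predictors follow the sign conventions", {
  tab <- data.frame(
    participant = 1L, block = 1L, trial = 1:3,
    condition = "Random", experiment = "E1",
    n_stimuli = 2L,
    rotation_delta = NA_real_,
    is_early_control = FALSE, is_rotation_break_control = FALSE,
    orientations = c("40;20", "10;170", "100;100"),
    target = c(20, 170, 100),
    reported = c(30, 175, 100),
    rt = 1.5)
  out <- compute_errors(tab)
  expect_equal(out$error, c(10, 5, 0))
  # sequence (..., 40, 20): previous minus present = +20; an error of the
  # same sign counts as attraction toward the previous orientation
  expect_equal(out$delta_prev_stim, c(20, 20, 0))
})

test_that("constant response offsets vanish after mean correction", {
  spec <- design_spec("E1", n_blocks = 2L, trials_per_block = 24L)
  tab <- simulate_dataset(spec, 2, one_bias_observer("none", noise_sd = 0),
                          seed = 51)
  tab$reported <- wrap_orientation(tab$target + 7)
  clean <- preprocess_trials(tab)
  expect_equal(clean$error, rep(0, nrow(clean)), tolerance = 1e-9)
  # and per-group means are numerically zero on noisy data too
  tab2 <- simulate_dataset(spec, 3, observer_params(), seed = 52)
  clean2 <- preprocess_trials(tab2)
  grp_means <- tapply(clean2$error,
                      interaction(clean2$participant, clean2$condition),
                      mean)
  expect_true(all(abs(grp_means) < 1e-9))
})

test_that("outlier flagging applies the strict RT and 3-SD rules", {
  set.seed(53)
  n <- 200
  tab <- data.frame(
    participant = 1L, block = rep(1:2, each = n / 2), trial = rep(1:(n / 2), 2),
    condition = "Random", experiment = "E1", n_stimuli = 6L,
    rotation_delta = 20,
    is_early_control = FALSE, is_rotation_break_control = FALSE,
    orientations = "100;80;60;40;20;0", target = 0,
    reported = wrap_orientation(rnorm(n, 0, 5)), rt = 1.5)
  tab$reported[10] <- 80           # planted gross error among sigma = 5 noise
  tab$rt[20] <- 0.4                # below 500 ms: outlier
  tab$rt[30] <- 0.5                # exactly 500 ms: retained
  tab$rt[40] <- 10.0               # exactly 10 s: retained
  tab$rt[50] <- 10.5               # above 10 s: outlier
  out <- flag_outliers(compute_errors(tab))
  expect_true(out$is_outlier[10])
  expect_true(out$is_outlier[20])
  expect_false(out$is_outlier[30])
  expect_false(out$is_outlier[40])
  expect_true(out$is_outlier[50])
  expect_equal(sum(out$is_outlier), 3)
  # successor flagged within block only
  expect_true(out$is_post_outlier[11])
  expect_false(out$is_post_outlier[1])
  tab2 <- tab
  tab2$reported[n / 2] <- 88       # outlier on the last trial of block 1
  out2 <- flag_outliers(compute_errors(tab2))
  expect_false(out2$is_post_outlier[n / 2 + 1])  # block 2 does not inherit it
})

test_that("participants are excluded on the 30-degree error-SD rule", {
  spec <- design_spec("E1", n_blocks = 2L, trials_per_block = 36L)
  good <- simulate_dataset(spec, 2, one_bias_observer("none", noise_sd = 8),
                           seed = 54)
  guesser <- simulate_dataset(spec, 1, observer_params(lapse_rate = 1),
                              seed = 55)
  guesser$participant <- 3L
  tab <- compute_errors(rbind(good, guesser))
  # uniform errors on (-90, 90] have SD 180/sqrt(12) ~ 52 degrees
  sd_guess <- sd(tab$error[tab$participant == 3])
  expect_gt(sd_guess, 45)
  expect_lt(sd_guess, 60)
  ex <- exclude_participants(tab)
  expect_equal(ex$excluded, 3)
  expect_false(3 %in% ex$table$participant)

  # SD just under the threshold is retained; an error-free table excludes no one
  tab$error[tab$participant == 3] <- rnorm(sum(tab$participant == 3), 0, 29)
  expect_length(exclude_participants(tab)$excluded, 0)
  tab$error <- 0
  expect_length(exclude_participants(tab)$excluded, 0)
})

test_that("preprocessing removes the right rows and is stable on reapplication", {
  tab <- simulate_dataset("E1", 4, observer_params(), seed = 56)
  clean <- preprocess_trials(tab)
  expect_lt(nrow(clean), nrow(tab))
  expect_gt(nrow(clean), 0)
  expect_false(any(clean$is_early_control | clean$is_rotation_break_control |
                     clean$is_outlier | clean$is_post_outlier))
  expect_lt(attr(clean, "outlier_rate"), 0.05)
  # reapplying the pipeline to its own output changes nothing
  expect_identical(preprocess_trials(clean), clean)
  # and the rules themselves are deterministic
  expect_identical(preprocess_trials(tab)$error, clean$error)
})

test_that("the previous-report predictor skips outliers and can chain", {
  tab <- data.frame(
    participant = 1L, block = 1L, trial = 1:5,
    condition = "Random", experiment = "E1", n_stimuli = 6L,
    rotation_delta = 20,
    is_early_control = FALSE, is_rotation_break_control = FALSE,
    orientations = "100;80;60;40;20;0", target = 0,
    reported = c(10, 12, 170, 8, 11), rt = c(1.5, 1.5, 12, 1.5, 1.5))
  clean <- suppressWarnings(preprocess_trials(tab))
  # trial 3 is an RT outlier; trial 4 follows it and is removed
  expect_equal(clean$trial, c(1L, 2L, 5L))
  # the block's first trial has no previous report
  expect_true(is.na(clean$delta_prev_report[clean$trial == 1]))
  expect_equal(clean$delta_prev_report[clean$trial == 2], acute_diff(10, 0))
  # trial 4 was removed from analysis but its report was still made, so it
  # remains trial 5's serial-dependence source
  expect_equal(clean$delta_prev_report[clean$trial == 5], acute_diff(8, 0))
  # chaining across the removed outlier leaves retained predictors intact
  chained <- suppressWarnings(preprocess_trials(tab, chain_prev_report = TRUE))
  expect_equal(chained$delta_prev_report, clean$delta_prev_report)
})

test_that("trial tables round-trip through CSV and column maps", {
  tab <- simulate_dataset(design_spec("E1", n_blocks = 2L,
                                      trials_per_block = 12L),
                          2, observer_params(), seed = 57)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tab, path)
  back <- read_trials(path)
  expect_equal(back, tab)

  # external headers adapted through a column map give the same clean table
  ext <- tab
  names(ext)[names(ext) == "participant"] <- "subj"
  names(ext)[names(ext) == "reported"] <- "resp"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(ext, path2)
  expect_error(read_trials(path2), "participant")
  remapped <- read_trials(path2, col_map = c(subj = "participant",
                                             resp = "reported"))
  expect_equal(preprocess_trials(remapped)$error, preprocess_trials(tab)$error)
})
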