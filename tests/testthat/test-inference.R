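test_that("degenerate stratified resampling collapses to the point estimate", {
  clean <- small_clean(n_participants = 1, seed = 61)
  bt <- stratified_bootstrap_alpha(clean, "prev_stim", n_iter = 25,
                                   frac = 1.0, seed = 1)
  expect_true(all(bt$alphas == bt$alpha_point))
})

test_that("bootstrap and permutation results are reproducible given a seed", {
  clean <- small_clean(seed = 62)
  b1 <- stratified_bootstrap_alpha(clean, "prev_stim", n_iter = 40, seed = 9)
  b2 <- stratified_bootstrap_alpha(clean, "prev_stim", n_iter = 40, seed = 9)
  expect_identical(b1$alphas, b2$alphas)
  p1 <- permutation_test_alpha(clean, n_perm = 120, seed = 9)
  p2 <- permutation_test_alpha(clean, n_perm = 120, seed = 9)
  expect_identical(p1$perm_diffs, p2$perm_diffs)
  expect_true(p1$p_value >= 0 && p1$p_value <= 1)
})

test_that("a strong attractive bias yields a decisive bootstrap p", {
  obs <- observer_params(a_adapt = 4, a_sd = 0, rm_shift = 0,
                         noise_sd = 6, lapse_rate = 0)
  clean <- preprocess_trials(simulate_dataset(
    design_spec("E1", n_blocks = 2L, trials_per_block = 36L), 8, obs,
    seed = 63))
  bt <- stratified_bootstrap_alpha(clean, "prev_stim", n_iter = 300, seed = 2)
  expect_gt(bt$alpha_point, 2)
  expect_equal(bt$p_value, 0)        # no bootstrap amplitude crosses zero
  expect_gt(min(bt$alphas), 0)
})

test_that("null bootstrap p values are broadly distributed, not pinned at zero", {
  # the one-sided subsample-bootstrap p is anti-conservative by construction
  # (an 80% subsample spreads about half as much as the sampling error of
  # the full fit), so under the null it is broad rather than uniform; the
  # calibrated between-condition test is the permutation test
  p <- vapply(1:10, function(r) {
    clean <- small_clean(seed = 640 + r, params = one_bias_observer("none"))
    stratified_bootstrap_alpha(clean, "prev_stim", n_iter = 100,
                               seed = r)$p_value
  }, numeric(1))
  expect_gte(mean(p > 0.01), 0.6)
  expect_gt(max(p), 0.2)
})

test_that("the permutation test rejects a real condition difference", {
  # adaptation plus momentum makes the Rotational amplitude clearly more
  # negative than the Random one
  obs <- observer_params(a_adapt = -2, a_sd = 0, rm_shift = 3,
                         noise_sd = 6, lapse_rate = 0)
  clean <- preprocess_trials(simulate_dataset("E1", 8, obs, seed = 65))
  pt <- permutation_test_alpha(clean, n_perm = 300, seed = 4)
  expect_lt(pt$p_value, 0.01)
})

test_that("the permutation test refuses a confounded design", {
  clean <- small_clean(seed = 66)
  confounded <- clean
  confounded$condition <- ifelse(confounded$participant %% 2 == 0,
                                 "Rotational", "Random")
  expect_error(permutation_test_alpha(confounded, n_perm = 100),
               "confounded")
  expect_warning(permutation_test_alpha(clean, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("the model-free index carries the attraction-positive convention", {
  clean0 <- small_clean(seed = 67, params = one_bias_observer("none"))
  zero <- clean0
  zero$error <- 0
  idx0 <- model_free_index(zero, "prev_stim")
  expect_equal(idx0$index, rep(0, nrow(idx0)))

  attract <- preprocess_trials(simulate_dataset(
    "E1", 8, one_bias_observer("sd", amplitude = 2, noise_sd = 6), seed = 68))
  idx_a <- model_free_index(attract, "prev_report")
  expect_gt(mean(idx_a$index, na.rm = TRUE), 0)

  repel <- preprocess_trials(simulate_dataset(
    "E1", 8, one_bias_observer("adapt", amplitude = -3, noise_sd = 6),
    seed = 69))
  idx_r <- model_free_index(repel, "prev_stim")
  expect_lt(mean(idx_r$index, na.rm = TRUE), 0)
  gt <- group_tests(idx_r$index)
  expect_lt(gt$t, 0)                 # repulsion prints as a negative t
  idx_lit <- model_free_index(repel, "prev_stim", orientation = "literal")
  expect_equal(idx_lit$index, -idx_r$index)
})

test_that("group tests match the d = t/sqrt(n) identity and flag zero variance", {
  set.seed(70)
  x <- rnorm(14, 0.5, 1)
  gt <- group_tests(x)
  expect_equal(gt$cohens_d, gt$t / sqrt(14), tolerance = 1e-12)
  expect_equal(gt$df, 13)
  expect_equal(gt$p, t.test(x)$p.value)
  expect_warning(g0 <- group_tests(c(1, 1, 1)), "variance")
  expect_true(is.infinite(g0$t) && g0$t > 0)
  y <- rnorm(14)
  gp <- group_tests(x, y)
  expect_equal(gp$t, t.test(x, y, paired = TRUE)$statistic[[1]],
               tolerance = 1e-12)
})

test_that("dominance analysis separates stimulus-driven from report-driven bias", {
  zero <- small_clean(seed = 71, params = one_bias_observer("none"))
  zero$error <- 0
  dz <- dominance_analysis(zero, n_iter = 30, seed = 1)
  for (el in dz) {
    if (length(el$b1) > 0) {
      expect_equal(el$b1, rep(0, length(el$b1)), tolerance = 1e-12)
      expect_equal(el$b2, rep(0, length(el$b2)), tolerance = 1e-12)
    }
  }

  stim_only <- preprocess_trials(simulate_dataset(
    "E1", 14, one_bias_observer("adapt", amplitude = -3, noise_sd = 6),
    seed = 72))
  ds <- dominance_analysis(stim_only, n_iter = 150, seed = 2)
  for (el in ds) {
    expect_gt(mean(el$diff < 0), 0.9)         # stimulus dominates, negative
    expect_lt(abs(median(el$b2)), 1)          # report coefficient near zero
    expect_lt(median(el$b1), -1.5)
  }

  rep_only <- preprocess_trials(simulate_dataset(
    "E1", 14, one_bias_observer("sd", amplitude = 3, noise_sd = 6),
    seed = 73))
  dr <- dominance_analysis(rep_only, n_iter = 150, seed = 3)
  for (el in dr) {
    expect_lt(abs(median(el$b1)), 1)          # roles reversed
    expect_gt(median(el$b2), 1)
    expect_gt(mean(el$abs_diff < 0), 0.9)     # report history dominates
  }
})

test_that("control checks behave under the null and detect planted noise", {
  tab <- simulate_dataset("E1", 8, observer_params(), seed = 74)
  cc <- control_checks(tab)
  expect_s3_class(cc$early_fifth, "group_test")
  expect_s3_class(cc$rotation_break, "group_test")
  expect_gt(cc$early_fifth$p, 0.05)
  expect_gt(cc$rotation_break$p, 0.05)

  # doubling the response noise on early controls makes test (i) fire
  noisy <- tab
  sel <- noisy$is_early_control
  set.seed(75)
  noisy$reported[sel] <- wrap_orientation(noisy$reported[sel] +
                                            rnorm(sum(sel), 0, 25))
  cc2 <- control_checks(noisy)
  expect_lt(cc2$early_fifth$p, 0.01)

  no_controls <- tab[!tab$is_early_control & !tab$is_rotation_break_control, ]
  cc3 <- control_checks(no_controls)
  expect_equal(cc3$early_fifth, "not applicable")
  expect_equal(cc3$rotation_break, "not applicable")
})
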