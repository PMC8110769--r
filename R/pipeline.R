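# End-to-end orchestration: design -> simulate -> preprocess -> fit ->
# inference, as one reproducible run driven by a serialisable config, plus
# the parameter-recovery harness used to validate the pipeline.

#' Pipeline run configuration
#'
#' Bundles everything a run needs: the experiment design, the synthetic
#' observer, iteration counts for the resampling procedures, and the master
#' seed. The whole object serialises to JSON ([save_config()]) so a run's
#' configuration can be archived beside its outputs.
#'
#' @param experiment `"E1"`, `"E2"` or `"E3"`.
#' @param n_participants simulated participants.
#' @param observer an [observer_params()].
#' @param design optional [design_spec()] override (defaults to the
#'   experiment's standard design).
#' @param seed master seed; every stochastic stage derives from it.
#' @param n_boot bootstrap iterations for amplitude inference.
#' @param n_perm permutations for the between-condition test.
#' @param n_dom bootstrap iterations for the dominance analysis.
#' @param frac stratified-resampling fraction.
#' @param fit_method DoG fitting strategy used inside resampling loops.
#' @param chain_prev_report see [preprocess_trials()].
#' @param out_dir optional directory: when set, `trials.csv`, `clean.csv`,
#'   `report.json` and `run.log` are written there.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = "E1",
                            n_participants = 14,
                            observer = observer_params(),
                            design = NULL,
                            seed = 1L,
                            n_boot = 1000,
                            n_perm = 1000,
                            n_dom = 500,
                            frac = 0.80,
                            fit_method = "profile",
                            chain_prev_report = FALSE,
                            out_dir = NULL) {
  if (is.null(design)) design <- design_spec(experiment)
  structure(
    list(experiment = experiment,
         n_participants = as.integer(n_participants),
         observer = observer,
         design = design,
         seed = as.integer(seed),
         n_boot = as.integer(n_boot),
         n_perm = as.integer(n_perm),
         n_dom = as.integer(n_dom),
         frac = frac,
         fit_method = fit_method,
         chain_prev_report = chain_prev_report,
         out_dir = out_dir),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$observer <- unclass(x$observer)
  x$design <- unclass(x$design)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  obs <- do.call(observer_params, x$observer)
  des <- design_spec(x$design$experiment,
                     n_blocks = x$design$n_blocks,
                     trials_per_block = x$design$trials_per_block,
                     p_early_control = x$design$p_early_control,
                     p_rotation_break_control = x$design$p_rotation_break_control,
                     delta_set = x$design$delta_set,
                     seq_len_range = x$design$seq_len_range)
  pipeline_config(experiment = x$experiment,
                  n_participants = x$n_participants,
                  observer = obs,
                  design = des,
                  seed = x$seed,
                  n_boot = x$n_boot,
                  n_perm = x$n_perm,
                  n_dom = x$n_dom,
                  frac = x$frac,
                  fit_method = x$fit_method,
                  chain_prev_report = x$chain_prev_report,
                  out_dir = x$out_dir)
}

.fit_summary <- function(fit) {
  list(alpha = fit$alpha, w = fit$w, peak_delta = fit$peak_delta,
       peak_bias = fit$peak_bias, peak_percent = fit$peak_percent,
       sse = fit$sse, n_trials = fit$n_trials, converged = fit$converged)
}

.boot_summary <- function(bt) {
  list(alpha_point = bt$alpha_point, boot_mean = bt$boot_mean,
       boot_median = bt$boot_median,
       q025 = unname(stats::quantile(bt$alphas, 0.025)),
       q975 = unname(stats::quantile(bt$alphas, 0.975)),
       p_value = bt$p_value, p_two_sided = bt$p_two_sided,
       n_iter = bt$n_iter, frac = bt$frac)
}

.gt_summary <- function(gt) {
  if (is.character(gt)) return(gt)
  unclass(gt)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Simulates the configured experiment, preprocesses it, and runs the
#' model-based (DoG fits with stratified-bootstrap p values per condition
#' plus the previous-report fit, and the between-condition permutation
#' test), model-free (per-condition indices, one-sample and paired t
#' tests), dominance, and control-check analyses. Experiment 3 is analysed
#' model-free only, matching the restricted Delta range of that design.
#'
#' @param config a [pipeline_config()].
#' @return a report list (class `pipeline_report`); when `config$out_dir`
#'   is set, `trials.csv`, `clean.csv`, `report.json` and `run.log` are
#'   written there. The report JSON contains no timestamps, so identical
#'   configs give byte-identical reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }

  say("stage design+simulate: ", config$experiment, ", ",
      config$n_participants, " participants, seed ", config$seed)
  trials <- simulate_dataset(config$design, config$n_participants,
                             config$observer, seed = config$seed)

  checks <- control_checks(trials)

  say("stage preprocess")
  clean <- preprocess_trials(trials,
                             chain_prev_report = config$chain_prev_report)
  say("  excluded participants: ",
      paste(attr(clean, "excluded_participants"), collapse = ", "),
      if (length(attr(clean, "excluded_participants")) == 0) "(none)")
  say(sprintf("  outlier rate %.2f%%, %d of %d trials retained",
              100 * attr(clean, "outlier_rate"), nrow(clean), nrow(trials)))

  conds <- sort(unique(clean$condition))
  model_based <- NULL
  if (config$experiment != "E3") {
    say("stage model-based fits")
    by_cond <- lapply(conds, function(cc) {
      bt <- stratified_bootstrap_alpha(clean, "prev_stim", condition = cc,
                                       n_iter = config$n_boot,
                                       frac = config$frac,
                                       seed = config$seed + 1L,
                                       fit_method = config$fit_method)
      list(fit = .fit_summary(bt$fit), bootstrap = .boot_summary(bt))
    })
    names(by_cond) <- conds
    bt_rep <- stratified_bootstrap_alpha(clean, "prev_report",
                                         n_iter = config$n_boot,
                                         frac = config$frac,
                                         seed = config$seed + 2L,
                                         fit_method = config$fit_method)
    perm <- permutation_test_alpha(clean, "prev_stim",
                                   n_perm = config$n_perm,
                                   seed = config$seed + 3L,
                                   fit_method = config$fit_method)
    model_based <- list(
      prev_stim = by_cond,
      prev_report = list(fit = .fit_summary(bt_rep$fit),
                         bootstrap = .boot_summary(bt_rep)),
      permutation = list(observed_diff = perm$observed,
                         p_value = perm$p_value,
                         conditions = perm$conditions,
                         n_perm = config$n_perm))
  }

  say("stage model-free")
  mf <- lapply(conds, function(cc) {
    idx <- model_free_index(clean, "prev_stim", condition = cc)
    list(indices = idx$index, test = .gt_summary(group_tests(idx$index)))
  })
  names(mf) <- conds
  idx1 <- model_free_index(clean, "prev_stim", condition = conds[1])$index
  idx2 <- model_free_index(clean, "prev_stim", condition = conds[2])$index
  mf_paired <- .gt_summary(group_tests(idx1, idx2))
  mf_report <- model_free_index(clean, "prev_report")
  mf_report_test <- .gt_summary(group_tests(mf_report$index))

  dom <- NULL
  if (config$experiment != "E3") {
    say("stage dominance")
    dm <- dominance_analysis(clean, n_iter = config$n_dom,
                             frac = config$frac, seed = config$seed + 4L)
    dom <- lapply(dm, function(el) {
      if (is.null(el$summary)) list(condition = el$condition, n = el$n)
      else as.list(el$summary)
    })
  }

  report <- structure(
    list(schema_version = "1",
         experiment = config$experiment,
         seed = config$seed,
         n_participants = config$n_participants,
         excluded_participants = attr(clean, "excluded_participants"),
         outlier_rate = attr(clean, "outlier_rate"),
         n_trials = nrow(trials),
         n_clean = nrow(clean),
         mean_abs_error = mean(abs(acute_diff(trials$reported, trials$target))),
         model_based = model_based,
         model_free = list(by_condition = mf,
                           paired = mf_paired,
                           prev_report = list(indices = mf_report$index,
                                              test = mf_report_test)),
         dominance = dom,
         control_checks = list(
           early_fifth = .gt_summary(checks$early_fifth),
           rotation_break = .gt_summary(checks$rotation_break))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    write_trials(as.data.frame(clean), file.path(config$out_dir, "clean.csv"))
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    save_config(config, file.path(config$out_dir, "config.json"))
    writeLines(c(paste("run at", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 log_lines),
               file.path(config$out_dir, "run.log"))
  }
  attr(report, "log") <- log_lines
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %s, %d participants, seed %d\n",
              x$experiment, x$n_participants, x$seed))
  cat(sprintf("  %d trials, %d clean (outlier rate %.2f%%), mean |error| %.2f deg\n",
              x$n_trials, x$n_clean, 100 * x$outlier_rate, x$mean_abs_error))
  if (!is.null(x$model_based)) {
    for (cc in names(x$model_based$prev_stim)) {
      el <- x$model_based$prev_stim[[cc]]
      cat(sprintf("  %s: alpha %+.2f (peak %.1f deg, %.1f%%), bootstrap p = %.4g\n",
                  cc, el$fit$alpha, el$fit$peak_delta, el$fit$peak_percent,
                  el$bootstrap$p_value))
    }
    cat(sprintf("  prev report: alpha %+.2f, bootstrap p = %.4g\n",
                x$model_based$prev_report$fit$alpha,
                x$model_based$prev_report$bootstrap$p_value))
    cat(sprintf("  condition difference: %+.2f, permutation p = %.4g\n",
                x$model_based$permutation$observed_diff,
                x$model_based$permutation$p_value))
  }
  invisible(x)
}

#' Parameter-recovery harness
#'
#' Simulates datasets over a grid of generative observer parameters,
#' runs the full preprocessing + fitting pipeline on each replicate, and
#' tabulates generative against recovered quantities: the adaptation
#' amplitude (fitted on the preceding-stimulus predictor), the
#' serial-dependence amplitude (previous-report predictor), and the
#' per-condition model-free indices.
#'
#' @param grid `data.frame` whose columns (any of `a_adapt`, `a_sd`,
#'   `rm_shift`, `noise_sd`, `lapse_rate`) override [observer_params()]
#'   defaults row by row; unnamed parameters keep their defaults.
#' @param n_replicates simulated datasets per grid row.
#' @param design a [design_spec()].
#' @param n_participants participants per dataset.
#' @param seed master seed.
#' @param base_observer observer whose unlisted parameters are kept.
#' @param fit_method DoG fitting strategy.
#' @return `data.frame`, one row per grid cell: generative values, mean
#'   recovered amplitudes, bias, RMSE, sign-recovery rates, and the mean
#'   per-condition model-free indices.
#' @export
run_recovery <- function(grid, n_replicates = 10,
                         design = design_spec("E1"),
                         n_participants = 14,
                         seed = 1L,
                         base_observer = observer_params(),
                         fit_method = "profile") {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * n_replicates),
                      nrow = nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pars <- unclass(base_observer)
    for (nm in names(grid)) pars[[nm]] <- grid[[nm]][g]
    obs <- do.call(observer_params, pars)
    a_hat <- s_hat <- mf_rot <- mf_rnd <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      tab <- simulate_dataset(design, n_participants, obs,
                              seed = rep_seeds[g, r])
      clean <- preprocess_trials(tab)
      a_hat[r] <- fit_dog(clean$delta_prev_stim, clean$error,
                          method = fit_method)$alpha
      s_hat[r] <- fit_dog(clean$delta_prev_report, clean$error,
                          method = fit_method)$alpha
      mf_rot[r] <- mean(model_free_index(clean, "prev_stim",
                                         condition = "Rotational")$index,
                        na.rm = TRUE)
      mf_rnd[r] <- mean(model_free_index(clean, "prev_stim",
                                         condition = "Random")$index,
                        na.rm = TRUE)
    }
    rows[[g]] <- data.frame(
      a_adapt_true = obs$a_adapt, a_sd_true = obs$a_sd,
      rm_shift = obs$rm_shift, noise_sd = obs$noise_sd,
      a_adapt_hat = mean(a_hat), a_adapt_bias = mean(a_hat - obs$a_adapt),
      a_adapt_rmse = sqrt(mean((a_hat - obs$a_adapt)^2)),
      a_adapt_sign_rate = mean(sign(a_hat) == sign(obs$a_adapt)),
      a_sd_hat = mean(s_hat), a_sd_bias = mean(s_hat - obs$a_sd),
      a_sd_rmse = sqrt(mean((s_hat - obs$a_sd)^2)),
      a_sd_sign_rate = mean(sign(s_hat) == sign(obs$a_sd)),
      mf_index_rotational = mean(mf_rot),
      mf_index_random = mean(mf_rnd),
      n_replicates = n_replicates)
  }
  do.call(rbind, rows)
}
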