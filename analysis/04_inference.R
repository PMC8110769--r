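#!/usr/bin/env Rscript
# Model-free indices and group tests, between-condition permutation tests,
# dominance analyses, and the control-trial checks, for all experiments.

library(serialbias)
report <- list()

for (exp in c("e1", "e2", "e3")) {
  EXP <- toupper(exp)
  cat("==", EXP, "==\n")
  raw <- read_trials(file.path("results", paste0("trials_", exp, ".csv")))
  clean <- read_trials(file.path("results", paste0("clean_", exp, ".csv")))

  cc <- control_checks(raw)
  print(cc)

  idx_rot <- model_free_index(clean, "prev_stim", condition = "Rotational")
  idx_rnd <- model_free_index(clean, "prev_stim", condition = "Random")
  cat("model-free, Rotational: "); print(group_tests(idx_rot$index))
  cat("model-free, Random:     "); print(group_tests(idx_rnd$index))
  cat("model-free, paired:     "); print(group_tests(idx_rot$index, idx_rnd$index))
  entry <- list(
    control_checks = list(
      early_fifth = if (is.character(cc$early_fifth)) cc$early_fifth
                    else unclass(cc$early_fifth),
      rotation_break = if (is.character(cc$rotation_break)) cc$rotation_break
                       else unclass(cc$rotation_break)),
    model_free = list(
      rotational = unclass(group_tests(idx_rot$index)),
      random = unclass(group_tests(idx_rnd$index)),
      paired = unclass(group_tests(idx_rot$index, idx_rnd$index))))

  if (exp != "e3") {
    idx_rep <- model_free_index(clean, "prev_report")
    cat("model-free, prev report:"); print(group_tests(idx_rep$index))
    entry$model_free$prev_report <- unclass(group_tests(idx_rep$index))

    pt <- permutation_test_alpha(clean, "prev_stim", n_perm = 1000, seed = 99)
    cat(sprintf("permutation Rot-vs-Rand: diff %+0.2f deg, p = %.4g\n",
                pt$observed, pt$p_value))
    entry$permutation <- list(observed = pt$observed, p = pt$p_value)

    dm <- dominance_analysis(clean, n_iter = 500, seed = 100)
    print(dm)
    entry$dominance <- lapply(dm, function(el) as.list(el$summary))
  }
  report[[EXP]] <- entry
}

jsonlite::write_json(report, "results/inference.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/inference.json\n")
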