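#!/usr/bin/env Rscript
# Clean the simulated trial tables: compute errors, apply the outlier and
# participant-exclusion rules, and mean-correct. Writes the clean tables
# and a short filtering log.

library(serialbias)

log_lines <- character()
for (exp in c("e1", "e2", "e3")) {
  tab <- read_trials(file.path("results", paste0("trials_", exp, ".csv")))
  clean <- preprocess_trials(tab)
  write_trials(as.data.frame(clean),
               file.path("results", paste0("clean_", exp, ".csv")))
  line <- sprintf(
    "%s: %d/%d trials retained, outlier rate %.2f%%, excluded participants: %s",
    toupper(exp), nrow(clean), nrow(tab), 100 * attr(clean, "outlier_rate"),
    if (length(attr(clean, "excluded_participants")) == 0) "none"
    else paste(attr(clean, "excluded_participants"), collapse = ", "))
  cat(line, "\n")
  log_lines <- c(log_lines, line)
}
writeLines(log_lines, "results/preprocess_log.txt")
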