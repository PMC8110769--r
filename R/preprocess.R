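# Error computation and trial/participant filtering, following the study's
# preprocessing rules: adjustment error is the signed acute angle between
# reported and actual orientation; trials with |error| beyond 3 SD of the
# participant's mean or reaction times below 500 ms / above 10 s (strict
# inequalities) are outliers; control trials, outliers and the trial
# immediately after an outlier are removed; participants with an error SD
# above 30 degrees are excluded; retained errors are mean-corrected per
# participant x condition.

.order_trials <- function(table) {
  table[order(table$participant, table$block, table$trial), , drop = FALSE]
}

#' Compute adjustment errors and the stimulus-history predictor
#'
#' Adds to the table the raw adjustment error
#' `acute_diff(reported, target)` and `delta_prev_stim`, the acute
#' difference between the penultimate stimulus of the sequence and the
#' target (previous minus present; `NA` for single-stimulus sequences).
#' Rows with a missing report get `NA` errors and a message; they are not
#' dropped here.
#'
#' @param table a trial table.
#' @return the table with `error` and `delta_prev_stim` columns, ordered by
#'   participant, block, trial.
#' @export
compute_errors <- function(table) {
  stopifnot(all(c("reported", "orientations") %in% names(table)))
  table <- .order_trials(table)
  ors <- .parse_orientations(table$orientations)
  n_st <- lengths(ors)
  if (is.null(table$target)) {
    table$target <- vapply(seq_along(ors), function(i) ors[[i]][n_st[i]],
                           numeric(1))
  }
  table$error <- acute_diff(table$reported, table$target)
  prev_stim <- rep(NA_real_, nrow(table))
  has_prev <- n_st >= 2L
  prev_stim[has_prev] <- vapply(which(has_prev), function(i) {
    ors[[i]][n_st[i] - 1L]
  }, numeric(1))
  table$delta_prev_stim <- acute_diff(prev_stim, table$target)
  n_missing <- sum(is.na(table$reported))
  if (n_missing > 0) {
    message(n_missing, " trial(s) without a report were flagged (error = NA)")
  }
  table
}

#' Flag outlier trials and their successors
#'
#' Marks as outliers trials whose absolute error deviates from the
#' participant's mean raw error by more than `sd_mult` standard deviations
#' (one pass, computed per participant on raw errors), or whose reaction
#' time is strictly below `rt_limits[1]` or strictly above `rt_limits[2]`
#' seconds; rows with a missing error are also flagged. The trial
#' immediately following an outlier within the same block is marked
#' `is_post_outlier` (the first trial of a block never inherits one).
#'
#' @param table a trial table with errors computed.
#' @param rt_limits numeric(2) reaction-time window in seconds.
#' @param sd_mult multiplier of the per-participant error SD.
#' @return the table with logical `is_outlier` and `is_post_outlier`
#'   columns.
#' @export
flag_outliers <- function(table, rt_limits = c(0.5, 10), sd_mult = 3) {
  stopifnot("error" %in% names(table))
  table <- .order_trials(table)
  mu <- stats::ave(table$error, table$participant,
                   FUN = function(x) mean(x, na.rm = TRUE))
  sd_p <- stats::ave(table$error, table$participant,
                     FUN = function(x) stats::sd(x, na.rm = TRUE))
  err_out <- !is.na(table$error) & abs(table$error - mu) > sd_mult * sd_p
  rt_out <- !is.na(table$rt) &
    (table$rt < rt_limits[1] | table$rt > rt_limits[2])
  table$is_outlier <- err_out | rt_out | is.na(table$error)

  grp <- interaction(table$participant, table$block, drop = TRUE)
  table$is_post_outlier <- as.logical(
    stats::ave(table$is_outlier, grp,
               FUN = function(x) c(FALSE, utils::head(x, -1))))

  usable <- tapply(!table$is_outlier, table$participant, sum)
  low <- names(usable)[usable < 10]
  if (length(low) > 0) {
    warning("participant(s) with fewer than 10 usable trials: ",
            paste(low, collapse = ", "))
  }
  table
}

#' Exclude imprecise participants
#'
#' Removes participants whose standard deviation of raw adjustment errors
#' exceeds `sd_limit` degrees (strictly), e.g. observers responding at
#' random (uniform errors on (-90, 90] have an SD of about 52 degrees).
#'
#' @param table a trial table with errors computed.
#' @param sd_limit exclusion threshold in degrees.
#' @return list with `table` (retained rows) and `excluded` (ids).
#' @export
exclude_participants <- function(table, sd_limit = 30) {
  stopifnot("error" %in% names(table))
  sds <- tapply(table$error, table$participant,
                function(x) stats::sd(x, na.rm = TRUE))
  excluded <- names(sds)[!is.na(sds) & sds > sd_limit]
  keep <- !(as.character(table$participant) %in% excluded)
  list(table = table[keep, , drop = FALSE],
       excluded = utils::type.convert(excluded, as.is = TRUE))
}

# previous retained report per row: raw adjacency by default (NA if the
# preceding trial was an outlier); chain = TRUE walks back to the last
# non-outlier report within the block
.prev_report <- function(table, chain = FALSE) {
  out <- rep(NA_real_, nrow(table))
  grp <- interaction(table$participant, table$block, drop = TRUE)
  for (g in levels(grp)) {
    k <- which(grp == g)
    rep_g <- table$reported[k]
    out_g <- table$is_outlier[k]
    if (!chain) {
      prev <- c(NA_real_, utils::head(rep_g, -1))
      prev[c(FALSE, utils::head(out_g, -1))] <- NA_real_
    } else {
      prev <- rep(NA_real_, length(k))
      last_ok <- NA_real_
      for (j in seq_along(k)) {
        prev[j] <- last_ok
        if (!out_g[j]) last_ok <- rep_g[j]
      }
    }
    out[k] <- prev
  }
  out
}

#' Run the full preprocessing pipeline
#'
#' Computes errors, flags outliers, excludes imprecise participants,
#' attaches the previous-report predictor, removes control trials, outliers
#' and trials immediately after an outlier, and mean-corrects the retained
#' errors per participant x condition. The previous-report predictor
#' `delta_prev_report` is computed before control rows are dropped (a
#' report made on a control trial is still the observer's most recent
#' decision) but is `NA` when the preceding trial was an outlier, unless
#' `chain_prev_report = TRUE`, in which case it falls back to the last
#' retained report within the block.
#'
#' @param table a raw trial table.
#' @param chain_prev_report chain the previous-report predictor across
#'   removed trials? Default `FALSE`.
#' @param rt_limits,sd_mult passed to [flag_outliers()].
#' @param sd_limit passed to [exclude_participants()].
#' @return the clean table (class `clean_trials`): no control trials, no
#'   outliers, no post-outlier trials, errors mean-corrected per
#'   participant x condition, with `delta_prev_stim` and
#'   `delta_prev_report` columns. Attributes: `excluded_participants`,
#'   `outlier_rate`, `n_input`.
#' @examples
#' tab <- simulate_dataset("E1", 2, seed = 1)
#' clean <- preprocess_trials(tab)
#' attr(clean, "outlier_rate")
#' @export
preprocess_trials <- function(table, chain_prev_report = FALSE,
                              rt_limits = c(0.5, 10), sd_mult = 3,
                              sd_limit = 30) {
  # preprocessing is idempotent: a table that has already been cleaned is
  # returned as is (the outlier thresholds are defined on the raw data, so
  # re-estimating them on the filtered subset would be a different rule)
  if (inherits(table, "clean_trials")) return(table)
  t1 <- compute_errors(table)
  t2 <- flag_outliers(t1, rt_limits = rt_limits, sd_mult = sd_mult)
  ex <- exclude_participants(t2, sd_limit = sd_limit)
  t3 <- ex$table
  t3$delta_prev_report <- acute_diff(.prev_report(t3, chain = chain_prev_report),
                                     t3$target)
  outlier_rate <- mean(t3$is_outlier)
  keep <- !t3$is_early_control & !t3$is_rotation_break_control &
    !t3$is_outlier & !t3$is_post_outlier & !is.na(t3$error)
  clean <- t3[keep, , drop = FALSE]
  clean$error <- clean$error -
    stats::ave(clean$error, clean$participant, clean$condition)
  rownames(clean) <- NULL
  structure(clean,
            excluded_participants = ex$excluded,
            outlier_rate = outlier_rate,
            n_input = nrow(table),
            class = c("clean_trials", class(clean)))
}
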