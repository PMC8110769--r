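# Group-level inference on the bias curves: stratified bootstrap on the
# DoG amplitude, permutation comparison between conditions, the model-free
# positive-vs-negative Delta index with standard t statistics, the
# regression dominance analysis of stimulus history against report
# history, and the control-trial sanity checks.

.predictor_col <- function(predictor = c("prev_stim", "prev_report")) {
  predictor <- match.arg(predictor)
  paste0("delta_", predictor)
}

.participant_index <- function(table) {
  split(seq_len(nrow(table)), table$participant)
}

# one stratified subsample: floor(frac * n_p) trials per participant,
# without replacement, pooled into a grand-subject index vector
.stratified_sample <- function(idx_by_p, frac) {
  unlist(lapply(idx_by_p, function(k) {
    m <- floor(frac * length(k))
    if (m >= length(k)) k else k[sample.int(length(k), m)]
  }), use.names = FALSE)
}

#' Stratified bootstrap of the DoG amplitude
#'
#' Repeatedly combines `frac` of randomly selected trials from each
#' participant (without replacement) into a grand-subject dataset, refits
#' the DoG curve, and records the amplitude. The p value is the proportion
#' of bootstrap amplitudes on the side of zero opposite to the sign of the
#' full-data point estimate (one-sided, as the bootstrap is used here for a
#' directional test of the amplitude against zero); a two-sided version
#' (`2 * min(tail proportions)`) is also returned.
#'
#' @param table a clean trial table (see [preprocess_trials()]).
#' @param predictor `"prev_stim"` (bias relative to the preceding stimulus)
#'   or `"prev_report"` (bias relative to the previous trial's report).
#' @param condition optional condition label to subset on.
#' @param n_iter number of bootstrap iterations (study default 5000).
#' @param frac fraction of each participant's trials per resample
#'   (study default 0.80).
#' @param seed optional seed; results are reproducible given
#'   `(seed, n_iter)`.
#' @param fit_method,... forwarded to [fit_dog()]; the exact-profile fit is
#'   the default inside resampling loops.
#' @return an object of class `bootstrap_result`: `alphas` (one per
#'   resample), `alpha_point` (full-data fit), `p_value`, `p_two_sided`,
#'   `boot_mean`, `boot_median`, `n_iter`, `frac`, plus the full-data
#'   `fit`.
#' @export
stratified_bootstrap_alpha <- function(table,
                                       predictor = c("prev_stim", "prev_report"),
                                       condition = NULL,
                                       n_iter = 5000, frac = 0.80,
                                       seed = NULL,
                                       fit_method = "profile", ...) {
  col <- .predictor_col(predictor)
  if (!is.null(condition)) table <- table[table$condition == condition, ]
  table <- table[is.finite(table[[col]]) & is.finite(table$error), ]
  if (length(unique(table$participant)) < 1) stop("no usable trials")
  if (!is.null(seed)) set.seed(seed)

  point <- fit_dog(table[[col]], table$error, method = fit_method, ...)
  idx_by_p <- .participant_index(table)
  alphas <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    for (try in 1:100) {
      k <- .stratified_sample(idx_by_p, frac)
      if (length(k) >= 20) break
    }
    alphas[b] <- fit_dog(table[[col]][k], table$error[k],
                         method = fit_method, ...)$alpha
  }
  p_neg <- mean(alphas < 0)
  p_pos <- mean(alphas > 0)
  p_one <- if (point$alpha > 0) p_neg else if (point$alpha < 0) p_pos
           else min(p_neg, p_pos)
  structure(
    list(alphas = alphas,
         alpha_point = point$alpha,
         p_value = p_one,
         p_two_sided = min(1, 2 * min(p_neg, p_pos)),
         boot_mean = mean(alphas),
         boot_median = stats::median(alphas),
         n_iter = n_iter, frac = frac,
         predictor = match.arg(predictor), condition = condition,
         fit = point),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Stratified bootstrap (%d x %.0f%%) of DoG alpha [%s%s]\n",
              x$n_iter, 100 * x$frac, x$predictor,
              if (is.null(x$condition)) "" else paste0(", ", x$condition)))
  cat(sprintf("  point %+.3f, boot mean %+.3f [%.3f, %.3f], p = %.4g\n",
              x$alpha_point, x$boot_mean,
              stats::quantile(x$alphas, 0.025),
              stats::quantile(x$alphas, 0.975), x$p_value))
  invisible(x)
}

#' Permutation test of the amplitude difference between conditions
#'
#' Shuffles the condition labels of trials within each participant,
#' refits the DoG per label on the pooled data, and compares the observed
#' amplitude difference with the surrogate distribution. Two-sided:
#' `p = mean(|surrogate| >= |observed|)`.
#'
#' @inheritParams stratified_bootstrap_alpha
#' @param n_perm number of label shuffles (study default 10,000).
#' @return list with `observed` (alpha difference, first condition label in
#'   sort order minus the second), `p_value`, `perm_diffs`, `conditions`.
#' @export
permutation_test_alpha <- function(table,
                                   predictor = c("prev_stim", "prev_report"),
                                   n_perm = 10000, seed = NULL,
                                   fit_method = "profile", ...) {
  col <- .predictor_col(predictor)
  table <- table[is.finite(table[[col]]) & is.finite(table$error), ]
  conds <- sort(unique(table$condition))
  if (length(conds) != 2) stop("exactly two condition labels are required")
  per_p <- tapply(table$condition, table$participant,
                  function(x) length(unique(x)))
  if (all(per_p < 2)) {
    stop("condition is confounded with participant: ",
         "within-participant shuffling is impossible")
  }
  if (n_perm < 100) warning("n_perm < 100 gives unstable p values")
  if (!is.null(seed)) set.seed(seed)

  d <- table[[col]]
  e <- table$error
  lab <- table$condition
  fit_diff <- function(labels) {
    a1 <- fit_dog(d[labels == conds[1]], e[labels == conds[1]],
                  method = fit_method, ...)$alpha
    a2 <- fit_dog(d[labels == conds[2]], e[labels == conds[2]],
                  method = fit_method, ...)$alpha
    a1 - a2
  }
  observed <- fit_diff(lab)
  idx_by_p <- .participant_index(table)
  perm_diffs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    shuffled <- lab
    for (k in idx_by_p) shuffled[k] <- lab[k[sample.int(length(k))]]
    perm_diffs[b] <- fit_diff(shuffled)
  }
  list(observed = observed,
       p_value = mean(abs(perm_diffs) >= abs(observed)),
       perm_diffs = perm_diffs,
       conditions = conds)
}

#' Model-free bias index
#'
#' For each participant, the mean error at Delta in `{+20, +40}` minus the
#' mean error at Delta in `{-20, -40}` degrees (trials at larger |Delta|
#' are excluded). With this orientation a positive index means attraction
#' toward the previous orientation and a negative index repulsion,
#' consistent with the sign convention of the model-based analysis;
#' `orientation = "literal"` returns the opposite (repulsion-positive)
#' sign.
#'
#' @param table a clean trial table.
#' @param predictor which history variable defines Delta.
#' @param condition optional condition subset.
#' @param band numeric(2), inclusive |Delta| range in degrees.
#' @param orientation `"attraction"` (positive = attractive; default) or
#'   `"literal"`.
#' @return `data.frame` with `participant`, `index` (degrees), and the
#'   per-side trial counts; participants lacking trials on either side get
#'   `NA` with a message.
#' @export
model_free_index <- function(table,
                             predictor = c("prev_stim", "prev_report"),
                             condition = NULL,
                             band = c(20, 40),
                             orientation = c("attraction", "literal")) {
  orientation <- match.arg(orientation)
  col <- .predictor_col(predictor)
  if (!is.null(condition)) table <- table[table$condition == condition, ]
  d <- table[[col]]
  ok <- is.finite(d) & is.finite(table$error) &
    abs(d) >= band[1] - 1e-9 & abs(d) <= band[2] + 1e-9
  tab <- table[ok, ]
  ids <- sort(unique(table$participant))
  res <- lapply(ids, function(p) {
    tp <- tab[tab$participant == p, ]
    dp <- tp[[col]]
    pos <- tp$error[dp > 0]
    neg <- tp$error[dp < 0]
    if (length(pos) == 0 || length(neg) == 0) {
      message("participant ", p, ": no trials on one side of Delta = 0; ",
              "index set to NA")
      idx <- NA_real_
    } else {
      idx <- mean(pos) - mean(neg)
    }
    data.frame(participant = p, index = idx,
               n_pos = length(pos), n_neg = length(neg))
  })
  out <- do.call(rbind, res)
  if (orientation == "literal") out$index <- -out$index
  out
}

#' One-sample or paired t summary with Cohen's d
#'
#' One-sample two-tailed t test of `x` against zero, or a paired t test of
#' `x` against `y` (computed on the differences). Cohen's d is the mean of
#' the (difference) scores divided by their SD, so `d = t / sqrt(n)`.
#'
#' @param x numeric values (e.g. per-participant indices).
#' @param y optional paired values.
#' @return list of class `group_test`: `estimate`, `t`, `df`, `p`,
#'   `cohens_d`, `n`. Zero variance yields an infinite t with a warning.
#' @export
group_tests <- function(x, y = NULL) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep] - y[keep]
  } else {
    x <- x[is.finite(x)]
  }
  n <- length(x)
  if (n < 3) stop("at least 3 values are required")
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) {
    warning("zero variance: t is infinite")
    t_val <- sign(m) * Inf
    p <- if (m == 0) NA_real_ else 0
    d <- sign(m) * Inf
  } else {
    ht <- stats::t.test(x, mu = 0)
    t_val <- unname(ht$statistic)
    p <- ht$p.value
    d <- m / s
  }
  structure(list(estimate = m, t = t_val, df = n - 1L, p = p,
                 cohens_d = d, n = n),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.2f (mean %+.3f, n = %d)\n",
              x$df, x$t, x$p, x$cohens_d, x$estimate, x$n))
  invisible(x)
}

#' Dominance analysis of stimulus history versus report history
#'
#' Restricts to trials where both |Delta| values (preceding stimulus and
#' previous report) fall in the 20-40 degree band, where the DoG is
#' approximately linear, codes the two predictors by their sign
#' (`+1`/`-1`), and within each stratified-bootstrap resample fits the
#' ordinary least-squares model
#' `error ~ b0 + b1 * sign(delta_prev_stim) + b2 * sign(delta_prev_report)`.
#' The distribution of `b1 - b2` (and of `|b1| - |b2|`, the magnitude
#' dominance) is recorded per condition. Resamples in which the two sign
#' predictors are collinear are redrawn.
#'
#' @inheritParams stratified_bootstrap_alpha
#' @param band inclusive |Delta| band in degrees.
#' @return list of class `dominance_result`, one element per condition,
#'   each with vectors `b1`, `b2`, `diff`, `abs_diff` and a `summary` row.
#' @export
dominance_analysis <- function(table, n_iter = 1000, frac = 0.80,
                               seed = NULL, band = c(20, 40)) {
  stopifnot(all(c("delta_prev_stim", "delta_prev_report") %in% names(table)))
  if (!is.null(seed)) set.seed(seed)
  conds <- sort(unique(table$condition))
  out <- lapply(conds, function(cond) {
    tc <- table[table$condition == cond, ]
    ok <- is.finite(tc$delta_prev_stim) & is.finite(tc$delta_prev_report) &
      abs(tc$delta_prev_stim) >= band[1] - 1e-9 &
      abs(tc$delta_prev_stim) <= band[2] + 1e-9 &
      abs(tc$delta_prev_report) >= band[1] - 1e-9 &
      abs(tc$delta_prev_report) <= band[2] + 1e-9
    tc <- tc[ok, ]
    if (nrow(tc) < 20) {
      return(list(condition = cond, n = nrow(tc), b1 = numeric(0),
                  b2 = numeric(0), diff = numeric(0), abs_diff = numeric(0),
                  summary = NULL))
    }
    x1 <- sign(tc$delta_prev_stim)
    x2 <- sign(tc$delta_prev_report)
    e <- tc$error
    idx_by_p <- .participant_index(tc)
    b1 <- b2 <- numeric(n_iter)
    redrawn <- 0L
    for (b in seq_len(n_iter)) {
      for (try in 1:100) {
        k <- .stratified_sample(idx_by_p, frac)
        if (stats::var(x1[k]) > 0 && stats::var(x2[k]) > 0 &&
            abs(stats::cor(x1[k], x2[k])) < 1 - 1e-12) break
        redrawn <- redrawn + 1L
      }
      cf <- stats::.lm.fit(cbind(1, x1[k], x2[k]), e[k])$coefficients
      b1[b] <- cf[2]
      b2[b] <- cf[3]
    }
    if (redrawn > 0) message(cond, ": ", redrawn, " collinear resample(s) redrawn")
    diff <- b1 - b2
    list(condition = cond, n = nrow(tc), b1 = b1, b2 = b2,
         diff = diff, abs_diff = abs(b1) - abs(b2),
         summary = data.frame(
           condition = cond, n = nrow(tc),
           b1_median = stats::median(b1), b2_median = stats::median(b2),
           diff_median = stats::median(diff),
           diff_q025 = unname(stats::quantile(diff, 0.025)),
           diff_q975 = unname(stats::quantile(diff, 0.975)),
           p_diff_below_zero = mean(diff < 0)))
  })
  names(out) <- conds
  structure(out, class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  for (el in x) {
    if (is.null(el$summary)) {
      cat(el$condition, ": insufficient trials (n =", el$n, ")\n")
    } else {
      s <- el$summary
      cat(sprintf(
        "%s (n = %d): b1 median %+.3f, b2 median %+.3f, b1-b2 median %+.3f [%.3f, %.3f]\n",
        s$condition, s$n, s$b1_median, s$b2_median, s$diff_median,
        s$diff_q025, s$diff_q975))
    }
  }
  invisible(x)
}

#' Control-trial sanity checks
#'
#' Run on the *raw* trial table (before filtering). Two paired t tests on
#' per-participant mean absolute raw errors:
#' (i) early-terminating control trials that ended at the fifth stimulus
#' versus full-length non-control trials (attention to the whole
#' sequence), and (ii) rotation-break controls versus complete Rotational
#' trials (no precision gain from predictability). If the relevant control
#' trials are absent the corresponding test is marked not applicable.
#'
#' @param table a raw trial table (errors are computed internally if the
#'   `error` column is absent).
#' @param early_length sequence length defining "ended at the fifth
#'   stimulus" (default 5).
#' @return list of class `control_checks` with elements `early_fifth` and
#'   `rotation_break`, each either a [group_tests()] result or the string
#'   `"not applicable"`.
#' @export
control_checks <- function(table, early_length = 5L) {
  if (!"error" %in% names(table)) table <- compute_errors(table)
  ids <- sort(unique(table$participant))
  per_p <- function(sel) {
    vapply(ids, function(p) {
      e <- table$error[sel & table$participant == p]
      e <- e[is.finite(e)]
      if (length(e) == 0) NA_real_ else mean(abs(e))
    }, numeric(1))
  }
  full <- !table$is_early_control & !table$is_rotation_break_control

  early5 <- table$is_early_control & table$n_stimuli == early_length
  res_early <- if (!any(early5)) {
    "not applicable"
  } else {
    group_tests(per_p(early5), per_p(full))
  }

  brk <- table$is_rotation_break_control
  res_brk <- if (!any(brk)) {
    "not applicable"
  } else {
    group_tests(per_p(brk), per_p(full & table$condition == "Rotational"))
  }
  structure(list(early_fifth = res_early, rotation_break = res_brk),
            class = "control_checks")
}

#' @export
print.control_checks <- function(x, ...) {
  cat("Fifth-vs-sixth stimulus error magnitude: ")
  if (is.character(x$early_fifth)) cat(x$early_fifth, "\n") else print(x$early_fifth)
  cat("Rotation-break vs complete rotational:   ")
  if (is.character(x$rotation_break)) cat(x$rotation_break, "\n") else print(x$rotation_break)
  invisible(x)
}
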