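# Derivative-of-Gaussian (DoG) bias curve and its constrained least-squares
# fit. The curve is the standard model of serial-dependence bias profiles:
#
#   error(Delta) = Delta * alpha * w * c * exp(-(w * Delta)^2),
#
# with c = sqrt(2) / exp(-0.5). The constant c is chosen so that the curve
# attains its extremum exactly at |Delta| = 1/(sqrt(2) w) with value alpha:
# alpha is therefore both the amplitude parameter and the peak bias in
# degrees. alpha > 0 is attraction toward the previous orientation,
# alpha < 0 repulsion away from it.

#' @rdname dog
#' @export
dog_constant <- sqrt(2) / exp(-0.5)

#' Derivative-of-Gaussian bias curve
#'
#' Evaluates the odd, bell-lobed bias curve
#' `Delta * alpha * w * c * exp(-(w * Delta)^2)` with
#' `c = sqrt(2)/exp(-0.5)`. The peak lies at `Delta = 1/(sqrt(2) * w)` and
#' equals `alpha` exactly.
#'
#' @param delta signed orientation difference(s) in degrees.
#' @param alpha amplitude in degrees (equals the peak bias).
#' @param w inverse curve width, in 1/degrees; must be positive.
#' @return predicted error(s) in degrees.
#' @examples
#' w <- 1 / (23 * sqrt(2))
#' dog(23, alpha = 5.26, w = w)  # peak value = alpha
#' @export
dog <- function(delta, alpha, w) {
  if (any(w <= 0)) stop("`w` must be positive")
  delta * alpha * w * dog_constant * exp(-(w * delta)^2)
}

#' Peak location of the DoG curve
#' @param w inverse width in 1/degrees.
#' @return Delta (degrees) at which `|dog(delta, alpha, w)|` is maximal.
#' @export
dog_peak_delta <- function(w) 1 / (sqrt(2) * w)

.dog_sse <- function(par, d, e) {
  r <- e - dog(d, par[1], par[2])
  sum(r * r)
}

.dog_sse_grad <- function(par, d, e) {
  a <- par[1]; w <- par[2]
  E <- exp(-(w * d)^2)
  g <- d * a * w * dog_constant * E
  r <- e - g
  dga <- d * w * dog_constant * E
  dgw <- d * a * dog_constant * E * (1 - 2 * w^2 * d^2)
  c(-2 * sum(r * dga), -2 * sum(r * dgw))
}

# Exact profile over w: for fixed w the model is linear in alpha, so the
# optimal alpha has a closed form (clipped to its bounds). Scanning a log
# grid of w and refining the best bracket is fast and immune to the local
# minima that plague joint (alpha, w) descent, which makes it the workhorse
# for resampling loops.
.dog_profile_eval <- function(w_grid, d, e, alpha_bounds) {
  E <- exp(-(outer(d, w_grid))^2)
  G <- (d * dog_constant) * E * rep(w_grid, each = length(d))
  num <- colSums(e * G)
  den <- colSums(G * G)
  a <- ifelse(den > 0, num / den, 0)
  a <- pmin(pmax(a, alpha_bounds[1]), alpha_bounds[2])
  sse <- sum(e * e) - 2 * a * num + a * a * den
  list(alpha = a, sse = sse)
}

#' Fit the DoG bias curve by constrained least squares
#'
#' Minimises the sum of squared residuals of trial-level `(delta, error)`
#' pairs over the amplitude `alpha` and inverse width `w`, both box
#' constrained. Two equivalent strategies are available:
#' `"multistart"` runs L-BFGS-B with an analytic gradient from a fixed grid
#' of starting points; `"profile"` exploits that the model is linear in
#' `alpha` given `w`, scanning a log-spaced `w` grid with the closed-form
#' conditional amplitude and refining the best bracket by 1-D optimisation.
#' Both are deterministic.
#'
#' Rows with `delta == 0` (where the model is identically zero) or missing
#' values are dropped before fitting.
#'
#' @param delta signed orientation differences in degrees (the history
#'   predictor, previous minus present).
#' @param error adjustment errors in degrees, same length as `delta`.
#' @param alpha_bounds numeric(2), bounds for the amplitude in degrees.
#' @param w_bounds numeric(2), bounds for the inverse width in 1/degrees.
#'   The defaults put the peak location between roughly 3.5 and 141 degrees.
#' @param method `"multistart"` (default) or `"profile"`.
#' @param n_starts integer(2), starting-grid dimensions for `"multistart"`.
#' @param n_grid number of `w` grid points for `"profile"`.
#' @param min_n minimum number of usable observations; fewer is an error.
#' @return an object of class `dog_fit`: list with elements `alpha`, `w`,
#'   `sse`, `peak_delta`, `peak_bias`, `peak_percent`, `n_trials`,
#'   `converged`, `method`.
#' @seealso [peak_metrics()], [stratified_bootstrap_alpha()]
#' @examples
#' d <- rep(c(-60, -40, -20, 20, 40, 60), each = 10)
#' e <- dog(d, alpha = 3, w = 0.04)
#' fit_dog(d, e)
#' @export
fit_dog <- function(delta, error,
                    alpha_bounds = c(-30, 30),
                    w_bounds = c(0.005, 0.20),
                    method = c("multistart", "profile"),
                    n_starts = c(5, 5),
                    n_grid = 41,
                    min_n = 20) {
  method <- match.arg(method)
  keep <- is.finite(delta) & is.finite(error) & delta != 0
  d <- delta[keep]
  e <- error[keep]
  if (length(d) < min_n) {
    stop("fit_dog needs at least ", min_n, " usable (delta, error) pairs; got ",
         length(d))
  }

  if (method == "multistart") {
    a_starts <- seq(alpha_bounds[1], alpha_bounds[2], length.out = n_starts[1])
    w_starts <- exp(seq(log(w_bounds[1]), log(w_bounds[2]),
                        length.out = n_starts[2]))
    best <- NULL
    any_conv <- FALSE
    for (a0 in a_starts) {
      for (w0 in w_starts) {
        res <- tryCatch(
          stats::optim(c(a0, w0), .dog_sse, gr = .dog_sse_grad, d = d, e = e,
                       method = "L-BFGS-B",
                       lower = c(alpha_bounds[1], w_bounds[1]),
                       upper = c(alpha_bounds[2], w_bounds[2])),
          error = function(cnd) NULL)
        if (is.null(res)) next
        if (res$convergence == 0) any_conv <- TRUE
        if (is.null(best) || res$value < best$value) best <- res
      }
    }
    if (is.null(best)) {
      # every start failed; fall through to the profile strategy
      return(fit_dog(delta, error, alpha_bounds, w_bounds,
                     method = "profile", n_grid = n_grid, min_n = min_n))
    }
    alpha <- best$par[1]; w <- best$par[2]; sse <- best$value
    converged <- any_conv
  } else {
    w_grid <- exp(seq(log(w_bounds[1]), log(w_bounds[2]), length.out = n_grid))
    prof <- .dog_profile_eval(w_grid, d, e, alpha_bounds)
    i <- which.min(prof$sse)
    lo <- w_grid[max(i - 1L, 1L)]
    hi <- w_grid[min(i + 1L, length(w_grid))]
    f1 <- function(w) .dog_profile_eval(w, d, e, alpha_bounds)$sse
    opt <- stats::optimize(f1, lower = lo, upper = hi, tol = 1e-8)
    if (opt$objective <= prof$sse[i]) {
      w <- opt$minimum
      sse <- opt$objective
    } else {
      w <- w_grid[i]
      sse <- prof$sse[i]
    }
    alpha <- .dog_profile_eval(w, d, e, alpha_bounds)$alpha
    converged <- TRUE
  }

  structure(
    list(alpha = alpha,
         w = w,
         sse = sse,
         peak_delta = dog_peak_delta(w),
         peak_bias = alpha,
         peak_percent = 100 * abs(alpha) / dog_peak_delta(w),
         n_trials = length(d),
         converged = converged,
         method = method),
    class = "dog_fit")
}

#' Peak metrics of a fitted DoG curve
#'
#' The maximal predicted deviation of errors from zero (the peak bias, equal
#' to the fitted amplitude), the Delta at which it occurs
#' (`1/(sqrt(2) * w)`), and the peak expressed as a percentage of that
#' Delta, i.e. `100 * |peak_bias| / peak_delta`.
#'
#' @param fit a `dog_fit` object.
#' @return list with `peak_bias` (degrees, signed), `peak_delta` (degrees),
#'   `peak_percent`.
#' @examples
#' d <- rep(c(-40, -20, 20, 40), each = 10)
#' peak_metrics(fit_dog(d, dog(d, 1.24, 1 / (28.3 * sqrt(2)))))
#' @export
peak_metrics <- function(fit) {
  stopifnot(inherits(fit, "dog_fit"))
  list(peak_bias = fit$peak_bias,
       peak_delta = fit$peak_delta,
       peak_percent = fit$peak_percent)
}

#' @export
print.dog_fit <- function(x, ...) {
  cat("DoG fit (", x$method, ", n = ", x$n_trials, ")\n", sep = "")
  cat(sprintf("  alpha = %+.3f deg   w = %.5f /deg   sse = %.2f\n",
              x$alpha, x$w, x$sse))
  cat(sprintf("  peak bias %+.3f deg at Delta = %.1f deg (%.1f%%)\n",
              x$peak_bias, x$peak_delta, x$peak_percent))
  if (!x$converged) cat("  (optimiser did not report convergence)\n")
  invisible(x)
}
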