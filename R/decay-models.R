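# Decay-curve models for newborn cell populations.
#
# Longitudinal decay (one age, 2 d -> 30 d of cell life) is modelled as an
# exponential approach to a survival plateau,
#   Y(t) = plateau + (Y0 - plateau) * exp(-K * (t - anchor)),
# anchored at the 2 d peak. Transversal decay (across animal ages) is a
# pure exponential Y(x) = Y0 * exp(-k * x). Both are least-squares fits;
# the linear parameters are profiled out (variable projection) so only the
# rate constant is searched, which is robust on 3-5 point datasets where
# generic nonlinear optimizers stall.

.fit_rate_profiled <- function(t, y, basis, k_grid, interval_pad = 2) {
  # basis(k) must return the design matrix; returns list(k, coef, rss).
  rss_of <- function(k) .profiled_ls(basis(k), y)$rss
  grid_rss <- vapply(k_grid, rss_of, numeric(1))
  i <- which.min(grid_rss)
  lo <- k_grid[max(1L, i - 1L)]
  hi <- k_grid[min(length(k_grid), i + 1L)]
  if (lo == hi) {
    k <- lo
  } else {
    k <- stats::optimize(rss_of, lower = lo, upper = hi,
                         tol = 1e-12 * max(1, hi))$minimum
    # one refinement pass tightens the bracket around the optimum
    w <- (hi - lo) / 10
    k <- stats::optimize(rss_of, lower = max(lo, k - w), upper = min(hi, k + w),
                         tol = 1e-13 * max(1, hi))$minimum
  }
  # boundary grid points (e.g. K = 0 on flat data) can beat the interior
  if (grid_rss[i] < rss_of(k)) k <- k_grid[i]
  sol <- .profiled_ls(basis(k), y)
  list(k = k, coef = sol$coef, rss = sol$rss)
}

# Non-negative least squares on at most two columns, by enumeration of the
# active sets (adequate for this model family).
.profiled_ls <- function(X, y) {
  p <- ncol(X)
  best <- NULL
  consider <- function(coef) {
    if (anyNA(coef) || any(!is.finite(coef)) || any(coef < -1e-12)) return()
    coef <- pmax(coef, 0)
    r <- y - X %*% coef
    rss <- sum(r^2)
    if (is.null(best) || rss < best$rss) best <<- list(coef = coef, rss = rss)
  }
  full <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
  if (!is.null(full) && !anyNA(full)) consider(full)
  for (j in seq_len(p)) {
    cj <- sum(X[, j] * y) / sum(X[, j]^2)
    coef <- numeric(p)
    coef[j] <- cj
    consider(coef)
  }
  consider(numeric(p))
  best
}

.check_points <- function(points, min_n, t_col = "t", v_col = "value") {
  if (!all(c(t_col, v_col) %in% names(points))) {
    stop(sprintf("`points` needs columns `%s` and `%s`", t_col, v_col),
         call. = FALSE)
  }
  points <- points[stats::complete.cases(points[c(t_col, v_col)]), ]
  if (nrow(points) < min_n) {
    stop(sprintf("need at least %d points, got %d", min_n, nrow(points)),
         call. = FALSE)
  }
  if (any(points[[v_col]] < 0)) stop("values must be >= 0", call. = FALSE)
  points
}

.aicc <- function(rss, n, n_params) {
  kp <- n_params + 1  # GraphPad convention: the error variance counts
  if (n - kp - 1 <= 0) return(NA_real_)
  n * log(max(rss, 1e-300) / n) + 2 * kp + 2 * kp * (kp + 1) / (n - kp - 1)
}

.new_decay_fit <- function(model, params, rss, t, y, fitted, anchor_t, flat) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) ifelse(rss <= 1e-12, 1, 0) else 1 - rss / tss
  k <- params[["K"]]
  structure(list(
    model = model,
    params = params,
    half_life = if (k > 0) log(2) / k else Inf,
    plateau_pct = if (model == "plateau_decay") {
      if (params[["Y0"]] > 0) params[["plateau"]] / params[["Y0"]] * 100 else NA_real_
    } else NA_real_,
    r_squared = r2,
    aicc = .aicc(rss, n, length(params)),
    rss = rss,
    n_points = n,
    flat = flat,
    data = tibble::tibble(t = t, value = y, fitted = fitted,
                          residual = y - fitted),
    data_mode = if (anyDuplicated(t) > 0) "per_animal" else "group_means",
    anchor_t = anchor_t
  ), class = "decay_fit")
}

#' Fit a longitudinal exponential decay with survival plateau
#'
#' Least-squares fit of
#' `Y(t) = plateau + (Y0 - plateau) * exp(-K * (t - anchor_t))`
#' to BrdU+ counts over the chase time course, anchored at the 2 d peak
#' (the 2 h expansion-phase point is not part of the decay and should be
#' excluded by the caller). Constraints `K > 0`, `0 <= plateau <= Y0` are
#' enforced. Reported alongside the parameters: half-life `log(2)/K`, the
#' survival plateau as a percent of the fitted 2 d peak `Y0`, R-squared,
#' and AICc (NA when the small-sample correction is undefined).
#'
#' @param points Data frame with columns `t` (days, all `>= anchor_t`) and
#'   `value` (counts or percentages, `>= 0`); per-animal rows or group
#'   means (recorded as `data_mode`).
#' @param anchor_t Anchor time in days, default 2 (the peak).
#' @return A `decay_fit` object; see [tidy.decay_fit()], [glance.decay_fit()].
#' @examples
#' pts <- tibble::tibble(t = c(2, 4, 10, 30),
#'                       value = 10 + 90 * exp(-0.5 * (c(2, 4, 10, 30) - 2)))
#' fit_plateau_decay(pts)
#' @export
fit_plateau_decay <- function(points, anchor_t = 2) {
  points <- .check_points(points, min_n = 4)
  if (any(points$t < anchor_t)) {
    stop("all `t` must be >= `anchor_t` (the decay is anchored at the peak)",
         call. = FALSE)
  }
  t <- points$t
  y <- points$value
  basis <- function(k) cbind(plateau = rep(1, length(t)),
                             amp = exp(-k * (t - anchor_t)))
  k_grid <- exp(seq(log(1e-4), log(25), length.out = 80))
  sol <- .fit_rate_profiled(t, y, basis, k_grid)
  plateau <- sol$coef[[1]]
  amp <- sol$coef[[2]]
  params <- c(Y0 = plateau + amp, K = sol$k, plateau = plateau)
  fitted <- as.numeric(basis(sol$k) %*% sol$coef)
  .new_decay_fit("plateau_decay", params, sol$rss, t, y, fitted, anchor_t,
                 flat = amp == 0)
}

#' Fit a pure exponential decay
#'
#' Least-squares fit of `Y(x) = Y0 * exp(-K * x)`, used for the transversal
#' decline of a population across animal ages (x in days; convert months
#' with [age_to_days()]). Flat data (no decline) yield `K = 0`, an
#' infinite half-life, and `flat = TRUE`.
#'
#' @param points Data frame with columns `t` (days) and `value` (`>= 0`).
#' @return A `decay_fit` object.
#' @export
fit_exponential_decay <- function(points) {
  points <- .check_points(points, min_n = 3)
  t <- points$t
  y <- points$value
  basis <- function(k) cbind(Y0 = exp(-k * t))
  # absolute grid down to 0 so flat data can select K = 0 exactly
  k_grid <- c(0, exp(seq(log(1e-7), log(25), length.out = 90)))
  sol <- .fit_rate_profiled(t, y, basis, k_grid)
  params <- c(Y0 = sol$coef[[1]], K = sol$k)
  fitted <- as.numeric(basis(sol$k) %*% sol$coef)
  .new_decay_fit("pure_exponential", params, sol$rss, t, y, fitted,
                 anchor_t = 0, flat = sol$k <= 1e-10)
}

#' Predicted values from a decay fit
#'
#' @param object A `decay_fit`.
#' @param t Times (days) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.decay_fit <- function(object, t, ...) {
  p <- object$params
  if (object$model == "plateau_decay") {
    p[["plateau"]] + (p[["Y0"]] - p[["plateau"]]) *
      exp(-p[["K"]] * (t - object$anchor_t))
  } else {
    p[["Y0"]] * exp(-p[["K"]] * t)
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  lab <- c(plateau_decay = "exponential decay with plateau",
           pure_exponential = "exponential decay")[[x$model]]
  cat(sprintf("<decay_fit> %s (n = %d, %s)\n", lab, x$n_points, x$data_mode))
  cat("  ", paste(sprintf("%s = %.6g", names(x$params), x$params),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  half-life = %.4g d%s, R^2 = %.4f, AICc = %s\n",
              x$half_life,
              if (!is.na(x$plateau_pct))
                sprintf(", plateau = %.3g%% of Y0", x$plateau_pct) else "",
              x$r_squared,
              if (is.na(x$aicc)) "NA" else sprintf("%.2f", x$aicc)))
  invisible(x)
}

#' Rank decay fits of the same data by small-sample-corrected AICc
#'
#' `AICc = n * log(RSS / n) + 2 K' + 2 K' (K' + 1) / (n - K' - 1)` with
#' `K'` the number of free parameters plus one (the error variance). The
#' lowest AICc wins; exact ties go to the model with fewer parameters.
#' Only differences are meaningful, so `delta_aicc` against the best model
#' is reported.
#'
#' @param fits List of `decay_fit` objects fitted to identical data.
#' @return Tibble ranked by AICc: `model`, `n_params`, `rss`, `aicc`,
#'   `delta_aicc`, `rank`, `preferred`.
#' @export
compare_aicc <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "decay_fit")))
  ys <- lapply(fits, function(f) sort(f$data$value))
  if (!all(vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])), TRUE))) {
    stop("AICc is only comparable across fits of identical data",
         call. = FALSE)
  }
  n <- fits[[1]]$n_points
  kp <- vapply(fits, function(f) length(f$params), numeric(1)) + 1
  if (any(n - kp - 1 <= 0)) {
    stop(sprintf(
      "AICc correction undefined: n = %d points with %d free parameter(s)",
      n, max(kp) - 1), call. = FALSE)
  }
  out <- tibble::tibble(
    model = vapply(fits, function(f) f$model, character(1)),
    n_params = kp - 1,
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  out$delta_aicc <- out$aicc - min(out$aicc)
  ord <- order(out$aicc, out$n_params)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$preferred <- out$rank == 1
  out
}

#' Ordinary least-squares regression with F-test
#'
#' Simple linear regression used for the progenitor-to-progeny
#' correlations (simulated 30 d neurons or astrocytes against 2 h
#' proliferating progenitors).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must vary.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`
#'   (overall F-test), `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete points", call. = FALSE)
  if (stats::var(x) == 0) stop("`x` has zero variance", call. = FALSE)
  if (stats::var(y) == 0) {
    # a constant response carries no explainable variance
    return(tibble::tibble(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) 1 else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = p,
    n = length(x)
  )
}

#' Validate a fitted decay curve against independent timepoint means
#'
#' Computes residuals between independent observed means and the curve's
#' predictions at the same timepoints, then runs a two-tailed one-sample
#' t-test of the residuals against zero. Residuals that all vanish (within
#' 1e-9) give p = 1 by convention. The independent data must be on the
#' same scale as the fitted curve (e.g. both normalized to the 2 d peak).
#'
#' @param fit A `decay_fit`.
#' @param independent_means Data frame with columns `t` (days) and `value`
#'   (mean at each timepoint); at least 3 timepoints.
#' @return One-row tibble: `p_value`, `mean_residual`, `n`; per-timepoint
#'   residual table in attribute `"residuals"`.
#' @export
validate_against_curve <- function(fit, independent_means) {
  stopifnot(inherits(fit, "decay_fit"))
  pts <- .check_points(independent_means, min_n = 3)
  res <- tibble::tibble(
    t = pts$t,
    observed = pts$value,
    predicted = predict(fit, pts$t)
  )
  res$residual <- res$observed - res$predicted
  if (all(abs(res$residual) < 1e-9)) {
    out <- tibble::tibble(p_value = 1, mean_residual = 0, n = nrow(res))
  } else if (stats::sd(res$residual) == 0) {
    # identical nonzero offsets: no within-sample spread, call it discordant
    out <- tibble::tibble(p_value = 0, mean_residual = mean(res$residual),
                          n = nrow(res))
  } else {
    tt <- stats::t.test(res$residual, mu = 0)
    out <- tibble::tibble(p_value = tt$p.value,
                          mean_residual = mean(res$residual), n = nrow(res))
  }
  attr(out, "residuals") <- res
  out
}

#' Piecewise exponential fit split at a candidate age
#'
#' Fits independent pure exponential decays to the points strictly below
#' and at-or-above `split_age`. Used for populations whose decline changes
#' regime at a maturation benchmark (e.g. human neuroblast density around
#' 2 years of age).
#'
#' @param points Data frame with columns `t` (age, any consistent unit)
#'   and `value`.
#' @param split_age Split location, same unit as `t`.
#' @return List of class `split_decay_fit`: `young` and `old` `decay_fit`s
#'   plus `split_age` and the combined `rss`.
#' @export
split_age_fit <- function(points, split_age) {
  points <- .check_points(points, min_n = 6)
  young <- points[points$t < split_age, ]
  old <- points[points$t >= split_age, ]
  if (nrow(young) < 3) {
    stop(sprintf("insufficient points below split (%d < 3)", nrow(young)),
         call. = FALSE)
  }
  if (nrow(old) < 3) {
    stop(sprintf("insufficient points at or above split (%d < 3)", nrow(old)),
         call. = FALSE)
  }
  fy <- fit_exponential_decay(young)
  fo <- fit_exponential_decay(old)
  structure(list(young = fy, old = fo, split_age = split_age,
                 rss = fy$rss + fo$rss),
            class = "split_decay_fit")
}

#' @export
print.split_decay_fit <- function(x, ...) {
  cat(sprintf("<split_decay_fit> split at %g\n", x$split_age))
  cat(sprintf("  young: half-life %.4g, R^2 %.4f (n = %d)\n",
              x$young$half_life, x$young$r_squared, x$young$n_points))
  cat(sprintf("  old:   half-life %.4g, R^2 %.4f (n = %d)\n",
              x$old$half_life, x$old$r_squared, x$old$n_points))
  invisible(x)
}
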