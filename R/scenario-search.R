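# Extra-survival scenarios: decompose the 30 d net survival of a mature
# age into the baseline predicted by the young (reference) survival and
# differentiation pattern plus an "extra" component, then search for the
# neuron:astrocyte allocation of that extra which reproduces a target
# neuron-to-astrocyte ratio.

#' Decompose a mature age's 30 d survival into baseline plus extra
#'
#' Applies the reference age's net survival fraction (30 d mean over 2 d
#' mean) to the mature age's 2 d peak to get the baseline 30 d survivors,
#' splits that baseline into neurons and astrocytes with the reference
#' marker fractions, and calls whatever the mature age's observed 30 d
#' count adds on top of it the extra net survival (any sign).
#'
#' The 2 d peak anchors the baseline because the longitudinal survival
#' fractions are expressed relative to it.
#'
#' @param summaries Group-summary tibble with `total` rows at 2d and 30d
#'   for both ages.
#' @param fractions Marker-fraction summary tibble with the reference
#'   age's 30 d NeuN and GFAP fractions ([summarize_fractions()]).
#' @param age Mature age (months) to decompose.
#' @param reference_age Reference age, default 1 month.
#' @return One-row tibble of class basis for the search:
#'   `age_months`, `reference_age`, `baseline_total`, `baseline_neurons`,
#'   `baseline_astrocytes`, `extra`, `observed_30d`.
#' @export
decompose_survival <- function(summaries, fractions, age, reference_age = 1) {
  get_mean <- function(a, tp) {
    row <- summaries |>
      dplyr::filter(.data$age_months == a, .data$marker == "total",
                    .data$timepoint == tp)
    if (nrow(row) != 1) {
      stop(sprintf("missing `total` %s summary for age %g m", tp, a),
           call. = FALSE)
    }
    row$mean
  }
  n2d_a <- get_mean(age, "2d")
  n30_a <- get_mean(age, "30d")
  n2d_r <- get_mean(reference_age, "2d")
  n30_r <- get_mean(reference_age, "30d")
  if (n2d_r <= 0) {
    stop("reference 2d mean must be > 0 to define a survival fraction",
         call. = FALSE)
  }
  frac <- function(marker) .age_fraction(fractions, reference_age, marker)$mean
  baseline_total <- n2d_a * (n30_r / n2d_r)
  tibble::tibble(
    age_months = age,
    reference_age = reference_age,
    baseline_total = baseline_total,
    baseline_neurons = baseline_total * frac("NeuN"),
    baseline_astrocytes = baseline_total * frac("GFAP"),
    extra = n30_a - baseline_total,
    observed_30d = n30_a
  )
}

#' Neuron-to-astrocyte ratio under an extra-survival allocation
#'
#' With a fraction `p_neuron` of the extra survival assigned to neurons
#' (the remainder to astrocytes), the achieved ratio is
#' `(baseline_neurons + p * extra) / (baseline_astrocytes + (1 - p) * extra)`.
#' `p_neuron` may lie outside `[0, 1]`: negative values describe scenarios
#' where even the baseline neuron production is undercut in favour of
#' astrocytes. A non-positive astrocyte total leaves the ratio `NA`.
#'
#' @param dec One-row decomposition tibble from [decompose_survival()]
#'   (or any data frame with `baseline_neurons`, `baseline_astrocytes`,
#'   `extra`).
#' @param p_neuron Neuron share(s) of the extra survival.
#' @return Numeric vector of achieved ratios.
#' @export
scenario_ratio <- function(dec, p_neuron) {
  num <- dec$baseline_neurons + p_neuron * dec$extra
  den <- dec$baseline_astrocytes + (1 - p_neuron) * dec$extra
  ifelse(den > 0, num / den, NA_real_)
}

# closed-form allocation: solve (N_b + p E) / (A_b + (1 - p) E) = R for p
.allocation_closed_form <- function(dec, target_ratio) {
  (target_ratio * (dec$baseline_astrocytes + dec$extra) - dec$baseline_neurons) /
    (dec$extra * (1 + target_ratio))
}

#' Iterative midpoint search for the extra-survival allocation
#'
#' Finds the neuron share `p` of the extra net survival whose scenario
#' ratio matches a target neuron-to-astrocyte ratio, by repeated interval
#' halving: starting from the scenario pair p = 0.5 and p = 0.0, the
#' midpoint scenario is computed and compared against the better endpoint,
#' iterating until the achieved ratio is within `tolerance` of the target.
#' When the target is not enclosed by the initial pair, the bracket grows
#' in steps of 0.25 up to `[-1, 2]` — allocations outside `[0, 1]`
#' (including negative neuron shares) are legitimate solutions. The
#' bisection result is always cross-checked against the closed form
#' `p* = (R (A_b + E) - N_b) / (E (1 + R))`; disagreement beyond tolerance
#' is an internal error.
#'
#' @param dec One-row decomposition from [decompose_survival()]; `extra`
#'   must be nonzero.
#' @param target_ratio Target neuron-to-astrocyte ratio (>= 0), e.g. from
#'   [yields_by_age()] or [yields_from_simulation()].
#' @param tolerance Convergence tolerance on the achieved ratio.
#' @param max_iter Iteration cap.
#' @param source Optional label recording where the target came from
#'   (e.g. `"experimental"`, `"marsaglia"`).
#' @return One-row tibble: `age_months`, `p_neuron`, `achieved_ratio`,
#'   `target_ratio`, `iterations`, `converged`, `source`; the search trace
#'   (tibble of `p`, `ratio` per iteration) in attribute `"trace"`.
#' @export
find_allocation <- function(dec, target_ratio, tolerance = 1e-6,
                            max_iter = 200, source = NA_character_) {
  if (nrow(dec) != 1) stop("`dec` must be a single decomposition",
                           call. = FALSE)
  if (is.na(target_ratio) || target_ratio < 0) {
    stop("`target_ratio` must be >= 0", call. = FALSE)
  }
  if (dec$extra == 0) {
    br <- with(dec, ifelse(baseline_astrocytes > 0,
                           baseline_neurons / baseline_astrocytes, NA_real_))
    if (!is.na(br) && abs(br - target_ratio) <= tolerance) {
      out <- tibble::tibble(
        age_months = dec$age_months, p_neuron = NA_real_,
        achieved_ratio = br, target_ratio = target_ratio,
        iterations = 0L, converged = TRUE, source = source
      )
      attr(out, "trace") <- tibble::tibble(p = numeric(), ratio = numeric())
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    stop("extra survival is zero: every allocation gives the baseline ratio",
         call. = FALSE)
  }

  g <- function(p) scenario_ratio(dec, p) - target_ratio
  # the astrocyte total vanishes at the pole p = 1 + A_b / E; the ratio is
  # only meaningful on the side of the pole with a positive denominator,
  # where it diverges as the pole is approached — so clamping the bracket
  # just inside the pole keeps every attainable target enclosed
  pole <- 1 + dec$baseline_astrocytes / dec$extra
  if (dec$extra > 0) {
    lo_bound <- -1
    hi_bound <- min(2, pole - 1e-9)
  } else {
    lo_bound <- max(-1, pole + 1e-9)
    hi_bound <- 2
  }
  if (lo_bound >= hi_bound) {
    stop(sprintf("no allocation in [-1, 2] keeps the astrocyte total positive (pole at p = %.4g)",
                 pole), call. = FALSE)
  }
  # bracket: start from the scenario pair {0.5, 0.0}, expand by 0.25 steps
  lo <- max(0, lo_bound)
  hi <- min(0.5, hi_bound)
  if (lo >= hi) {
    lo <- lo_bound
    hi <- hi_bound
  }
  repeat {
    if (!is.na(g(lo)) && !is.na(g(hi)) && g(lo) * g(hi) <= 0) break
    if (lo <= lo_bound && hi >= hi_bound) {
      stop(sprintf(
        "target ratio %.4g not attainable for p in [%.4g, %.4g] (achieved range [%.4g, %.4g])",
        target_ratio, lo_bound, hi_bound,
        min(g(lo), g(hi)) + target_ratio,
        max(g(lo), g(hi)) + target_ratio), call. = FALSE)
    }
    lo <- max(lo_bound, lo - 0.25)
    hi <- min(hi_bound, hi + 0.25)
  }
  ps <- c(lo, hi)
  trace <- tibble::tibble(p = ps, ratio = scenario_ratio(dec, ps))
  converged <- FALSE
  mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- scenario_ratio(dec, mid)
    trace <- dplyr::bind_rows(trace, tibble::tibble(p = mid, ratio = r_mid))
    if (abs(r_mid - target_ratio) <= tolerance && (hi - lo) <= tolerance) {
      converged <- TRUE
      break
    }
    if (g(lo) * (r_mid - target_ratio) <= 0) hi <- mid else lo <- mid
  }
  p_star <- .allocation_closed_form(dec, target_ratio)
  if (converged && abs(mid - p_star) > 10 * tolerance) {
    stop(sprintf(
      "internal error: bisection allocation %.8g disagrees with closed form %.8g",
      mid, p_star), call. = FALSE)
  }
  out <- tibble::tibble(
    age_months = dec$age_months,
    p_neuron = mid,
    achieved_ratio = scenario_ratio(dec, mid),
    target_ratio = target_ratio,
    iterations = it,
    converged = converged,
    source = source
  )
  attr(out, "trace") <- trace
  out
}

#' Fixed neuron:astrocyte scenarios for an extra-survival decomposition
#'
#' Evaluates the canonical 100:0, 50:50 and 0:100 neuron:astrocyte
#' allocations (plus any additional `p` values) of the extra survival.
#'
#' @param dec One-row decomposition from [decompose_survival()].
#' @param p_neuron Allocations to evaluate, default `c(1, 0.5, 0)`.
#' @return Tibble: `age_months`, `scenario`, `p_neuron`, `ratio`.
#' @export
scenario_table <- function(dec, p_neuron = c(1, 0.5, 0)) {
  tibble::tibble(
    age_months = dec$age_months,
    scenario = sprintf("%.0fN:%.0fA", 100 * p_neuron, 100 * (1 - p_neuron)),
    p_neuron = p_neuron,
    ratio = scenario_ratio(dec, p_neuron)
  )
}
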