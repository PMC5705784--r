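# Constrained Monte-Carlo simulation of nested BrdU+ cohorts.
#
# Each replicate is a virtual animal: a nested vector of BrdU+ counts at
# 2 h, 2 d, 4 d, 10 d and 30 d plus a 30 d split into newborn astrocytes
# (GFAP+) and neurons (NeuN+). Draws come from the Marsaglia polar stream
# with the experimentally estimated group mean and SD at each timepoint,
# subject to the biological ordering restrictions
#   2h <= 2d >= 4d >= 10d >= 30d >= (GFAP + NeuN),
# with GFAP + NeuN = 30d exactly under either locked strategy.

.sim_timepoints <- c("2h", "2d", "4d", "10d", "30d")

sim_strategies <- c("gfap-locked", "neun-locked")

# means/sds for marker "total" at the five timepoints of one age, as a
# named list; errors if any row is missing.
.age_moments <- function(summaries, age) {
  rows <- summaries |>
    dplyr::filter(.data$age_months == age, .data$marker == "total",
                  .data$timepoint %in% .sim_timepoints)
  miss <- setdiff(.sim_timepoints, rows$timepoint)
  if (length(miss) > 0) {
    stop(sprintf("missing `total` summary row(s) for age %g m: %s",
                 age, paste(miss, collapse = ", ")), call. = FALSE)
  }
  list(mean = stats::setNames(rows$mean, rows$timepoint)[.sim_timepoints],
       sd = stats::setNames(rows$sd, rows$timepoint)[.sim_timepoints])
}

.age_fraction <- function(fractions, age, marker) {
  row <- fractions |>
    dplyr::filter(.data$age_months == age, .data$marker == !!marker)
  if (nrow(row) != 1) {
    stop(sprintf("missing 30d %s fraction summary for age %g m", marker, age),
         call. = FALSE)
  }
  row
}

#' Simulate constraint-satisfying pseudorandom BrdU+ cohorts
#'
#' Generates `n_replicates` nested pseudo-animal records per age from group
#' summaries (mean, SD per timepoint) and 30 d marker-fraction summaries.
#' Constraint enforcement is sequential forward rejection: the 2 h count is
#' drawn truncated at zero; the 2 d count is redrawn until it is at least
#' the 2 h count; each later timepoint is redrawn until it is between zero
#' and its predecessor; the locked marker's fraction is redrawn until it
#' lies in `[0, 1]`. Under `"gfap-locked"` the GFAP fraction is drawn from
#' its normal law, newborn astrocytes are `fraction * n30d`, and newborn
#' neurons are the 30 d remainder; `"neun-locked"` is the mirror image. An
#' alternative `mode = "joint"` redraws whole unconstrained vectors until
#' the full ordering holds, for sensitivity analysis.
#'
#' Counts stay real-valued inside the simulation (populations of
#' magnitudes); rounding, if wanted, is a display concern.
#'
#' @param summaries Group-summary tibble (`marker == "total"` rows at all
#'   five timepoints for every age), e.g. from [summarize_counts()].
#' @param fractions 30 d marker-fraction summary tibble
#'   (`age_months`, `marker`, `mean`, `sd`), e.g. from
#'   [summarize_fractions()].
#' @param n_replicates Virtual animals per age (default 1000).
#' @param strategy `"gfap-locked"` (default) or `"neun-locked"`.
#' @param seed Master integer seed; each age uses its own substream.
#' @param mode Constraint enforcement: `"sequential"` (default) or
#'   `"joint"`.
#' @param max_tries Redraw cap per constrained quantity (or per vector in
#'   joint mode) before an error naming the age and timepoint.
#' @return Tibble with one row per replicate: `age_months`, `replicate`,
#'   `strategy`, `n2h`, `n2d`, `n4d`, `n10d`, `n30d`, `n_gfap`, `n_neun`.
#' @examples
#' ds <- generate_dataset(default_truths(), n_per_group = 8, seed = 7)
#' sims <- simulate_cohort(summarize_counts(ds$observations),
#'                         summarize_fractions(ds$observations),
#'                         n_replicates = 100, seed = 7)
#' @export
simulate_cohort <- function(summaries, fractions, n_replicates = 1000,
                            strategy = c("gfap-locked", "neun-locked"),
                            seed = 1, mode = c("sequential", "joint"),
                            max_tries = 1e5) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1.", call. = FALSE)
  locked_marker <- if (strategy == "gfap-locked") "GFAP" else "NeuN"
  ages <- sort(unique(summaries$age_months))
  if (length(ages) == 0) stop("no ages in `summaries`", call. = FALSE)

  purrr::map_dfr(ages, function(age) {
    mom <- .age_moments(summaries, age)
    if (!(mom$mean[["2h"]] <= mom$mean[["2d"]] &&
          all(diff(mom$mean[c("2d", "4d", "10d", "30d")]) <= 0))) {
      warning(sprintf(
        "experimental means at %g m violate the nested ordering; %s",
        age, "rejection will pull draws toward feasibility"), call. = FALSE)
    }
    fr <- .age_fraction(fractions, age, locked_marker)
    rng <- cascade_rng(derive_seed(seed, "cohort", age, strategy, mode))
    draw_seq <- function() {
      n2h <- rng_truncnorm(rng, mom$mean[["2h"]], mom$sd[["2h"]], lower = 0,
                           what = sprintf("2h at %g m", age))
      n2d <- rng_truncnorm(rng, mom$mean[["2d"]], mom$sd[["2d"]], lower = n2h,
                           what = sprintf("2d at %g m", age))
      prev <- n2d
      out <- c("2h" = n2h, "2d" = n2d)
      for (tp in c("4d", "10d", "30d")) {
        # a tight gate here keeps rejection runs short; a dead end is
        # recovered by restarting the whole vector in draw_vec()
        val <- rng_truncnorm(rng, mom$mean[[tp]], mom$sd[[tp]],
                             lower = 0, upper = prev,
                             what = sprintf("%s at %g m", tp, age),
                             min_mass = 1e-3)
        out[[tp]] <- val
        prev <- val
      }
      out
    }
    draw_vec <- function() {
      if (mode == "sequential") {
        # a low early draw can leave a later timepoint with essentially no
        # feasible mass (means close to ties); restart the vector and only
        # give up when every restart dead-ends
        last <- NULL
        for (i in seq_len(500L)) {
          v <- tryCatch(draw_seq(), error = function(e) e)
          if (!inherits(v, "error")) return(v)
          last <- v
        }
        stop(conditionMessage(last), call. = FALSE)
      } else {
        for (i in seq_len(max_tries)) {
          v <- vapply(.sim_timepoints, function(tp)
            rng_normal(rng, mom$mean[[tp]], mom$sd[[tp]]), numeric(1))
          if (v[["2h"]] >= 0 && v[["2h"]] <= v[["2d"]] &&
              all(diff(v[c("2d", "4d", "10d", "30d")]) <= 0) &&
              v[["30d"]] >= 0) {
            return(v)
          }
        }
        stop(sprintf("joint redraw cap reached at age %g m", age),
             call. = FALSE)
      }
    }
    draw_frac <- function() {
      rng_truncnorm(rng, fr$mean, fr$sd, lower = 0, upper = 1,
                    what = sprintf("30d %s fraction at %g m", locked_marker, age))
    }
    m <- matrix(NA_real_, nrow = n_replicates, ncol = 7)
    for (r in seq_len(n_replicates)) {
      v <- draw_vec()
      f <- draw_frac()
      locked <- f * v[["30d"]]
      m[r, ] <- c(v, locked, v[["30d"]] - locked)
    }
    gfap_locked <- strategy == "gfap-locked"
    tibble::tibble(
      age_months = age, replicate = seq_len(n_replicates),
      strategy = strategy,
      n2h = m[, 1], n2d = m[, 2], n4d = m[, 3], n10d = m[, 4], n30d = m[, 5],
      n_gfap = if (gfap_locked) m[, 6] else m[, 7],
      n_neun = if (gfap_locked) m[, 7] else m[, 6]
    )
  })
}

#' Percent deviation of simulated populations from experimental summaries
#'
#' Scores a simulated cohort against experimental group summaries as the
#' mean, over all (age x population) cells, of the absolute relative
#' difference between the simulated and experimental means, in percent.
#' Populations are the five timepoint totals plus the 30 d NeuN and GFAP
#' counts (when marker count summaries are present). Cells whose
#' experimental mean is zero are excluded with a warning.
#'
#' @param records Simulated cohort tibble from [simulate_cohort()].
#' @param summaries Group-summary tibble (counts; marker rows `NeuN` and
#'   `GFAP` at 30 d are used when available).
#' @return One-row tibble: `deviation_pct`, `n_cells`, `n_excluded`, with
#'   the per-cell table in attribute `"by_cell"`.
#' @export
deviation_from_experiment <- function(records, summaries) {
  sim <- records |>
    dplyr::group_by(.data$age_months) |>
    dplyr::summarise(dplyr::across(c("n2h", "n2d", "n4d", "n10d", "n30d",
                                     "n_gfap", "n_neun"), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"age_months", names_to = "population",
                        values_to = "simulated")
  exp_tot <- summaries |>
    dplyr::filter(.data$marker == "total",
                  .data$timepoint %in% .sim_timepoints) |>
    dplyr::mutate(population = paste0("n", .data$timepoint))
  exp_mk <- summaries |>
    dplyr::filter(.data$marker %in% c("NeuN", "GFAP"), .data$timepoint == "30d") |>
    dplyr::mutate(population = dplyr::if_else(.data$marker == "NeuN",
                                              "n_neun", "n_gfap"))
  expd <- dplyr::bind_rows(exp_tot, exp_mk) |>
    dplyr::select("age_months", "population", experimental = "mean")
  cells <- dplyr::inner_join(sim, expd, by = c("age_months", "population"))
  if (nrow(cells) == 0) {
    stop("records and summaries share no (age, population) cells",
         call. = FALSE)
  }
  if (!setequal(unique(cells$age_months), unique(records$age_months))) {
    stop("records and summaries do not cover the same ages", call. = FALSE)
  }
  zero <- cells$experimental == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with experimental mean 0 excluded from ",
            "the deviation", call. = FALSE)
  }
  used <- cells[!zero, ]
  used$deviation_pct <-
    abs(used$simulated - used$experimental) / used$experimental * 100
  out <- tibble::tibble(
    deviation_pct = mean(used$deviation_pct),
    n_cells = nrow(used),
    n_excluded = sum(zero)
  )
  attr(out, "by_cell") <- used
  out
}

#' Mean-based direct simulation of newborn neurons and astrocytes
#'
#' The simplest end-point model: each animal's simulated 30 d newborn
#' neuron (astrocyte) count is its 2 h proliferating progenitor count
#' times the age's mean net survival rate (30 d mean over 2 h mean) times
#' the age's mean NeuN (GFAP) differentiation fraction. No variability is
#' modelled — this is the deterministic counterpart of
#' [simulate_cohort()].
#'
#' @param observations_2h Tibble of per-animal 2 h counts: `age_months`,
#'   `animal_id`, `count`.
#' @param rates Per-age rate tibble: `age_months`, `survival_rate`,
#'   `neun_fraction`, `gfap_fraction` (see [direct_rates()]).
#' @return Input tibble with `sim_neurons` and `sim_astrocytes` columns.
#' @export
direct_simulation <- function(observations_2h, rates) {
  if (any(rates$survival_rate < 0, na.rm = TRUE)) {
    stop("`survival_rate` must be >= 0.", call. = FALSE)
  }
  if (any(rates$neun_fraction < 0 | rates$neun_fraction > 1) ||
      any(rates$gfap_fraction < 0 | rates$gfap_fraction > 1)) {
    stop("differentiation fractions must lie in [0, 1].", call. = FALSE)
  }
  if (any(observations_2h$count < 0)) {
    stop("2 h counts must be >= 0.", call. = FALSE)
  }
  observations_2h |>
    dplyr::inner_join(rates, by = "age_months") |>
    dplyr::mutate(
      sim_neurons = .data$count * .data$survival_rate * .data$neun_fraction,
      sim_astrocytes = .data$count * .data$survival_rate * .data$gfap_fraction
    ) |>
    dplyr::select(dplyr::all_of(names(observations_2h)),
                  "sim_neurons", "sim_astrocytes")
}

#' Extract per-age mean survival and differentiation rates
#'
#' @param summaries Group-summary tibble with `total` rows at 2 h and 30 d.
#' @param fractions Marker-fraction summary tibble ([summarize_fractions()]).
#' @return Tibble: `age_months`, `survival_rate` (30 d mean / 2 h mean),
#'   `neun_fraction`, `gfap_fraction`.
#' @export
direct_rates <- function(summaries, fractions) {
  tot <- summaries |>
    dplyr::filter(.data$marker == "total", .data$timepoint %in% c("2h", "30d")) |>
    dplyr::select("age_months", "timepoint", "mean") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean")
  if (any(tot$`2h` <= 0)) {
    stop("2 h mean must be > 0 to define a survival rate.", call. = FALSE)
  }
  fr <- fractions |>
    dplyr::select("age_months", "marker", "mean") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "mean")
  tot |>
    dplyr::inner_join(fr, by = "age_months") |>
    dplyr::transmute(
      age_months = .data$age_months,
      survival_rate = .data$`30d` / .data$`2h`,
      neun_fraction = .data$NeuN,
      gfap_fraction = .data$GFAP
    )
}
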