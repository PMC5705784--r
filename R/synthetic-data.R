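# Synthetic BrdU pulse-and-chase datasets with known ground truth.
#
# The generator emulates the cross-sectional design of a semicumulative
# BrdU labelling experiment: independent groups of animals are "sacrificed"
# at 2 h, 2 d, 4 d, 10 d or 30 d after labelling, and each animal
# contributes one whole-hippocampus BrdU+ count (plus NeuN/GFAP marker
# counts at 30 d and a Ki67 count at 2 d).

#' Canonical chase timepoints
#'
#' Tokens and their numeric values in days (2 h is 1/12 d). The internal
#' time unit throughout the package is days.
#'
#' @format Named numeric vector of length 5.
#' @export
cascade_timepoints <- c("2h" = 1 / 12, "2d" = 2, "4d" = 4, "10d" = 10, "30d" = 30)

.markers <- c("total", "NeuN", "GFAP", "Ki67")

#' Convert timepoint tokens to days
#'
#' @param tp Character vector of timepoint tokens (`"2h"`, `"2d"`, `"4d"`,
#'   `"10d"`, `"30d"`).
#' @return Numeric vector of times in days.
#' @export
timepoint_days <- function(tp) {
  bad <- setdiff(unique(tp), names(cascade_timepoints))
  if (length(bad) > 0) {
    stop("unknown timepoint token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(cascade_timepoints[tp])
}

#' Convert animal age in months to days
#'
#' Uses 30.44 days per month (365.25 / 12), the convention under which a
#' 53-day transversal half-life reads as about 1.7 months.
#'
#' @param age_months Numeric vector of ages in months.
#' @param days_per_month Conversion constant, default 30.44.
#' @return Ages in days.
#' @export
age_to_days <- function(age_months, days_per_month = 30.44) {
  age_months * days_per_month
}

#' Ground truth for one age group of the BrdU cascade
#'
#' Bundles the generative quantities behind one age: the 2 h proliferating
#' progenitor pool (`mu_2h`, `sigma_2h`), the net expansion factor from
#' 2 h to the 2 d peak, interval net-survival fractions for 2-4 d, 4-10 d
#' and 10-30 d, the 30 d NeuN and GFAP marker fractions, and a
#' multiplicative noise coefficient of variation applied at each cascade
#' step.
#'
#' @param age_months Age in months (> 0).
#' @param mu_2h,sigma_2h Mean and SD of the 2 h BrdU+ count (>= 0).
#' @param expansion Multiplicative net expansion 2 h -> 2 d (>= 1).
#' @param surv_4d,surv_10d,surv_30d Interval survival fractions in (0, 1].
#' @param frac_neun,frac_gfap 30 d marker fractions in `[0, 1]`, summing to
#'   at most 1.
#' @param noise_cv Per-step multiplicative noise CV (>= 0).
#' @param ki67_p Fraction of 2 d cells in active cell cycle (Ki67+); only
#'   carried through to the data model, no analysis consumes it.
#' @return A one-row tibble.
#' @export
cascade_truth <- function(age_months, mu_2h, sigma_2h = 0, expansion = 1,
                          surv_4d = 1, surv_10d = 1, surv_30d = 1,
                          frac_neun = 0, frac_gfap = 0, noise_cv = 0,
                          ki67_p = 0.3) {
  out <- tibble::tibble(
    age_months = age_months, mu_2h = mu_2h, sigma_2h = sigma_2h,
    expansion = expansion, surv_4d = surv_4d, surv_10d = surv_10d,
    surv_30d = surv_30d, frac_neun = frac_neun, frac_gfap = frac_gfap,
    noise_cv = noise_cv, ki67_p = ki67_p
  )
  validate_truths(out)
  out
}

#' Validate a table of cascade ground truths
#'
#' @param truths Tibble as built by [cascade_truth()] (rows may be bound).
#' @return `truths`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_truths <- function(truths) {
  need <- c("age_months", "mu_2h", "sigma_2h", "expansion", "surv_4d",
            "surv_10d", "surv_30d", "frac_neun", "frac_gfap", "noise_cv")
  miss <- setdiff(need, names(truths))
  if (length(miss) > 0) {
    stop("truth table is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(truths) == 0) stop("truth table is empty", call. = FALSE)
  chk <- function(cond, field, rule) {
    if (!all(cond)) {
      stop(sprintf("invalid truth field `%s`: must be %s", field, rule),
           call. = FALSE)
    }
  }
  chk(truths$age_months > 0, "age_months", "> 0")
  chk(truths$mu_2h >= 0, "mu_2h", ">= 0")
  chk(truths$sigma_2h >= 0, "sigma_2h", ">= 0")
  chk(truths$expansion >= 1, "expansion", ">= 1")
  for (f in c("surv_4d", "surv_10d", "surv_30d")) {
    chk(truths[[f]] > 0 & truths[[f]] <= 1, f, "in (0, 1]")
  }
  for (f in c("frac_neun", "frac_gfap")) {
    chk(truths[[f]] >= 0 & truths[[f]] <= 1, f, "in [0, 1]")
  }
  chk(truths$frac_neun + truths$frac_gfap <= 1 + 1e-12,
      "frac_neun + frac_gfap", "<= 1")
  chk(truths$noise_cv >= 0, "noise_cv", ">= 0")
  if (anyDuplicated(truths$age_months)) {
    stop("invalid truth field `age_months`: ages must be unique", call. = FALSE)
  }
  invisible(truths)
}

#' Build an age-group truth from decay-curve parameters
#'
#' Translates a longitudinal plateau-decay description (half-life in days
#' and plateau as a fraction of the 2 d peak) into the interval survival
#' fractions used by the generator, via
#' `f(t) = plateau + (1 - plateau) * exp(-K (t - 2))` with
#' `K = log(2) / half_life`.
#'
#' @inheritParams cascade_truth
#' @param half_life_d Longitudinal half-life in days.
#' @param plateau_frac Survival plateau as a fraction of the 2 d peak.
#' @return A one-row truth tibble.
#' @export
truth_from_decay <- function(age_months, mu_2h, sigma_2h, expansion,
                             half_life_d, plateau_frac,
                             frac_neun, frac_gfap, noise_cv = 0,
                             ki67_p = 0.3) {
  k <- log(2) / half_life_d
  f <- function(t) plateau_frac + (1 - plateau_frac) * exp(-k * (t - 2))
  cascade_truth(
    age_months = age_months, mu_2h = mu_2h, sigma_2h = sigma_2h,
    expansion = expansion,
    surv_4d = f(4), surv_10d = f(10) / f(4), surv_30d = f(30) / f(10),
    frac_neun = frac_neun, frac_gfap = frac_gfap, noise_cv = noise_cv,
    ki67_p = ki67_p
  )
}

#' Default four-age ground truth
#'
#' The package's stated world: mice at 1, 2, 6 and 12 months. Longitudinal
#' half-lives of 2.8 and 2.7 d with survival plateaus of 10.3% and 12.8%
#' of the 2 d peak in young animals, versus 1.1 d and 22.1-29.4% in mature
#' ones; 2 h progenitor pools declining across age with a 53 d transversal
#' half-life from 2000 cells at 1 month; 30 d NeuN fractions of 82/80/55/52%
#' against GFAP fractions of 18/19/41/44%; twofold net expansion from 2 h
#' to 2 d at every age; 15% between-animal CV on the 2 h pool and 12%
#' per-step multiplicative noise.
#'
#' @param noise_cv Per-step noise CV; set to 0 for a fully deterministic
#'   cascade.
#' @return A four-row truth tibble.
#' @export
default_truths <- function(noise_cv = 0.12) {
  ages <- c(1, 2, 6, 12)
  mu <- 2000 * exp(-log(2) / 53 * age_to_days(ages - 1))
  half <- c(2.8, 2.7, 1.1, 1.1)
  plat <- c(0.103, 0.128, 0.221, 0.294)
  neun <- c(0.82, 0.80, 0.55, 0.52)
  gfap <- c(0.18, 0.19, 0.41, 0.44)
  dplyr::bind_rows(purrr::map(seq_along(ages), function(i) {
    truth_from_decay(
      age_months = ages[i], mu_2h = mu[i], sigma_2h = 0.15 * mu[i],
      expansion = 2, half_life_d = half[i], plateau_frac = plat[i],
      frac_neun = neun[i], frac_gfap = gfap[i], noise_cv = noise_cv
    )
  }))
}

#' Expected noiseless cascade per truth
#'
#' The deterministic product `mu_2h * expansion * prod(surv)` evaluated at
#' each timepoint, before any rounding: the generator's exact expectation
#' when all noise terms are zero, and its mean otherwise.
#'
#' @param truths Truth tibble.
#' @return Tibble with `age_months`, `timepoint`, `t_days`, `expected`.
#' @export
cascade_expectation <- function(truths) {
  validate_truths(truths)
  purrr::map_dfr(seq_len(nrow(truths)), function(i) {
    tr <- truths[i, ]
    v <- c(
      "2h"  = tr$mu_2h,
      "2d"  = tr$mu_2h * tr$expansion,
      "4d"  = tr$mu_2h * tr$expansion * tr$surv_4d,
      "10d" = tr$mu_2h * tr$expansion * tr$surv_4d * tr$surv_10d,
      "30d" = tr$mu_2h * tr$expansion * tr$surv_4d * tr$surv_10d * tr$surv_30d
    )
    tibble::tibble(
      age_months = tr$age_months,
      timepoint = names(v),
      t_days = timepoint_days(names(v)),
      expected = unname(v)
    )
  })
}

round_half_up <- function(x) pmax(floor(x + 0.5), 0)

# Multiplicative log-normal noise factor with expectation exactly 1 and
# coefficient of variation cv. cv = 0 short-circuits to 1.
ln_noise <- function(rng, cv) {
  if (cv == 0) return(1)
  s2 <- log(1 + cv^2)
  exp(rng_normal(rng, -s2 / 2, sqrt(s2)))
}

#' Generate a synthetic per-animal BrdU count dataset
#'
#' For each age and each chase timepoint, draws `n_per_group` independent
#' pseudo-animals. Each animal's 2 h pool is a truncated-at-zero normal
#' draw; the cascade then multiplies by the expansion factor and interval
#' survival fractions, with independent multiplicative log-normal noise
#' (mean 1, CV `noise_cv`) at each step, and the count at the animal's own
#' sacrifice timepoint is rounded half-up to an integer. Animals at 30 d
#' additionally carry NeuN and GFAP marker counts (fractions of the 30 d
#' total, noisy in the same way, capped at the total); animals at 2 d carry
#' a Ki67 count (normal approximation to a Binomial(`n2d`, `ki67_p`) draw).
#'
#' Randomness is fully reproducible: each (age, timepoint) group uses its
#' own substream derived from `seed` via [derive_seed()].
#'
#' @param truths Truth tibble (one row per age), see [cascade_truth()].
#' @param n_per_group Animals per age x timepoint group (>= 1).
#' @param seed Master integer seed.
#' @return A list of class `cascade_dataset` with elements
#'   `observations` (tibble: `age_months`, `timepoint`, `animal_id`,
#'   `marker`, `count`) and `truth` (the input truth tibble).
#' @examples
#' ds <- generate_dataset(default_truths(noise_cv = 0), n_per_group = 3, seed = 1)
#' head(ds$observations)
#' @export
generate_dataset <- function(truths, n_per_group = 5, seed = 1) {
  validate_truths(truths)
  if (n_per_group < 1) stop("`n_per_group` must be >= 1.", call. = FALSE)
  obs <- purrr::map_dfr(seq_len(nrow(truths)), function(i) {
    tr <- truths[i, ]
    purrr::map_dfr(names(cascade_timepoints), function(tp) {
      rng <- cascade_rng(derive_seed(seed, tr$age_months, tp))
      purrr::map_dfr(seq_len(n_per_group), function(a) {
        v <- rng_truncnorm(rng, tr$mu_2h, tr$sigma_2h, lower = 0,
                           what = sprintf("2h pool at %g m", tr$age_months))
        steps <- c("2d" = tr$expansion, "4d" = tr$surv_4d,
                   "10d" = tr$surv_10d, "30d" = tr$surv_30d)
        for (s in names(steps)) {
          if (timepoint_days(s) > timepoint_days(tp)) break
          v <- v * steps[[s]] * ln_noise(rng, tr$noise_cv)
        }
        id <- sprintf("a%gm_%s_%02d", tr$age_months, tp, a)
        rows <- tibble::tibble(
          age_months = tr$age_months, timepoint = tp, animal_id = id,
          marker = "total", count = round_half_up(v)
        )
        if (tp == "30d") {
          neun <- min(round_half_up(tr$frac_neun * v * ln_noise(rng, tr$noise_cv)),
                      rows$count)
          gfap <- min(round_half_up(tr$frac_gfap * v * ln_noise(rng, tr$noise_cv)),
                      rows$count)
          rows <- dplyr::bind_rows(
            rows,
            tibble::tibble(age_months = tr$age_months, timepoint = tp,
                           animal_id = id, marker = c("NeuN", "GFAP"),
                           count = c(neun, gfap))
          )
        }
        if (tp == "2d") {
          n2d <- rows$count
          p <- tr$ki67_p
          ki <- if (tr$noise_cv == 0 || n2d == 0) {
            round_half_up(p * n2d)
          } else {
            round_half_up(rng_normal(rng, p * n2d, sqrt(n2d * p * (1 - p))))
          }
          rows <- dplyr::bind_rows(
            rows,
            tibble::tibble(age_months = tr$age_months, timepoint = tp,
                           animal_id = id, marker = "Ki67",
                           count = min(ki, n2d))
          )
        }
        rows
      })
    })
  })
  structure(list(observations = obs, truth = truths),
            class = "cascade_dataset")
}

#' @export
print.cascade_dataset <- function(x, ...) {
  cat(sprintf("<cascade_dataset> %d observations, %d age group(s)\n",
              nrow(x$observations), nrow(x$truth)))
  print(x$observations, n = 6)
  invisible(x)
}

#' Summarize per-animal counts into group statistics
#'
#' Computes mean, sample SD (n - 1 denominator) and group size per
#' (age, timepoint, marker) cell: the interface between per-animal data
#' and the constrained cohort simulation. Singleton groups get `sd = 0`
#' and are flagged in the `degenerate` column (with a warning), since a
#' single animal carries no spread information.
#'
#' @param observations Tibble with columns `age_months`, `timepoint`,
#'   `marker`, `count` (e.g. `generate_dataset(...)$observations`).
#' @return Tibble: `age_months`, `timepoint`, `marker`, `mean`, `sd`, `n`,
#'   `degenerate`.
#' @export
summarize_counts <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0) {
    stop("no observations to summarize", call. = FALSE)
  }
  out <- observations |>
    dplyr::group_by(.data$age_months, .data$timepoint, .data$marker) |>
    dplyr::summarise(
      mean = mean(.data$count),
      sd = ifelse(dplyr::n() == 1, 0, stats::sd(.data$count)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(degenerate = .data$n == 1)
  if (any(out$degenerate)) {
    warning(sum(out$degenerate),
            " group(s) contain a single animal; their sd is reported as 0.",
            call. = FALSE)
  }
  out
}

#' Summarize 30 d marker fractions per animal
#'
#' Converts 30 d NeuN/GFAP marker counts into per-animal fractions of each
#' animal's total 30 d count, then summarizes mean, SD and n per age. These
#' fraction summaries parameterize the marker-allocation step of the
#' cohort simulation.
#'
#' @param observations Observation tibble (must contain `total` and marker
#'   rows at the requested timepoint).
#' @param markers Markers to summarize, default NeuN and GFAP.
#' @param timepoint Timepoint token, default `"30d"`.
#' @return Tibble: `age_months`, `marker`, `mean`, `sd`, `n` (fractions).
#' @export
summarize_fractions <- function(observations, markers = c("NeuN", "GFAP"),
                                timepoint = "30d") {
  tot <- observations |>
    dplyr::filter(.data$timepoint == !!timepoint, .data$marker == "total") |>
    dplyr::select("age_months", "animal_id", total = "count")
  frac <- observations |>
    dplyr::filter(.data$timepoint == !!timepoint, .data$marker %in% markers) |>
    dplyr::inner_join(tot, by = c("age_months", "animal_id")) |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(frac = .data$count / .data$total)
  if (nrow(frac) == 0) {
    stop("no marker observations at timepoint ", timepoint, call. = FALSE)
  }
  frac |>
    dplyr::group_by(.data$age_months, .data$marker) |>
    dplyr::summarise(
      mean = mean(.data$frac),
      sd = ifelse(dplyr::n() == 1, 0, stats::sd(.data$frac)),
      n = dplyr::n(),
      .groups = "drop"
    )
}
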