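# Descriptive statistics of the neurogenic cascade: normalization to the
# 2 h progenitor pool, interval cell loss, lineage yields, and the
# neuron-to-astrocyte ratio.

#' Normalize timepoint counts to the 2 h value
#'
#' Expresses each timepoint's count as a percentage of the BrdU+ count at
#' 2 h within the same group (per age when an `age_months` column is
#' present), so time courses from differently sized progenitor pools can
#' be overlaid.
#'
#' @param data Tibble with columns `timepoint` and `count` (e.g. group
#'   means), optionally `age_months`.
#' @return `data` with an added `pct_of_2h` column.
#' @export
normalize_to_2h <- function(data) {
  stopifnot(all(c("timepoint", "count") %in% names(data)))
  grp <- intersect("age_months", names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      base <- d$count[d$timepoint == "2h"]
      if (length(base) != 1 || is.na(base)) {
        stop("each group needs exactly one 2h count", call. = FALSE)
      }
      if (base <= 0) stop("2h count must be > 0 to normalize", call. = FALSE)
      dplyr::mutate(d, pct_of_2h = 100 * .data$count / base)
    }) |>
    dplyr::ungroup()
}

#' Cells lost per day over an interval
#'
#' `(count_t1 - count_t2) / (t2 - t1)`: the average daily loss of BrdU+
#' cells between two chase timepoints. Negative values (net gain) are
#' allowed and flagged by the caller-facing [interval_losses()].
#'
#' @param count_t1,count_t2 Counts at the earlier and later timepoint.
#' @param t1,t2 Times in days, `t2 > t1`.
#' @return Cells per day (vectorized).
#' @export
loss_per_day <- function(count_t1, count_t2, t1, t2) {
  if (any(t2 <= t1)) stop("`t2` must be greater than `t1`", call. = FALSE)
  (count_t1 - count_t2) / (t2 - t1)
}

#' Interval loss as a percentage of the 2 d peak
#'
#' `100 * (count_t1 - count_t2) / count_2d`: the share of the peak cohort
#' lost during an interval. The three chase intervals telescope, so their
#' rates sum to `100 * (count_2d - count_30d) / count_2d`.
#'
#' @param count_t1,count_t2 Counts at the interval ends.
#' @param count_2d Count at the 2 d peak (> 0).
#' @return Percent of the 2 d peak (vectorized).
#' @export
loss_rate_of_peak <- function(count_t1, count_t2, count_2d) {
  if (any(count_2d <= 0)) stop("`count_2d` must be > 0", call. = FALSE)
  100 * (count_t1 - count_t2) / count_2d
}

#' Per-age interval losses over the chase time course
#'
#' Applies [loss_per_day()] and [loss_rate_of_peak()] to the 2-4 d,
#' 4-10 d and 10-30 d intervals of each age's `total` group means.
#'
#' @param summaries Group-summary tibble with `total` rows at 2d, 4d, 10d
#'   and 30d per age.
#' @return Tibble: `age_months`, `interval`, `cells_per_day`,
#'   `pct_of_peak`, `net_gain` (flag for negative loss).
#' @export
interval_losses <- function(summaries) {
  wide <- summaries |>
    dplyr::filter(.data$marker == "total") |>
    dplyr::select("age_months", "timepoint", "mean") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean")
  need <- c("2d", "4d", "10d", "30d")
  miss <- setdiff(need, names(wide))
  if (length(miss) > 0) {
    stop("missing timepoint(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ints <- tibble::tibble(
    interval = c("2d-4d", "4d-10d", "10d-30d"),
    from = c("2d", "4d", "10d"), to = c("4d", "10d", "30d"),
    t1 = c(2, 4, 10), t2 = c(4, 10, 30)
  )
  purrr::map_dfr(seq_len(nrow(ints)), function(i) {
    tibble::tibble(
      age_months = wide$age_months,
      interval = ints$interval[i],
      cells_per_day = loss_per_day(wide[[ints$from[i]]], wide[[ints$to[i]]],
                                   ints$t1[i], ints$t2[i]),
      pct_of_peak = loss_rate_of_peak(wide[[ints$from[i]]], wide[[ints$to[i]]],
                                      wide$`2d`)
    )
  }) |>
    dplyr::mutate(net_gain = .data$cells_per_day < 0) |>
    dplyr::arrange(.data$age_months)
}

#' Neurogenic and astrogenic yield of proliferating progenitors
#'
#' The neuronal (astrocytic) yield is the number of newborn NeuN+ (GFAP+)
#' BrdU+ cells at 30 d divided by the number of BrdU+ proliferating
#' progenitors at 2 h. Their quotient, the neuron-to-astrocyte ratio,
#' cancels the common 2 h denominator and equals the 30 d count ratio.
#' A zero astrocytic yield leaves the ratio `NA` with
#' `ratio_defined = FALSE` rather than erroring.
#'
#' @param mean_2h Mean BrdU+ count at 2 h (> 0).
#' @param mean_neun_30d,mean_gfap_30d Mean marker-positive counts at 30 d.
#' @param age_months Optional age label carried into the result.
#' @return Tibble (one row per input element): `neuronal_yield`,
#'   `astrocytic_yield`, `ratio`, `ratio_defined`.
#' @examples
#' yields(100, 20, 5)  # neuronal 0.2, astrocytic 0.05, ratio 4
#' @export
yields <- function(mean_2h, mean_neun_30d, mean_gfap_30d, age_months = NULL) {
  if (any(mean_2h <= 0)) stop("`mean_2h` must be > 0", call. = FALSE)
  if (any(mean_neun_30d < 0) || any(mean_gfap_30d < 0)) {
    stop("marker counts must be >= 0", call. = FALSE)
  }
  out <- tibble::tibble(
    neuronal_yield = mean_neun_30d / mean_2h,
    astrocytic_yield = mean_gfap_30d / mean_2h
  )
  out$ratio_defined <- out$astrocytic_yield > 0
  out$ratio <- ifelse(out$ratio_defined,
                      out$neuronal_yield / out$astrocytic_yield, NA_real_)
  if (!is.null(age_months)) {
    out <- dplyr::bind_cols(tibble::tibble(age_months = age_months), out)
  }
  out[c(intersect("age_months", names(out)),
        "neuronal_yield", "astrocytic_yield", "ratio", "ratio_defined")]
}

#' Per-age yields from group summaries
#'
#' Convenience wrapper applying [yields()] to each age's `total` 2 h mean
#' and `NeuN`/`GFAP` 30 d marker-count means.
#'
#' @param summaries Group-summary tibble with the required rows.
#' @return Tibble as from [yields()] with an `age_months` column.
#' @export
yields_by_age <- function(summaries) {
  two_h <- summaries |>
    dplyr::filter(.data$marker == "total", .data$timepoint == "2h") |>
    dplyr::select("age_months", mean_2h = "mean")
  mk <- summaries |>
    dplyr::filter(.data$marker %in% c("NeuN", "GFAP"),
                  .data$timepoint == "30d") |>
    dplyr::select("age_months", "marker", "mean") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "mean")
  if (!all(c("NeuN", "GFAP") %in% names(mk))) {
    stop("summaries lack 30d NeuN/GFAP marker rows", call. = FALSE)
  }
  j <- dplyr::inner_join(two_h, mk, by = "age_months")
  if (nrow(j) == 0) stop("no age has both 2h totals and 30d markers",
                         call. = FALSE)
  yields(j$mean_2h, j$NeuN, j$GFAP, age_months = j$age_months)
}

#' Per-age yields from a simulated cohort
#'
#' Plug-in yields using the simulated population means of each age: mean
#' `n_neun` and `n_gfap` over replicates divided by mean `n2h`.
#'
#' @param records Simulated cohort tibble from [simulate_cohort()].
#' @return Tibble as from [yields()] with an `age_months` column.
#' @export
yields_from_simulation <- function(records) {
  m <- records |>
    dplyr::group_by(.data$age_months) |>
    dplyr::summarise(n2h = mean(.data$n2h), n_neun = mean(.data$n_neun),
                     n_gfap = mean(.data$n_gfap), .groups = "drop")
  yields(m$n2h, m$n_neun, m$n_gfap, age_months = m$age_months)
}
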