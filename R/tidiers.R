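# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit's parameters
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `half_life`, `plateau_pct`,
#'   `r_squared`, `aicc`, `rss`, `n_points`, `flat`, `data_mode`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    half_life = x$half_life,
    plateau_pct = x$plateau_pct,
    r_squared = x$r_squared,
    aicc = x$aicc,
    rss = x$rss,
    n_points = x$n_points,
    flat = x$flat,
    data_mode = x$data_mode
  )
}

#' @rdname glance.decay_fit
#' @export
glance.split_decay_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$young), side = "young", .before = 1),
    dplyr::mutate(glance(x$old), side = "old", .before = 1)
  ) |>
    dplyr::mutate(split_age = x$split_age)
}

#' Per-point fitted values and residuals of a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble: `t`, `value`, `fitted`, `residual`.
#' @export
augment.decay_fit <- function(x, ...) {
  x$data
}

#' @importFrom generics augment
#' @export
generics::augment
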