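# CSV dialects: raw per-animal counts
# (age_months,timepoint,animal_id,marker,count) and group summaries
# (age_months,timepoint,marker,mean,sd,n). Ground truth travels as a JSON
# sidecar next to generated CSVs.

#' Load a raw per-animal count table
#'
#' Reads a UTF-8 CSV with header columns `age_months`, `timepoint`,
#' `animal_id`, `marker`, `count` (extra columns are ignored with a
#' message). Rows violating the record invariants — unknown timepoint or
#' marker tokens are a hard error listing the offending values; negative,
#' missing or non-integer counts are rejected row-wise — are dropped and
#' reported via the `"rejected"` attribute and a message.
#'
#' @param path Path to the CSV file.
#' @return Tibble of validated observations; attribute `"rejected"` holds
#'   the dropped rows (with a `reason` column), possibly empty.
#' @export
load_raw_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           age_months = readr::col_double(),
                           timepoint = readr::col_character(),
                           animal_id = readr::col_character(),
                           marker = readr::col_character(),
                           count = readr::col_double(),
                           .default = readr::col_guess()))
  need <- c("age_months", "timepoint", "animal_id", "marker", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), need)
  if (length(extra) > 0) {
    message("ignoring unrelated column(s): ", paste(extra, collapse = ", "))
  }
  raw <- raw[need]
  bad_tp <- setdiff(unique(raw$timepoint), names(cascade_timepoints))
  if (length(bad_tp) > 0) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)
  }
  bad_mk <- setdiff(unique(raw$marker), .markers)
  if (length(bad_mk) > 0) {
    stop("unknown marker label(s): ", paste(bad_mk, collapse = ", "),
         call. = FALSE)
  }
  raw <- dplyr::mutate(raw, count = as.numeric(.data$count),
                       age_months = as.numeric(.data$age_months))
  reason <- dplyr::case_when(
    is.na(raw$count) ~ "missing count",
    raw$count < 0 ~ "negative count",
    raw$count != floor(raw$count) ~ "non-integer count",
    is.na(raw$age_months) | raw$age_months <= 0 ~ "invalid age",
    TRUE ~ NA_character_
  )
  rejected <- dplyr::mutate(raw[!is.na(reason), ], reason = reason[!is.na(reason)])
  ok <- raw[is.na(reason), ]
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  attr(ok, "rejected") <- rejected
  ok
}

#' Write a raw per-animal count table
#'
#' @param observations Observation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_counts <- function(observations, path) {
  cols <- c("age_months", "timepoint", "animal_id", "marker", "count")
  readr::write_csv(observations[cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write group-summary tables
#'
#' The summary dialect carries one row per (age, timepoint, marker) with
#' `mean`, `sd` and `n`.
#'
#' @param path CSV path.
#' @return `read_group_summary()`: a summary tibble.
#' @export
read_group_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("age_months", "timepoint", "marker", "mean", "sd", "n")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x[intersect(c(need, "degenerate"), names(x))]
}

#' @rdname read_group_summary
#' @param summaries Summary tibble (from [summarize_counts()]).
#' @export
write_group_summary <- function(summaries, path) {
  readr::write_csv(summaries, path, progress = FALSE)
  invisible(path)
}

#' Write a generated dataset with its ground-truth sidecar
#'
#' Writes the observation CSV and, next to it, a JSON sidecar
#' (`<stem>_truth.json`) holding the generating truth table so recovery
#' tests can reload both halves.
#'
#' @param dataset A `cascade_dataset` from [generate_dataset()].
#' @param path Output CSV path for the observations.
#' @return Named character vector with the `csv` and `truth` paths,
#'   invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cascade_dataset"))
  write_raw_counts(dataset$observations, path)
  sidecar <- paste0(sub("\\.csv$", "", path), "_truth.json")
  jsonlite::write_json(dataset$truth, sidecar, digits = NA, pretty = TRUE)
  invisible(c(csv = path, truth = sidecar))
}

#' Reload a dataset written by [write_dataset()]
#'
#' @param path The observation CSV path (sidecar found next to it).
#' @return A `cascade_dataset` list.
#' @export
read_dataset <- function(path) {
  obs <- load_raw_counts(path)
  sidecar <- paste0(sub("\\.csv$", "", path), "_truth.json")
  truth <- if (file.exists(sidecar)) {
    tibble::as_tibble(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  } else {
    NULL
  }
  structure(list(observations = obs, truth = truth), class = "cascade_dataset")
}
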