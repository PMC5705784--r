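# Shared fixture builders (all data is generated in code).

# fully deterministic four-age world
noiseless_truths <- function() {
  tr <- default_truths(noise_cv = 0)
  tr$sigma_2h <- 0
  tr
}

# hand-built group summaries for one age, total counts at all timepoints
make_summaries <- function(age = 1, means = c(100, 150, 80, 50, 30),
                           sds = rep(0, 5)) {
  tibble::tibble(
    age_months = age,
    timepoint = c("2h", "2d", "4d", "10d", "30d"),
    marker = "total",
    mean = means, sd = sds, n = 5
  )
}

make_fractions <- function(age = 1, gfap = 0.2, neun = 0.8,
                           sd_gfap = 0, sd_neun = 0) {
  tibble::tibble(
    age_months = age,
    marker = c("GFAP", "NeuN"),
    mean = c(gfap, neun),
    sd = c(sd_gfap, sd_neun),
    n = 5
  )
}

# noiseless plateau-decay curve values
plateau_curve <- function(t, y0, k, plateau, anchor = 2) {
  plateau + (y0 - plateau) * exp(-k * (t - anchor))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-12)),
              label = sprintf("relative error vs %s", deparse(expected)))
}
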