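# Constrained cohort simulation: degenerate configs, constraint totality,
# convergence to configured means, deviation metric arithmetic.

test_that("degenerate SDs reproduce the configured means exactly", {
  sm <- make_summaries(means = c(100, 150, 80, 50, 30))
  fr <- make_fractions(gfap = 0.2, neun = 0.8)
  rec <- simulate_cohort(sm, fr, n_replicates = 20, seed = 1)
  expect_true(all(rec$n2h == 100 & rec$n2d == 150 & rec$n4d == 80 &
                    rec$n10d == 50 & rec$n30d == 30))
  expect_true(all(rec$n_gfap == 6 & rec$n_neun == 24))
})

test_that("every emitted record satisfies the nested ordering restrictions", {
  ds <- generate_dataset(default_truths(), n_per_group = 8, seed = 3)
  sm <- summarize_counts(ds$observations)
  fr <- summarize_fractions(ds$observations)
  for (seed in c(11, 12)) {
    for (strat in c("gfap-locked", "neun-locked")) {
      rec <- suppressWarnings(
        simulate_cohort(sm, fr, n_replicates = 250, strategy = strat,
                        seed = seed))
      expect_equal(nrow(rec), 4 * 250)
      expect_true(all(rec$n2h >= 0 & rec$n2h <= rec$n2d &
                        rec$n2d >= rec$n4d & rec$n4d >= rec$n10d &
                        rec$n10d >= rec$n30d))
      # locked-strategy identity: markers partition the 30 d population
      expect_equal(rec$n_gfap + rec$n_neun, rec$n30d, tolerance = 1e-12)
      expect_true(all(rec$n_gfap >= 0 & rec$n_neun >= 0))
    }
  }
})

test_that("simulated means converge to the configured means", {
  sm <- make_summaries(means = c(100, 160, 90, 60, 35),
                       sds = c(10, 15, 9, 6, 4))
  fr <- make_fractions(gfap = 0.3, neun = 0.6, sd_gfap = 0.05, sd_neun = 0.05)
  rec <- simulate_cohort(sm, fr, n_replicates = 1000, seed = 21)
  for (col in c("n2h", "n2d", "n4d", "n10d", "n30d")) {
    tp <- c(n2h = "2h", n2d = "2d", n4d = "4d", n10d = "10d", n30d = "30d")[[col]]
    mu <- sm$mean[sm$timepoint == tp]
    # truncation shifts means slightly; allow 3 SE plus a 2% shift budget
    se <- sd(rec[[col]]) / sqrt(nrow(rec))
    expect_lt(abs(mean(rec[[col]]) - mu), 3 * se + 0.02 * mu)
  }
  # more replicates, closer agreement (fixed seeds)
  err_of <- function(n) {
    r <- simulate_cohort(sm, fr, n_replicates = n, seed = 77)
    mean(abs(vapply(c("2h", "2d", "4d", "10d", "30d"), function(tp) {
      col <- c("2h" = "n2h", "2d" = "n2d", "4d" = "n4d",
               "10d" = "n10d", "30d" = "n30d")[[tp]]
      mean(r[[col]]) - sm$mean[sm$timepoint == tp]
    }, numeric(1))))
  }
  expect_lt(err_of(4000), err_of(100))
})

test_that("GFAP-locked and NeuN-locked agree under a symmetric fraction law", {
  sm <- make_summaries(means = c(100, 160, 90, 60, 35),
                       sds = c(10, 15, 9, 6, 4))
  fr <- make_fractions(gfap = 0.5, neun = 0.5, sd_gfap = 0.05, sd_neun = 0.05)
  counts <- tibble::tibble(
    age_months = 1, timepoint = "30d", marker = c("NeuN", "GFAP"),
    mean = c(17.5, 17.5), sd = c(2, 2), n = 5
  )
  sm_full <- dplyr::bind_rows(sm, counts)
  d_g <- deviation_from_experiment(
    simulate_cohort(sm, fr, 1000, strategy = "gfap-locked", seed = 42), sm_full)
  d_n <- deviation_from_experiment(
    simulate_cohort(sm, fr, 1000, strategy = "neun-locked", seed = 42), sm_full)
  expect_lt(abs(d_g$deviation_pct - d_n$deviation_pct), 0.5)
})

test_that("the deviation metric is the stated mean absolute relative difference", {
  sm <- make_summaries(means = c(100, 150, 80, 50, 30))
  rec <- tibble::tibble(
    age_months = 1, replicate = 1:2, strategy = "gfap-locked",
    n2h = 110, n2d = 150, n4d = 80, n10d = 50, n30d = 30,
    n_gfap = 6, n_neun = 24
  )
  # one population off by 10%, four exact, no marker rows: mean = 2%
  d <- deviation_from_experiment(rec, sm)
  expect_equal(d$deviation_pct, 10 / 5, tolerance = 1e-12)
  # identical means give zero deviation
  rec$n2h <- 100
  expect_equal(deviation_from_experiment(rec, sm)$deviation_pct, 0)
})

test_that("missing summary rows and infeasible configs raise named errors", {
  sm <- make_summaries()[-2, ]  # drop the 2d row
  fr <- make_fractions()
  expect_error(simulate_cohort(sm, fr, 10, seed = 1), "2d")
  sm2 <- make_summaries()
  expect_error(simulate_cohort(sm2, fr[fr$marker == "NeuN", ], 10, seed = 1),
               "GFAP")
  # means violating the ordering provoke a warning
  sm3 <- make_summaries(means = c(100, 90, 80, 50, 30), sds = rep(8, 5))
  expect_warning(simulate_cohort(sm3, fr, 10, seed = 1), "ordering")
})

test_that("direct mean-based simulation is the stated arithmetic", {
  obs <- tibble::tibble(age_months = 1, animal_id = c("a", "b"),
                        count = c(100, 50))
  rates <- tibble::tibble(age_months = 1, survival_rate = 0.3,
                          neun_fraction = 0.8, gfap_fraction = 0.2)
  sim <- direct_simulation(obs, rates)
  expect_equal(sim$sim_neurons, c(24, 12))
  expect_equal(sim$sim_astrocytes, c(6, 3))
  rates0 <- dplyr::mutate(rates, survival_rate = 0)
  sim0 <- direct_simulation(obs, rates0)
  expect_true(all(sim0$sim_neurons == 0 & sim0$sim_astrocytes == 0))
  expect_error(direct_simulation(obs, dplyr::mutate(rates, survival_rate = -1)),
               "survival_rate")
})

test_that("direct rates come from the 30d/2h mean quotient", {
  ds <- generate_dataset(noiseless_truths(), n_per_group = 3, seed = 4)
  sm <- summarize_counts(ds$observations)
  fr <- summarize_fractions(ds$observations)
  rates <- direct_rates(sm, fr)
  exp_tbl <- cascade_expectation(noiseless_truths())
  for (a in rates$age_months) {
    e <- exp_tbl[exp_tbl$age_months == a, ]
    want <- round(e$expected[e$timepoint == "30d"]) /
      round(e$expected[e$timepoint == "2h"])
    expect_equal(rates$survival_rate[rates$age_months == a], want,
                 tolerance = 0.01)
  }
})
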