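# Extra-survival decomposition and the midpoint allocation search.

test_that("the decomposition is the stated baseline/extra arithmetic", {
  sm <- dplyr::bind_rows(
    make_summaries(age = 1, means = c(40, 50, 20, 10, 6)),
    make_summaries(age = 12, means = c(30, 50, 25, 15, 10))
  )
  fr <- make_fractions(age = 1, gfap = 0.25, neun = 0.75)
  dec <- decompose_survival(sm, fr, age = 12, reference_age = 1)
  # baseline: n2d(12m) * (n30d(1m) / n2d(1m)) = 50 * 0.12 = 6
  expect_equal(dec$baseline_total, 6)
  expect_equal(dec$baseline_neurons, 4.5)
  expect_equal(dec$baseline_astrocytes, 1.5)
  expect_equal(dec$extra, 4)

  # the reference age decomposed against itself has no extra survival
  dec_ref <- decompose_survival(sm, fr, age = 1, reference_age = 1)
  expect_equal(dec_ref$extra, 0, tolerance = 1e-12)

  sm0 <- dplyr::mutate(sm, mean = ifelse(age_months == 1 & timepoint == "2d",
                                         0, mean))
  expect_error(decompose_survival(sm0, fr, age = 12), "> 0")
})

test_that("a planted extra astrocyte survival is recovered exactly", {
  # noiseless mature cohort built by adding pure-astrocyte extra survival
  ref_curve <- c(`2h` = 100, `2d` = 200, `4d` = 120, `10d` = 70, `30d` = 40)
  extra <- 25
  mat <- ref_curve * 0.5
  mat[["30d"]] <- mat[["30d"]] + extra
  sm <- dplyr::bind_rows(
    make_summaries(age = 1, means = unname(ref_curve)),
    make_summaries(age = 6, means = unname(mat))
  )
  fr <- make_fractions(age = 1, gfap = 0.2, neun = 0.8)
  dec <- decompose_survival(sm, fr, age = 6, reference_age = 1)
  expect_equal(dec$extra, extra, tolerance = 1e-9)
})

test_that("scenario ratios respond to the allocation as stated", {
  dec <- tibble::tibble(age_months = 12, baseline_neurons = 30,
                        baseline_astrocytes = 10, extra = 20)
  # all extra to astrocytes: 30 / 30
  expect_equal(scenario_ratio(dec, 0), 1.0)
  # all extra to neurons: 50 / 10
  expect_equal(scenario_ratio(dec, 1), 5.0)
  # with no extra the allocation is irrelevant
  dec0 <- dplyr::mutate(dec, extra = 0)
  expect_true(all(scenario_ratio(dec0, seq(-1, 2, by = 0.5)) == 3))
  # strictly increasing in p when extra > 0 (within the defined domain,
  # i.e. below the pole at p = 1 + A_b/E = 1.5)
  grid <- scenario_ratio(dec, seq(-1, 1.45, length.out = 101))
  expect_true(all(diff(grid) > 0))
  st <- scenario_table(dec)
  expect_equal(st$scenario, c("100N:0A", "50N:50A", "0N:100A"))
  expect_equal(st$ratio, c(5, 2, 1))
})

test_that("bisection agrees with the closed form, including endpoints", {
  dec <- tibble::tibble(age_months = 12, baseline_neurons = 30,
                        baseline_astrocytes = 10, extra = 20)
  res <- find_allocation(dec, target_ratio = 1.0)
  expect_true(res$converged)
  expect_equal(res$p_neuron, 0, tolerance = 1e-6)
  expect_equal(res$achieved_ratio, 1.0, tolerance = 1e-6)
  expect_gt(nrow(attr(res, "trace")), 2)

  res1 <- find_allocation(dec, target_ratio = 5.0)
  expect_equal(res1$p_neuron, 1, tolerance = 1e-6)

  # negative allocations are reachable via bracket expansion
  res_neg <- find_allocation(dec, target_ratio = 0.6)
  p_star <- (0.6 * (10 + 20) - 30) / (20 * (1 + 0.6))
  expect_lt(res_neg$p_neuron, 0)
  expect_equal(res_neg$p_neuron, p_star, tolerance = 1e-6)
})

test_that("degenerate and infeasible searches raise the stated conditions", {
  dec0 <- tibble::tibble(age_months = 6, baseline_neurons = 30,
                         baseline_astrocytes = 10, extra = 0)
  res <- find_allocation(dec0, target_ratio = 3)
  expect_true(res$converged)
  expect_true(is.na(res$p_neuron))
  expect_true(isTRUE(attr(res, "degenerate")))
  expect_error(find_allocation(dec0, target_ratio = 2), "baseline ratio")
  dec <- dplyr::mutate(dec0, extra = 5)
  expect_error(find_allocation(dec, target_ratio = 50), "not attainable")
  expect_error(find_allocation(dec, target_ratio = -1), "target_ratio")
})

test_that("bisection matches the closed form across random feasible instances", {
  set.seed(99)
  n_ok <- 0
  for (i in 1:200) {
    nb <- runif(1, 1, 100)
    ab <- runif(1, 1, 100)
    ex <- runif(1, 1, 60) * sample(c(1, -1), 1, prob = c(0.8, 0.2))
    dec <- tibble::tibble(age_months = 6, baseline_neurons = nb,
                          baseline_astrocytes = ab, extra = ex)
    p_true <- runif(1, -1, 2)
    target <- scenario_ratio(dec, p_true)
    if (is.na(target) || target < 0) next
    res <- find_allocation(dec, target)
    p_star <- neurocascade:::.allocation_closed_form(dec, target)
    expect_lt(abs(res$p_neuron - p_star), 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 100)
})

test_that("the search is invariant to uniform rescaling of the decomposition", {
  dec <- tibble::tibble(age_months = 12, baseline_neurons = 12,
                        baseline_astrocytes = 7, extra = 9)
  dec2 <- dplyr::mutate(dec, dplyr::across(c(baseline_neurons,
                                             baseline_astrocytes, extra),
                                           function(x) x * 250))
  r1 <- find_allocation(dec, 1.4)
  r2 <- find_allocation(dec2, 1.4)
  expect_equal(r1$p_neuron, r2$p_neuron, tolerance = 1e-9)
})
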