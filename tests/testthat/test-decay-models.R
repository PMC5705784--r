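# Decay fitting: noiseless recovery, invariants, AICc ranking, regression
# oracle, curve validation, split-age fits.

test_that("noiseless plateau-decay data are recovered to 1e-6", {
  t <- c(2, 4, 10, 30)
  pts <- tibble::tibble(t = t, value = plateau_curve(t, 100, 0.5, 10))
  fit <- fit_plateau_decay(pts)
  expect_rel_equal(fit$params[["Y0"]], 100, 1e-6)
  expect_rel_equal(fit$params[["K"]], 0.5, 1e-6)
  expect_rel_equal(fit$params[["plateau"]], 10, 1e-6)
  expect_equal(fit$half_life, log(2) / fit$params[["K"]], tolerance = 1e-12)
  expect_rel_equal(fit$half_life, 1.3863, 1e-4)
  expect_equal(fit$plateau_pct, fit$params[["plateau"]] / fit$params[["Y0"]] * 100)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # K = log(2) means a one-day half-life, by definition
  pts2 <- tibble::tibble(t = t, value = plateau_curve(t, 80, log(2), 5))
  expect_rel_equal(fit_plateau_decay(pts2)$half_life, 1, 1e-6)
})

test_that("noiseless exponential decay is recovered to 1e-6, flat data flagged", {
  ages <- c(30.44, 60.88, 182.6, 365.3)
  k <- log(2) / 53
  fit <- fit_exponential_decay(tibble::tibble(t = ages, value = 500 * exp(-k * ages)))
  expect_rel_equal(fit$params[["K"]], k, 1e-6)
  expect_rel_equal(fit$half_life, 53, 1e-6)

  flat <- fit_exponential_decay(tibble::tibble(t = ages, value = rep(7, 4)))
  expect_true(flat$flat)
  expect_identical(flat$half_life, Inf)
})

test_that("fits are invariant to uniform rescaling of the response", {
  t <- c(2, 3, 4, 8, 15, 30)
  y <- plateau_curve(t, 100, 0.4, 25) * (1 + c(0.02, -0.03, 0.01, 0.04, -0.02, 0))
  f1 <- fit_plateau_decay(tibble::tibble(t = t, value = y))
  f2 <- fit_plateau_decay(tibble::tibble(t = t, value = 3.7 * y))
  expect_rel_equal(f2$half_life, f1$half_life, 1e-6)
  expect_rel_equal(f2$params[["Y0"]], 3.7 * f1$params[["Y0"]], 1e-6)
  expect_rel_equal(f2$params[["plateau"]], 3.7 * f1$params[["plateau"]], 1e-6)
  expect_equal(f2$plateau_pct, f1$plateau_pct, tolerance = 1e-6)
})

test_that("AICc prefers fewer parameters at equal RSS and needs enough points", {
  t <- c(2, 4, 8, 15, 22, 30)
  y <- 100 * exp(-0.3 * t)
  mk <- function(model, params, rss) {
    neurocascade:::.new_decay_fit(model, params, rss, t, y, y, 0, FALSE)
  }
  cmp <- compare_aicc(list(
    mk("plateau_decay", c(Y0 = 100, K = 0.3, plateau = 0), rss = 5),
    mk("pure_exponential", c(Y0 = 100, K = 0.3), rss = 5)
  ))
  expect_equal(cmp$model[1], "pure_exponential")
  expect_true(cmp$preferred[1])
  expect_equal(cmp$delta_aicc[1], 0)

  # 5 points leave n - K' - 1 = 0 for the 3-parameter model
  t5 <- c(2, 4, 10, 20, 30)
  y5 <- plateau_curve(t5, 100, 0.5, 10)
  f3 <- fit_plateau_decay(tibble::tibble(t = t5, value = y5))
  f2 <- fit_exponential_decay(tibble::tibble(t = t5, value = y5))
  expect_error(compare_aicc(list(f3, f2)), "undefined")
  expect_error(compare_aicc(list(
    fit_exponential_decay(tibble::tibble(t = t, value = y)),
    fit_exponential_decay(tibble::tibble(t = t, value = y + 1))
  )), "identical data")
})

test_that("linear regression matches the hand-computed normal equations", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- suppressWarnings(linear_regression(x, 2 * x))  # zero-residual lm
  expect_equal(perfect$slope, 2, tolerance = 1e-12)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)
  expect_equal(linear_regression(x, rep(3, 5))$r_squared, 0)

  # 6-point toy set against explicit normal equations
  x6 <- c(1.2, 2.5, 3.1, 4.8, 6.0, 7.3)
  y6 <- c(2.1, 4.4, 5.9, 9.6, 12.3, 14.1)
  n <- 6
  b1 <- (n * sum(x6 * y6) - sum(x6) * sum(y6)) /
    (n * sum(x6^2) - sum(x6)^2)
  b0 <- mean(y6) - b1 * mean(x6)
  res <- y6 - b0 - b1 * x6
  r2 <- 1 - sum(res^2) / sum((y6 - mean(y6))^2)
  fit <- linear_regression(x6, y6)
  expect_equal(fit$slope, b1, tolerance = 1e-12)
  expect_equal(fit$intercept, b0, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  # F-test p from the same sums of squares
  fstat <- (r2 / 1) / ((1 - r2) / (n - 2))
  expect_equal(fit$p_value, pf(fstat, 1, n - 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(linear_regression(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("curve validation flags shifted data and passes exact data", {
  t <- c(2, 4, 10, 20, 30)
  fit <- fit_plateau_decay(tibble::tibble(t = t, value = plateau_curve(t, 100, 0.5, 12)))
  on_curve <- tibble::tibble(t = t, value = predict(fit, t))
  v <- validate_against_curve(fit, on_curve)
  expect_identical(v$p_value, 1)
  expect_equal(attr(v, "residuals")$residual, rep(0, 5))

  # a +50% shift on a shallow curve: hand-computed one-sample t-test
  fit2 <- fit_plateau_decay(tibble::tibble(t = t, value = plateau_curve(t, 100, 0.5, 60)))
  shifted <- tibble::tibble(t = t, value = 1.5 * predict(fit2, t))
  v2 <- validate_against_curve(fit2, shifted)
  r <- 0.5 * predict(fit2, t)
  t_stat <- mean(r) / (sd(r) / sqrt(length(r)))
  expect_equal(v2$p_value, 2 * pt(-abs(t_stat), df = length(r) - 1),
               tolerance = 1e-9)
  expect_lt(v2$p_value, 0.05)
  expect_error(validate_against_curve(fit, on_curve[1:2, ]), "at least 3")
})

test_that("the residual test holds its nominal type-I error rate", {
  t <- c(2, 4, 10, 20, 30)
  fit <- fit_plateau_decay(tibble::tibble(t = t, value = plateau_curve(t, 100, 0.5, 12)))
  rng <- cascade_rng(606)
  rejections <- vapply(1:200, function(i) {
    means <- predict(fit, t) + vapply(t, function(.) rng_normal(rng, 0, 3),
                                      numeric(1))
    validate_against_curve(fit, tibble::tibble(t = t, value = pmax(means, 0)))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.12)
})

test_that("split-age fits recover piecewise half-lives and police point counts", {
  tt <- c(50, 200, 500, 600, 900, 5000, 12000, 20000)
  vv <- ifelse(tt < 730, 100 * exp(-log(2) / 191 * tt),
               30 * exp(-log(2) / 9131 * tt))
  pts <- tibble::tibble(t = tt, value = vv)
  sf <- split_age_fit(pts, 730)
  expect_rel_equal(sf$young$half_life, 191, 1e-6)
  expect_rel_equal(sf$old$half_life, 9131, 1e-6)
  expect_error(split_age_fit(pts, 201), "below split")
  expect_error(split_age_fit(pts, 20001), "at or above")

  # brute-force split search lands on the planted breakpoint
  candidates <- c(550, 730, 2000)
  rss <- vapply(candidates, function(s) split_age_fit(pts, s)$rss, numeric(1))
  expect_equal(candidates[which.min(rss)], 730)
})

test_that("tidy/glance/augment expose the fit in tabular form", {
  t <- c(2, 4, 10, 30)
  fit <- fit_plateau_decay(tibble::tibble(t = t, value = plateau_curve(t, 100, 0.5, 10)))
  td <- tidy(fit)
  expect_equal(td$term, c("Y0", "K", "plateau"))
  gl <- glance(fit)
  expect_equal(gl$n_points, 4L)
  expect_true(is.na(gl$aicc))  # correction undefined at n = 4 with 3 params
  expect_equal(nrow(augment(fit)), 4)
})
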