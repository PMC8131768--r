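# Logistic mortality curves, LC50 extraction, and population comparison.

test_that("symmetric mortality data put the MLE curve at its center dose", {
  # deaths mirror-symmetric about 10 ppt under d -> 20 - d, m -> 1 - m,
  # so the unique logit-linear MLE is centered there
  ds <- toy_tolerance(c(0, 5, 10, 15, 20), deaths = c(0, 1, 5, 9, 10))
  fit <- fit_mortality_curve(ds, 48)
  expect_true(fit$converged)
  expect_equal(fit$lc50, 10, tolerance = 1e-5)
  oracle <- logistic_nll_oracle(
    ds$records$salinity, ds$records$n_initial - ds$records$alive_48,
    ds$records$alive_48)
  expect_equal(c(fit$beta0, fit$beta1), oracle$par, tolerance = 1e-3)
})

test_that("fitted coefficients match the likelihood-optimizer oracle on
           randomized instances and LC50 is exactly -b0/b1", {
  set.seed(401)
  done <- 0
  attempt <- 0
  while (done < 20 && attempt < 200) {
    attempt <- attempt + 1
    doses <- sort(sample(0:30, sample(4:6, 1)))
    lc50 <- runif(1, 5, 20)
    slope <- runif(1, 0.2, 0.8)
    deaths <- rbinom(length(doses), 10, plogis(slope * (doses - lc50)))
    if (!well_posed_tolerance(deaths)) next
    ds <- toy_tolerance(doses, deaths)
    fit <- fit_mortality_curve(ds, 48)
    if (!fit$converged) next
    done <- done + 1
    oracle <- logistic_nll_oracle(
      doses, deaths, 10 - deaths,
      start = c(-0.3 * lc50, 0.3))
    expect_equal(c(fit$beta0, fit$beta1), unname(oracle$par),
                 tolerance = 1e-3)
    expect_identical(fit$lc50, -fit$beta0 / fit$beta1)
    expect_equal(lc50_from_fit(fit$beta0, fit$beta1), fit$lc50)
  }
  expect_gte(done, 20)
})

test_that("LC50 closed form follows the logit root and rejects zero slope", {
  expect_equal(lc50_from_fit(-10, 2), 5)
  expect_equal(lc50_from_fit(0, 1), 0)
  expect_equal(lc50_from_fit(-4, 0.5), 8)
  expect_error(lc50_from_fit(1, 0), "zero slope")
})

test_that("complete separation is flagged instead of trusted", {
  all_dead <- toy_tolerance(c(0, 5, 10), deaths = c(10, 10, 10))
  fit <- fit_mortality_curve(all_dead, 48)
  expect_true(fit$separated)
  expect_false(fit$converged)
  step <- toy_tolerance(c(0, 5, 15, 20), deaths = c(0, 0, 10, 10))
  expect_true(fit_mortality_curve(step, 48)$separated)
  expect_error(fit_mortality_curve(
    toy_tolerance(c(5, 5), deaths = c(2, 3)), 48), "2 distinct")
})

test_that("delta and Fieller intervals bracket the estimate and SE shrinks
           with group size", {
  ds <- toy_tolerance(c(0, 3, 6, 9, 12, 15), deaths = c(0, 1, 3, 7, 9, 10))
  fit <- fit_mortality_curve(ds, 48)
  ci <- lc50_confidence_interval(fit)
  expect_equal(ci$lo, fit$lc50 - qnorm(0.975) * fit$lc50_se)
  expect_equal(ci$hi, fit$lc50 + qnorm(0.975) * fit$lc50_se)
  cf <- lc50_confidence_interval(fit, method = "fieller")
  expect_true(cf$lo < fit$lc50 && fit$lc50 < cf$hi)
  expect_equal(c(cf$lo, cf$hi), c(ci$lo, ci$hi), tolerance = 0.15)

  doubled <- ds
  doubled$records$n_initial <- 20L
  doubled$records$alive_48 <- ds$records$alive_48 * 2L
  doubled$records$alive_72 <- ds$records$alive_72 * 2L
  doubled$records$alive_96 <- ds$records$alive_96 * 2L
  fit2 <- fit_mortality_curve(doubled, 48)
  expect_lt(fit2$lc50_se, fit$lc50_se)
})

test_that("LC50 estimation error shrinks as replication grows", {
  errs <- sapply(c(5, 50), function(reps) {
    fits <- sapply(1:50, function(i) {
      cfg <- tol_sim_config(true_lc50 = c(FW = 8.69), replicates = reps,
                            seed = 7000 + i)
      fit_mortality_curve(simulate_tolerance(cfg), 48)$lc50
    })
    median(abs(fits - 8.69))
  })
  expect_lt(errs[2], errs[1])
})

test_that("population comparison ANCOVA is null on relabeled copies and
           matches a direct least-squares R2", {
  base <- simulate_tolerance(tol_sim_config(true_lc50 = c(FW = 8.69),
                                            seed = 31))
  rec <- base$records
  rec2 <- rec
  rec2$population <- "BW"
  rec2$replicate_id <- paste0(rec2$replicate_id, "_copy")
  both <- tolerance_dataset(dplyr::bind_rows(rec, rec2))
  cmp <- lc50_comparison_model(both, 48)
  pop_rows <- grepl("population", cmp$terms$term)
  expect_true(all(cmp$terms$sum_sq[pop_rows] < 1e-20))
  expect_true(all(cmp$terms$p[pop_rows] > 0.999))

  mixed <- simulate_tolerance(tol_sim_config(seed = 32))
  cmp2 <- lc50_comparison_model(mixed, 48)
  d <- mixed$records
  X <- stats::model.matrix(~ salinity * factor(population), data = d)
  y <- d$alive_48 / d$n_initial
  beta <- qr.coef(qr(X), y)
  sse <- sum((y - drop(X %*% beta))^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(cmp2$r2, 1 - sse / sst, tolerance = 1e-10)

  expect_error(lc50_comparison_model(base, 48), "two populations")
})

test_that("a true 5 ppt tolerance gap is detected in most replicate
           experiments", {
  hits <- sapply(1:200, function(i) {
    cfg <- tol_sim_config(true_lc50 = c(FW = 8.69, BW = 13.69),
                          seed = 5000 + i)
    cmp <- lc50_comparison_model(simulate_tolerance(cfg), 48)
    rows <- grepl("population", cmp$terms$term)
    any(cmp$terms$p[rows] < 0.05)
  })
  expect_gte(mean(hits), 0.90)
})

test_that("the fitted mortality curve is strictly increasing in dose when
           the slope is positive", {
  ds <- toy_tolerance(c(0, 3, 6, 9, 12, 15), deaths = c(0, 1, 3, 7, 9, 10))
  fit <- fit_mortality_curve(ds, 48)
  expect_gt(fit$beta1, 0)
  grid <- plogis(fit$beta0 + fit$beta1 * seq(0, 33, by = 0.5))
  expect_true(all(diff(grid) > 0))
})
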