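# ANOVA, Tukey HSD, factorial models, logistic survival, Welch's test.

test_that("one-way ANOVA matches hand arithmetic and closed form", {
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(a$terms$sum_sq, 54)
  expect_equal(a$residual$sum_sq, 6)
  expect_equal(a$terms$df, 2)
  expect_equal(a$residual$df, 6)
  expect_equal(a$terms$statistic, 27)
  expect_equal(a$total_sum_sq, 60)

  flat <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(flat$terms$statistic, 0)
  expect_equal(flat$terms$p, 1)

  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(anova_oneway(g[c(3, 1, 2)])$terms[-1], a$terms[-1])
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
})

test_that("ANOVA agrees with the classical closed form across random
           designs", {
  set.seed(501)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:10, 1), j / 2))
    a <- anova_oneway(groups)
    means <- vapply(groups, mean, numeric(1))
    ns <- vapply(groups, length, integer(1))
    gm <- sum(means * ns) / sum(ns)
    ssb <- sum(ns * (means - gm)^2)
    ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
    f <- (ssb / (k - 1)) / (ssw / (sum(ns) - k))
    expect_equal(a$terms$sum_sq, ssb)
    expect_equal(a$residual$sum_sq, ssw)
    expect_equal(a$terms$statistic, f)
    expect_equal(a$terms$p, pf(f, k - 1, sum(ns) - k, lower.tail = FALSE))
  }
})

test_that("Tukey HSD reduces to the pooled t-test for two groups and
           matches stats::TukeyHSD", {
  set.seed(502)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  res <- tukey_hsd(list(a = x, b = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$pairs$adjusted_p, tt$p.value, tolerance = 1e-8)
  expect_equal(res$pairs$q_statistic, abs(tt$statistic) * sqrt(2),
               ignore_attr = TRUE)

  groups <- list(a = rnorm(6), b = rnorm(7, 1), c = rnorm(5, 3))
  res3 <- tukey_hsd(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- TukeyHSD(aov(y ~ g, data = df))$g
  expect_equal(res3$pairs$adjusted_p,
               unname(ref[c("b-a", "c-a", "c-b"), "p adj"]),
               tolerance = 1e-6)

  shifted <- tukey_hsd(list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 50))
  sig_c <- shifted$pairs$significant[shifted$pairs$group_a == "c" |
                                       shifted$pairs$group_b == "c"]
  expect_true(all(sig_c))
  letters <- tukey_letters(shifted)
  expect_equal(letters[["a"]], letters[["b"]])
  expect_false(letters[["c"]] == letters[["a"]])

  expect_error(tukey_hsd(list(a = c(1, 1), b = c(1, 1))), "variance")
})

test_that("factorial model gives exact sequential decompositions", {
  # additive 2x2 design with no noise: interaction SS is exactly 0
  d <- expand.grid(treatment = c(0, 1), origin = c("FW", "BW"),
                   rep = 1:3)
  d$y <- 1 * (d$treatment == 1) + 2 * (d$origin == "BW")
  ft <- suppressWarnings(factorial_lm(d, "y"))  # perfect fit by design
  expect_equal(ft$terms$sum_sq[ft$terms$term == "treatment:origin"], 0)
  expect_equal(sum(ft$terms$sum_sq) + ft$residual$sum_sq, ft$total_sum_sq)

  # with noise the decomposition identity still holds and chisq >= 0
  set.seed(503)
  d$y <- d$y + rnorm(nrow(d))
  ft2 <- factorial_lm(d, "y")
  expect_equal(sum(ft2$terms$sum_sq) + ft2$residual$sum_sq,
               ft2$total_sum_sq)
  expect_true(all(ft2$terms$chisq >= 0))
  expect_true(all(ft2$terms$p >= 0 & ft2$terms$p <= 1))

  # single factor reduces to the one-way table
  groups <- split(d$y, d$treatment)
  one <- anova_oneway(groups)
  red <- factorial_lm(d, "y", origin = NULL, with_interaction = FALSE)
  expect_equal(red$terms$sum_sq, one$terms$sum_sq)
  expect_equal(red$terms$statistic, one$terms$statistic)

  # aliased factor is an error naming the offender
  d$dup <- d$origin
  expect_error(factorial_lm(d, "y", origin = "dup", sex = "origin"),
               "aliased")
})

test_that("Welch test matches hand arithmetic and handles degeneracy", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -sqrt(1.5), tolerance = 1e-10)  # -1.2247
  expect_equal(w$df, 4)
  swapped <- welch_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$t, -w$t)
  expect_equal(swapped$p, w$p)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat_eq <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(flat_eq$t, 0)
  expect_equal(flat_eq$p, 1)
  flat_ne <- welch_t_test(c(3, 3), c(2, 2))
  expect_true(is.infinite(flat_ne$t) && flat_ne$infinite)
  expect_equal(flat_ne$p, 0)
})

flat_garden <- function(seed, p_surv = 0.5,
                        treatments = c(0, 1, 3, 5, 11), boxes = 8) {
  set.seed(seed)
  parts <- list()
  for (trt in treatments) {
    for (b in seq_len(boxes)) {
      m <- rbinom(1, 5, p_surv)
      f <- rbinom(1, 5, p_surv)
      parts[[length(parts) + 1]] <- make_box(
        sprintf("t%g_b%d", trt, b), treatment = trt,
        m_final = m, f_final = f, eggs = 10, offspring = 2)
    }
  }
  do.call(toy_garden, parts)
}

test_that("logistic survival slope CI covers zero under a flat synthetic
           truth", {
  covered <- sapply(1:200, function(i) {
    fit <- logistic_survival_model(flat_garden(8000 + i))
    sl <- fit$coefficients[fit$coefficients$term == "salinity", ]
    (sl$estimate - qnorm(0.975) * sl$se) < 0 &
      (sl$estimate + qnorm(0.975) * sl$se) > 0
  })
  expect_gte(mean(covered), 0.93)
})

test_that("logistic survival shares the mortality engine up to sign and
           recovers sex-specific slopes", {
  tol <- toy_tolerance(c(0, 3, 6, 9, 12), deaths = c(0, 2, 5, 8, 10))
  parts <- lapply(seq_len(nrow(tol$records)), function(i) {
    alive <- tol$records$alive_48[i]
    make_box(tol$records$replicate_id[i],
             treatment = tol$records$salinity[i],
             m_final = min(alive, 5), f_final = max(alive - 5, 0),
             eggs = 0, offspring = 0)
  })
  g <- do.call(toy_garden, parts)
  mort <- fit_mortality_curve(tol, 48)
  surv <- logistic_survival_model(g)
  expect_equal(surv$coefficients$estimate,
               -c(mort$beta0, mort$beta1), tolerance = 1e-6)

  set.seed(99)
  parts <- list()
  for (trt in c(0, 1, 3, 5, 11)) {
    for (b in 1:20) {
      pm <- plogis(1 - 0.2 * trt)
      pf <- plogis(1 - 0.4 * trt)
      parts[[length(parts) + 1]] <- make_box(
        sprintf("s%g_%d", trt, b), treatment = trt,
        m_final = rbinom(1, 5, pm), f_final = rbinom(1, 5, pf),
        eggs = 0, offspring = 0)
    }
  }
  fit <- logistic_survival_model(do.call(toy_garden, parts),
                                 predictors = c("salinity", "sex"))
  inter <- fit$coefficients[grepl(":", fit$coefficients$term), ]
  expect_equal(nrow(inter), 1)
  expect_lt(abs(abs(inter$estimate) - 0.2), 2 * inter$se)

  curve <- logistic_survival_model(flat_garden(42))$curve
  expect_true(all(curve$lo <= curve$fit & curve$fit <= curve$hi))
})
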