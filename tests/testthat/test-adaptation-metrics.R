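# LA / MA indices, trait averages, and trade-off classification.

test_that("the LA index reproduces its defining arithmetic", {
  expect_equal(local_adaptation_index(0.49, 0.35)$la, 0.14 / 0.42)
  expect_equal(local_adaptation_index(77.90, 24.00)$la,
               53.9 / 50.95)
  expect_equal(local_adaptation_index(3, 3)$la, 0)
  expect_equal(local_adaptation_index(0.7, 0)$la, 2)
  expect_equal(local_adaptation_index(0, 0.7)$la, -2)
  und <- local_adaptation_index(0, 0)
  expect_false(und$defined)
  expect_true(is.na(und$la))
  expect_error(local_adaptation_index(-1, 2), "non-negative")
})

test_that("LA is antisymmetric, scale-invariant and bounded in [-2, 2]", {
  set.seed(77)
  w1 <- runif(200, 0, 100)
  w2 <- runif(200, 0, 100)
  la <- local_adaptation_index(w1, w2)$la
  expect_equal(local_adaptation_index(w2, w1)$la, -la)
  k <- runif(200, 0.1, 10)
  expect_equal(local_adaptation_index(k * w1, k * w2)$la, la)
  expect_true(all(abs(la) <= 2))
})

test_that("MA is the proportional shortfall from the standardized ideal", {
  expect_equal(maladaptation_magnitude(0.49, 0.31)$ma, 1 - 0.31 / 0.49)
  expect_equal(maladaptation_magnitude(5, 5)$ma, 0)
  expect_equal(maladaptation_magnitude(5, 0)$ma, 1)
  over <- maladaptation_magnitude(2, 3)
  expect_equal(over$ma, -0.5)
  expect_true(over$exceeds_ideal)
  expect_error(maladaptation_magnitude(0, 1), "positive")
  # invariant to joint rescaling of ideal and realized
  expect_equal(maladaptation_magnitude(4.9, 3.1)$ma,
               maladaptation_magnitude(0.49, 0.31)$ma)
})

test_that("trait averages pool defined LA values", {
  vals <- c(survival = (0.14 - 0.24) / 0.19,
            fecundity = (12 - 18.5) / 15.25,
            oviposition_rate = (0.40 - 0.61) / 0.505,
            n_immatures = (1 - 2.5) / 1.75)
  avg <- trait_average_la(vals)
  expect_equal(avg$average, mean(vals))
  expect_equal(round(avg$average, 2), -0.56)
  expect_equal(avg$traits, names(vals))
  expect_equal(trait_average_la(c(a = 0.4))$average, 0.4)
  expect_equal(trait_average_la(c(-1, 1))$average, 0)
  expect_equal(trait_average_la(c(0.5, NA))$n_traits, 1)
  expect_error(trait_average_la(c(NA_real_, NA_real_)), "no defined")
  expect_error(trait_average_la(numeric(0)), "no LA values")
})

test_that("trade-off quadrants follow the signs of home and foreign LA", {
  expect_equal(classify_tradeoff(0.33, -0.48), "tradeoff_home")
  expect_equal(classify_tradeoff(1.06, 0.21), "no_tradeoff_both")
  expect_equal(classify_tradeoff(-0.2, 0.7), "inverse_tradeoff")
  expect_equal(classify_tradeoff(-0.2, -0.7), "no_tradeoff_neither")
  expect_equal(classify_tradeoff(0, 0), "boundary")
  expect_equal(classify_tradeoff(0.005, -0.4, tol = 0.01), "boundary")
  expect_equal(classify_tradeoff(c(1, -1), c(-1, -1)),
               c("tradeoff_home", "no_tradeoff_neither"))
})

test_that("the adaptation report assembles LA, averages, MA and quadrants
           from cell means", {
  rep <- adaptation_report(reported_fitness_means())
  la_of <- function(pop, site, trait) {
    rep$la$la[rep$la$population == pop & rep$la$site == site &
                rep$la$trait == trait]
  }
  expect_equal(la_of("FW", 0, "n_immatures"), 20 / 18)
  expect_equal(la_of("BW", 1, "survival"), 0.48)
  expect_equal(la_of("FW", 1, "survival"), -0.48)
  home_rows <- rep$la[rep$la$is_home, ]
  expect_setequal(unique(paste(home_rows$population, home_rows$site)),
                  c("FW 0", "BW 1"))
  expect_equal(rep$ma$ma[rep$ma$trait == "survival"], 1 - 0.31 / 0.49)
  # FW shows a home-vs-1ppt trade-off for survival but not fecundity
  to <- rep$tradeoffs
  expect_equal(to$quadrant[to$population == "FW" & to$trait == "survival" &
                             to$site_foreign == 1], "tradeoff_home")
  expect_equal(to$quadrant[to$population == "FW" & to$trait == "fecundity" &
                             to$site_foreign == 1], "no_tradeoff_both")

  empty <- adaptation_report(reported_fitness_means()[0, ])
  expect_equal(nrow(empty$la), 0)
  expect_equal(nrow(empty$ma), 0)

  missing_cell <- reported_fitness_means() |>
    dplyr::filter(!(population == "BW" & treatment == 3 &
                      trait == "fecundity"))
  # both populations lose that cell's LA, one warning each
  expect_warning(expect_warning(part <- adaptation_report(missing_cell),
                                "missing cell"), "missing cell")
  expect_equal(nrow(part$la[part$la$site == 3 &
                              part$la$trait == "fecundity", ]), 0)
})
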