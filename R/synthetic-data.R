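# Synthetic experiment generators with known ground truth, emulating the
# two designs: acute tolerance assays (9 salinity levels x 5 replicate
# boxes x 10 adults, censused at 48/72/96 hr) and 30-day common-garden
# boxes (5 males + 5 females per box, F1 followed to day 90).
#
# A single integer master seed drives everything; each box draws from a
# deterministic substream so changing the box count never reshuffles
# earlier boxes.

substream_seed <- function(master, index) {
  # double arithmetic is exact here and keeps the result below 2^31
  as.integer((as.numeric(master %% 2097143) * 1021 +
                as.numeric(index)) %% 2147483647)
}

with_substream <- function(master, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, index))
  force(expr)
}

#' Configuration for the tolerance-assay generator
#'
#' Individuals die by the 48-hr census with probability
#' `plogis(slope * (dose - true_lc50))`; survivors are exposed to the
#' same dose-dependent hazard, scaled by `hazard_scale`, over each of
#' the following 24-hr intervals (72 and 96 hr). The defaults reproduce
#' the reported study conditions: 48-hr LC50s of 8.69 ppt (FW) and
#' 10.58 ppt (BW), nine doses from freshwater to seawater, five
#' replicate boxes of ten adults. With `slope = 0.35` per ppt and
#' `hazard_scale = 1` the implied 72/96-hr LC50s fall to roughly 6 and
#' 5 ppt, matching the reported decline over exposure time.
#'
#' @param true_lc50 Named numeric vector of true 48-hr LC50s (ppt) per
#'   population.
#' @param slope Logistic slope per ppt (> 0).
#' @param doses Salinity levels in ppt.
#' @param replicates Replicate boxes per dose.
#' @param n_per_replicate Adults per box.
#' @param hazard_scale Multiplier on the 48-hr death probability applied
#'   per following 24-hr interval (>= 0).
#' @param seed Integer master seed.
#' @return List of class `tol_sim_config`.
#' @export
tol_sim_config <- function(true_lc50 = c(FW = 8.69, BW = 10.58),
                           slope = 0.35,
                           doses = c(0, 1, 3, 5, 10, 15, 20, 25, 33),
                           replicates = 5, n_per_replicate = 10,
                           hazard_scale = 1, seed = 1) {
  stopifnot(slope > 0, all(doses >= 0), replicates >= 1,
            n_per_replicate >= 1, hazard_scale >= 0,
            length(true_lc50) >= 1, !is.null(names(true_lc50)))
  structure(list(true_lc50 = true_lc50, slope = slope, doses = doses,
                 replicates = replicates, n_per_replicate = n_per_replicate,
                 hazard_scale = hazard_scale, seed = seed),
            class = "tol_sim_config")
}

#' Simulate a salinity-tolerance experiment
#'
#' @param cfg A [tol_sim_config()].
#' @return A [tolerance_dataset()]; identical config and seed give an
#'   identical dataset.
#' @export
simulate_tolerance <- function(cfg) {
  stopifnot(inherits(cfg, "tol_sim_config"))
  rows <- list()
  for (pop in names(cfg$true_lc50)) {
    lc50 <- cfg$true_lc50[[pop]]
    pop_i <- match(pop, names(cfg$true_lc50))
    for (dose in cfg$doses) {
      dose_i <- match(dose, cfg$doses)
      p48 <- plogis(cfg$slope * (dose - lc50))
      q_interval <- min(1, cfg$hazard_scale * p48)
      for (r in seq_len(cfg$replicates)) {
        # substream index keyed to (population, dose, replicate) so a
        # larger design never reshuffles earlier replicates
        idx <- ((pop_i - 1) * length(cfg$doses) + (dose_i - 1)) * 1e5 + r
        counts <- with_substream(cfg$seed, idx, {
          n <- cfg$n_per_replicate
          a48 <- n - rbinom(1, n, p48)
          a72 <- rbinom(1, a48, 1 - q_interval)
          a96 <- rbinom(1, a72, 1 - q_interval)
          c(a48, a72, a96)
        })
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate_id = sprintf("%s_d%g_r%d", pop, dose, r),
          population = pop, salinity = dose,
          n_initial = cfg$n_per_replicate,
          alive_48 = counts[1], alive_72 = counts[2], alive_96 = counts[3])
      }
    }
  }
  tolerance_dataset(dplyr::bind_rows(rows),
                    metadata = list(seed = cfg$seed,
                                    generator = "simulate_tolerance",
                                    true_lc50 = cfg$true_lc50,
                                    slope = cfg$slope))
}

#' Configuration for the common-garden generator
#'
#' Each box holds `n_males` + `n_females` adults; every adult dies each
#' day with its sex- and cell-specific probability. While at least one
#' female is alive (unless decoupled), the box lays a count of eggs per
#' day drawn from an overdispersed count distribution with the cell's
#' mean rate and `variance = mean * (1 + phi)` (`phi = 0` gives Poisson).
#' Offspring are a binomial thinning of the total eggs, and F1
#' individuals then die daily with the cell's F1 probability until day
#' `f1_days`, survivors censored there.
#'
#' @param cells Tibble with one row per population x treatment:
#'   `population`, `treatment`, `n_boxes`, `male_daily_death`,
#'   `female_daily_death`, `egg_rate`, `egg_phi`, `offspring_frac`,
#'   `f1_daily_death`.
#' @param n_males,n_females Adults stocked per box (default 5 + 5).
#' @param adult_days Adult observation window in days (default 30).
#' @param f1_days F1 follow-up horizon in days (default 90).
#' @param eggs_require_female If `TRUE` (default) egg laying requires at
#'   least one surviving female, coupling survival to fecundity; set
#'   `FALSE` to decouple them for null tests.
#' @param seed Integer master seed.
#' @return List of class `garden_sim_config`.
#' @export
garden_sim_config <- function(cells, n_males = 5, n_females = 5,
                              adult_days = 30, f1_days = 90,
                              eggs_require_female = TRUE, seed = 1) {
  cells <- tibble::as_tibble(cells)
  needed <- c("population", "treatment", "n_boxes", "male_daily_death",
              "female_daily_death", "egg_rate", "egg_phi",
              "offspring_frac", "f1_daily_death")
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0) {
    stop("cells table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  probs <- c(cells$male_daily_death, cells$female_daily_death,
             cells$offspring_frac, cells$f1_daily_death)
  stopifnot(all(probs >= 0 & probs <= 1), all(cells$egg_rate >= 0),
            all(cells$egg_phi >= 0), all(cells$n_boxes >= 1),
            n_males >= 0, n_females >= 0, adult_days >= 1, f1_days >= 1)
  structure(list(cells = cells, n_males = n_males, n_females = n_females,
                 adult_days = adult_days, f1_days = f1_days,
                 eggs_require_female = eggs_require_female, seed = seed),
            class = "garden_sim_config")
}

draw_eggs <- function(n_days, rate, phi) {
  if (n_days == 0 || rate == 0) return(integer(n_days))
  if (phi == 0) {
    rpois(n_days, rate)
  } else {
    rnbinom(n_days, size = rate / phi, mu = rate)
  }
}

#' Simulate a common-garden experiment
#'
#' @param cfg A [garden_sim_config()], e.g. from
#'   [calibrated_garden_config()].
#' @return A [garden_dataset()]; identical config and seed give an
#'   identical dataset. The generating cell table is stored in the
#'   metadata as `truth`.
#' @export
simulate_garden <- function(cfg) {
  stopifnot(inherits(cfg, "garden_sim_config"))
  boxes <- list(); daily <- list(); f1 <- list()
  idx <- 0L
  for (ci in seq_len(nrow(cfg$cells))) {
    cell <- cfg$cells[ci, ]
    for (bx in seq_len(cell$n_boxes)) {
      idx <- idx + 1L
      box_id <- sprintf("%s_t%g_b%02d", cell$population, cell$treatment, bx)
      # substream keyed to (cell, box) so adding boxes to a later cell
      # never reshuffles earlier ones
      sim <- with_substream(cfg$seed, (ci - 1) * 1e5 + bx, {
        m <- integer(cfg$adult_days + 1); f <- integer(cfg$adult_days + 1)
        m[1] <- cfg$n_males; f[1] <- cfg$n_females
        for (t in seq_len(cfg$adult_days)) {
          m[t + 1] <- rbinom(1, m[t], 1 - cell$male_daily_death)
          f[t + 1] <- rbinom(1, f[t], 1 - cell$female_daily_death)
        }
        lay_days <- if (cfg$eggs_require_female) {
          which(f[-1] >= 1)
        } else {
          seq_len(cfg$adult_days)
        }
        eggs_by_day <- integer(cfg$adult_days)
        eggs_by_day[lay_days] <- draw_eggs(length(lay_days), cell$egg_rate,
                                           cell$egg_phi)
        eggs_total <- sum(eggs_by_day)
        n_off <- rbinom(1, eggs_total, cell$offspring_frac)
        a <- integer(cfg$f1_days + 1)
        a[1] <- n_off
        for (t in seq_len(cfg$f1_days)) {
          a[t + 1] <- rbinom(1, a[t], 1 - cell$f1_daily_death)
        }
        list(m = m, f = f, eggs_total = eggs_total, n_off = n_off, f1 = a)
      })
      boxes[[idx]] <- tibble::tibble(
        box_id = box_id, origin = cell$population,
        treatment = cell$treatment, n_males = cfg$n_males,
        n_females = cfg$n_females, eggs_total = sim$eggs_total,
        days_observed = cfg$adult_days, n_offspring = sim$n_off)
      daily[[idx]] <- tibble::tibble(
        box_id = box_id,
        day = rep(0:cfg$adult_days, 2),
        sex = rep(c("M", "F"), each = cfg$adult_days + 1),
        n_alive = c(sim$m, sim$f))
      deaths <- -diff(sim$f1)
      days <- which(deaths > 0)
      ev_days <- rep(days, deaths[days])
      surv <- sim$f1[cfg$f1_days + 1]
      if (length(ev_days) > 0 || surv > 0) {
        f1[[length(f1) + 1]] <- tibble::tibble(
          box_id = box_id,
          day = c(ev_days, rep(cfg$f1_days, surv)),
          status = c(rep("death", length(ev_days)),
                     rep("censored", surv)))
      }
    }
  }
  f1_tbl <- dplyr::bind_rows(f1)
  garden_dataset(dplyr::bind_rows(boxes), dplyr::bind_rows(daily),
                 if (ncol(f1_tbl) > 0) f1_tbl else NULL,
                 metadata = list(seed = cfg$seed,
                                 generator = "simulate_garden",
                                 truth = cfg$cells))
}

expected_laying_days <- function(female_daily_death, n_females, adult_days) {
  s <- 1 - female_daily_death
  sum(1 - (1 - s^seq_len(adult_days))^n_females)
}

#' Expected cell means implied by a garden configuration
#'
#' Analytic expectations of the fitness surrogates under the generator:
#' the ground truth that estimated summaries and the adaptation indices
#' computed from them should recover.
#'
#' @param cfg A [garden_sim_config()].
#' @return Tibble `population`, `treatment`, `trait`, `mean` covering
#'   the six traits.
#' @export
expected_cell_means <- function(cfg) {
  stopifnot(inherits(cfg, "garden_sim_config"))
  rows <- list()
  denom <- cfg$n_males + cfg$n_females
  for (ci in seq_len(nrow(cfg$cells))) {
    cell <- cfg$cells[ci, ]
    sm <- (1 - cell$male_daily_death)^cfg$adult_days
    sf <- (1 - cell$female_daily_death)^cfg$adult_days
    e_days <- if (cfg$eggs_require_female) {
      expected_laying_days(cell$female_daily_death, cfg$n_females,
                           cfg$adult_days)
    } else {
      cfg$adult_days
    }
    fec <- cell$egg_rate * e_days
    rows[[ci]] <- tibble::tibble(
      population = cell$population, treatment = cell$treatment,
      trait = FITNESS_TRAITS,
      mean = c((cfg$n_males * sm + cfg$n_females * sf) / denom,
               cfg$n_males * sm / denom,
               cfg$n_females * sf / denom,
               fec,
               fec / cfg$adult_days,
               fec * cell$offspring_frac))
  }
  dplyr::bind_rows(rows)
}

#' Garden configuration calibrated to reported cell means
#'
#' Inverts the generator's expectations so that every cell's expected
#' fitness surrogates equal a table of target means (by default the
#' reported study means, [reported_fitness_means()]): per-sex daily
#' death probabilities from the sex-specific 30-day survival ratios
#' (whole-box denominator, so per-sex survival is twice the ratio under
#' the 5 + 5 design), the egg rate from the fecundity target divided by
#' the expected number of laying days, and the offspring fraction from
#' the immatures/fecundity ratio.
#'
#' @param means Target means in the [summarize_traits()] shape; must
#'   include `survival_male`, `survival_female`, `fecundity`, and
#'   `n_immatures` rows per cell.
#' @param egg_phi Overdispersion of the daily egg counts
#'   (`variance = mean * (1 + phi)`); default 5, reflecting the strongly
#'   overdispersed box-level egg totals in the reported data.
#' @param f1_daily_death Daily F1 death probability (default 0.02; F1
#'   longevity has no reported calibration target).
#' @param seed Integer master seed.
#' @inheritParams garden_sim_config
#' @return A [garden_sim_config()] whose [expected_cell_means()] equal
#'   the targets.
#' @export
calibrated_garden_config <- function(means = reported_fitness_means(),
                                     egg_phi = 5, f1_daily_death = 0.02,
                                     n_males = 5, n_females = 5,
                                     adult_days = 30, f1_days = 90,
                                     seed = 1) {
  means <- tibble::as_tibble(means)
  denom <- n_males + n_females
  wide <- tidyr::pivot_wider(means[, c("population", "treatment", "trait",
                                       "mean")],
                             names_from = "trait", values_from = "mean")
  n_tbl <- means |>
    dplyr::group_by(.data$population, .data$treatment) |>
    dplyr::summarise(n_boxes = max(.data$n_boxes), .groups = "drop")
  wide <- dplyr::left_join(wide, n_tbl, by = c("population", "treatment"))
  needed <- c("survival_male", "survival_female", "fecundity", "n_immatures")
  missing <- setdiff(needed, names(wide))
  if (length(missing) > 0) {
    stop("calibration needs trait(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  surv_m <- wide$survival_male * denom / n_males
  surv_f <- wide$survival_female * denom / n_females
  if (any(surv_m > 1) || any(surv_f > 1)) {
    stop("sex-specific survival targets exceed 1 after rescaling to the ",
         "per-sex denominator", call. = FALSE)
  }
  pf <- 1 - surv_f^(1 / adult_days)
  e_days <- vapply(pf, expected_laying_days, numeric(1),
                   n_females = n_females, adult_days = adult_days)
  cells <- tibble::tibble(
    population = wide$population,
    treatment = wide$treatment,
    n_boxes = wide$n_boxes,
    male_daily_death = 1 - surv_m^(1 / adult_days),
    female_daily_death = pf,
    egg_rate = ifelse(e_days > 0, wide$fecundity / e_days, 0),
    egg_phi = egg_phi,
    offspring_frac = ifelse(wide$fecundity > 0,
                            pmin(1, wide$n_immatures / wide$fecundity), 0),
    f1_daily_death = f1_daily_death)
  garden_sim_config(cells, n_males = n_males, n_females = n_females,
                    adult_days = adult_days, f1_days = f1_days, seed = seed)
}
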