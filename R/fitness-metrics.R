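# Per-box fitness surrogates and population x treatment summaries.
#
# The four surrogates are adult survival (survivors / initial adults in
# the box), fecundity (total eggs), oviposition rate (eggs per day of
# the observation window), and number of immatures (F1 juveniles before
# wing development). Sex-specific survival keeps the whole-box
# denominator so that male + female ratios add up to the overall value.

FITNESS_TRAITS <- c("survival", "survival_male", "survival_female",
                    "fecundity", "oviposition_rate", "n_immatures")

#' Adult survival ratio for one box
#'
#' Survivors at the horizon day divided by the total number of adults
#' initially stocked in the box. The sex-specific variant divides the
#' sex-specific survivor count by the same whole-box denominator, so the
#' male and female ratios sum to the overall ratio.
#'
#' @param ds A [garden_dataset()].
#' @param box_id Box identifier.
#' @param horizon_day Census day at which survival is read (default 30).
#' @param sex `NULL` for overall, `"M"` or `"F"` for a sex-specific ratio.
#' @return A fraction in `[0, 1]`.
#' @export
survival_ratio <- function(ds, box_id, horizon_day = 30, sex = NULL) {
  stopifnot(inherits(ds, "garden_dataset"))
  i <- match(box_id, ds$boxes$box_id)
  if (is.na(i)) stop("unknown box_id: ", box_id, call. = FALSE)
  denom <- ds$boxes$n_males[i] + ds$boxes$n_females[i]
  if (denom == 0) stop("box ", box_id, " has no initial adults", call. = FALSE)
  d <- ds$daily[ds$daily$box_id == box_id & ds$daily$day == horizon_day, ]
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  want <- if (is.null(sex)) 2L else 1L
  if (nrow(d) < want) {
    stop("no census at day ", horizon_day, " for box ", box_id,
         call. = FALSE)
  }
  sum(d$n_alive) / denom
}

#' Oviposition rate for one box
#'
#' Eggs per day over the box's observation window.
#'
#' @param eggs_total Total eggs laid in the box.
#' @param days_observed Length of the observation window (>= 1 day).
#' @return Eggs per day.
#' @export
oviposition_rate <- function(eggs_total, days_observed) {
  if (any(days_observed < 1)) {
    stop("days_observed must be at least 1", call. = FALSE)
  }
  eggs_total / days_observed
}

#' Per-box fitness surrogates
#'
#' @param ds A [garden_dataset()].
#' @param horizon_day Survival horizon (default 30).
#' @return Tibble with one row per box: `box_id`, `population`,
#'   `treatment`, and the six traits.
#' @export
box_fitness <- function(ds, horizon_day = 30) {
  stopifnot(inherits(ds, "garden_dataset"))
  b <- ds$boxes
  tibble::tibble(
    box_id = b$box_id,
    population = b$origin,
    treatment = b$treatment,
    survival = vapply(b$box_id, function(id)
      survival_ratio(ds, id, horizon_day), numeric(1)),
    survival_male = vapply(b$box_id, function(id)
      survival_ratio(ds, id, horizon_day, sex = "M"), numeric(1)),
    survival_female = vapply(b$box_id, function(id)
      survival_ratio(ds, id, horizon_day, sex = "F"), numeric(1)),
    fecundity = as.numeric(b$eggs_total),
    oviposition_rate = oviposition_rate(b$eggs_total, b$days_observed),
    n_immatures = as.numeric(b$n_offspring))
}

#' Summarize fitness surrogates per population x treatment
#'
#' One row per population x treatment x trait with the number of boxes,
#' the mean, and the standard error (sample SD / sqrt(n)). Values are
#' kept at full precision; rounding is a rendering concern. Cells with a
#' single box get `se = 0` with a degenerate-cell warning; empty cells
#' are simply absent.
#'
#' @param ds A [garden_dataset()].
#' @param horizon_day Survival horizon (default 30).
#' @return Tibble `population`, `treatment`, `trait`, `n_boxes`, `mean`,
#'   `se`, ordered by population, treatment, then trait.
#' @export
summarize_traits <- function(ds, horizon_day = 30) {
  per_box <- box_fitness(ds, horizon_day)
  long <- tidyr::pivot_longer(per_box, cols = dplyr::all_of(FITNESS_TRAITS),
                              names_to = "trait", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$population, .data$treatment, .data$trait) |>
    dplyr::summarise(
      n_boxes = dplyr::n(),
      mean = mean(.data$value),
      se = ifelse(dplyr::n() > 1, sd(.data$value) / sqrt(dplyr::n()), 0),
      .groups = "drop")
  degenerate <- out[out$n_boxes == 1, ]
  if (nrow(degenerate) > 0) {
    warning("single-box cell(s), SE reported as 0: ",
            paste(unique(paste0(degenerate$population, "@",
                                degenerate$treatment)), collapse = ", "),
            call. = FALSE)
  }
  out$trait <- factor(out$trait, levels = FITNESS_TRAITS)
  out <- dplyr::arrange(out, .data$population, .data$treatment, .data$trait)
  out$trait <- as.character(out$trait)
  out
}

#' Read a pre-aggregated fitness-means table
#'
#' Accepts a CSV with columns `population`, `treatment`, `trait`,
#' `n_boxes`, `mean`, `se` — the same shape [summarize_traits()]
#' produces — so published cell means can be fed to the adaptation
#' metrics directly, bypassing box-level data.
#'
#' @param path Path to the CSV file.
#' @return Tibble in the summary shape.
#' @export
read_fitness_means <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("population", "treatment", "trait", "n_boxes", "mean", "se")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$trait), FITNESS_TRAITS)
  if (length(bad) > 0) {
    stop("unknown trait(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$mean < 0) || any(df$se < 0)) {
    stop("means and SEs must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Reported common-garden fitness means for the two study populations
#'
#' The mean and standard error of each fitness surrogate per population
#' (freshwater-origin FW, brackish-origin BW) and salinity treatment
#' (0 = FW water, 1, 3, 5 ppt), as reported for wild-derived
#' *Telmatometra withei* populations from Panama. These cell means are
#' the inputs to the local-adaptation and maladaptation indices and the
#' calibration targets of [calibrated_garden_config()].
#'
#' @return Tibble `population`, `treatment`, `trait`, `n_boxes`, `mean`,
#'   `se`.
#' @export
reported_fitness_means <- function() {
  read_fitness_means(system.file("extdata", "garden_fitness_means.csv",
                                 package = "osmofit", mustWork = TRUE))
}
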