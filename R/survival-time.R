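# Kaplan-Meier product-limit estimation of time-to-death for adults
# (censored alive at day 30 when removed) and F1 offspring (followed to
# day 90, survivors censored there), with median survival time.

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimate of the survivor function with Greenwood
#' standard errors; deaths are processed before censorings at tied
#' times (the standard convention).
#'
#' @param events Data frame with columns `day` (>= 0) and `status`
#'   (`"death"`/`"censored"`, or 1/0).
#' @return List of class `km_curve`: `curve` tibble (`time`, `at_risk`,
#'   `deaths`, `censored`, `s_hat`, `greenwood_se`), `n`, `median_day`
#'   (NA when the curve never reaches 0.5), `last_followup`.
#' @export
kaplan_meier <- function(events) {
  events <- as.data.frame(events)
  if (nrow(events) == 0) stop("no event records supplied", call. = FALSE)
  if (!all(c("day", "status") %in% names(events))) {
    stop("events need columns 'day' and 'status'", call. = FALSE)
  }
  if (any(events$day < 0)) stop("event days must be >= 0", call. = FALSE)
  status01 <- if (is.numeric(events$status)) {
    as.integer(events$status)
  } else {
    match <- events$status %in% c("death", "censored")
    if (!all(match)) {
      stop("status must be 'death' or 'censored'", call. = FALSE)
    }
    as.integer(events$status == "death")
  }
  fit <- survival::survfit(survival::Surv(events$day, status01) ~ 1)
  curve <- tibble::tibble(
    time = fit$time,
    at_risk = fit$n.risk,
    deaths = fit$n.event,
    censored = fit$n.censor,
    s_hat = fit$surv,
    greenwood_se = fit$surv * fit$std.err)
  curve$greenwood_se[!is.finite(curve$greenwood_se)] <- 0
  hit <- curve$time[curve$s_hat <= 0.5 & curve$deaths > 0]
  median_day <- if (length(hit) > 0) min(hit) else NA_real_
  structure(list(curve = curve, n = nrow(events), median_day = median_day,
                 last_followup = max(events$day)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median_day)) {
    paste0(">= last follow-up day (", x$last_followup, ")")
  } else {
    paste0(x$median_day, " days")
  }
  cat(sprintf("<km_curve> n = %d, median survival %s\n", x$n, med))
  invisible(x)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Smallest event day at which the estimated survivor function is
#' <= 0.5. When the curve never reaches 0.5, `NA` is returned and the
#' cohort's median survival is reported as at least the last follow-up
#' day.
#'
#' @param curve A [kaplan_meier()] result.
#' @return Day (numeric) or `NA`.
#' @export
median_survival_time <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$median_day
}

#' Kaplan-Meier curves per population x treatment of a garden experiment
#'
#' Individuals are pooled across boxes within each population x
#' treatment cell. For the adult cohort, per-day deaths are recovered
#' from the daily census differences and adults alive at the end of the
#' observation window are censored there (they are removed from the
#' boxes); for the F1 cohort the recorded longevity events (deaths, or
#' censoring at day 90) are used directly.
#'
#' @param ds A [garden_dataset()].
#' @param cohort `"adults"` or `"f1"`.
#' @return List of class `km_set`: `curves` long tibble (`population`,
#'   `treatment`, `time`, `at_risk`, `deaths`, `censored`, `s_hat`,
#'   `greenwood_se`) and `medians` tibble (`population`, `treatment`,
#'   `n`, `median_day`, `last_followup`).
#' @export
garden_km <- function(ds, cohort = c("adults", "f1")) {
  stopifnot(inherits(ds, "garden_dataset"))
  cohort <- match.arg(cohort)
  b <- ds$boxes
  cells <- unique(b[, c("origin", "treatment")])
  curves <- list()
  medians <- list()
  for (i in seq_len(nrow(cells))) {
    pop <- cells$origin[i]
    trt <- cells$treatment[i]
    ids <- b$box_id[b$origin == pop & b$treatment == trt]
    ev <- if (cohort == "adults") {
      adult_events(ds, ids)
    } else {
      f1 <- ds$f1[ds$f1$box_id %in% ids, ]
      if (nrow(f1) == 0) NULL else
        data.frame(day = f1$day, status = f1$status)
    }
    if (is.null(ev) || nrow(ev) == 0) next
    km <- kaplan_meier(ev)
    curves[[length(curves) + 1]] <- dplyr::bind_cols(
      tibble::tibble(population = pop, treatment = trt), km$curve)
    medians[[length(medians) + 1]] <- tibble::tibble(
      population = pop, treatment = trt, n = km$n,
      median_day = km$median_day, last_followup = km$last_followup)
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 medians = dplyr::bind_rows(medians), cohort = cohort),
            class = "km_set")
}

adult_events <- function(ds, box_ids) {
  out <- list()
  for (id in box_ids) {
    i <- match(id, ds$boxes$box_id)
    horizon <- ds$boxes$days_observed[i]
    for (sx in c("M", "F")) {
      series <- ds$daily[ds$daily$box_id == id & ds$daily$sex == sx, ]
      series <- series[order(series$day), ]
      if (nrow(series) < 2) next
      deaths <- -diff(series$n_alive)
      days <- series$day[-1]
      keep <- deaths > 0
      if (any(keep)) {
        out[[length(out) + 1]] <- data.frame(
          day = rep(days[keep], deaths[keep]), status = "death")
      }
      final <- series$n_alive[nrow(series)]
      if (final > 0) {
        out[[length(out) + 1]] <- data.frame(
          day = rep(horizon, final), status = "censored")
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}
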