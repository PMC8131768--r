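# Mortality-vs-salinity dose-response curves and LC50 extraction.
#
# Mortality (not survival) probability is modeled so that LC50 is the
# 0.5 point of the fitted curve directly; the dose axis is untransformed
# because the design includes 0 ppt (log-dose is undefined there).

#' Fit a binomial logistic mortality curve along the salinity axis
#'
#' Maximum-likelihood binomial fit (logit link) of the probability of
#' death by the chosen census hour on untransformed salinity, using IRLS
#' with deviance tolerance 1e-8 and an iteration cap of 100. Complete
#' separation is detected by coefficient magnitude > 30 on the logit
#' scale (or by the absence of any partial-mortality replicate) and is
#' reported, not raised: the fit comes back with `converged = FALSE` and
#' `separated = TRUE`.
#'
#' @param ds A [tolerance_dataset()].
#' @param exposure_hr Census hour: 48, 72 or 96.
#' @param population Optional population label to subset on.
#' @return An object of class `dose_response_fit` with elements `beta0`,
#'   `beta1` (logit scale, per ppt), `vcov`, `lc50`, `lc50_se`
#'   (delta-method, ppt), `r2` (squared correlation between observed and
#'   fitted replicate mortality proportions), `exposure_hr`, `population`,
#'   `converged`, `separated`, `n_iter`, and the underlying `glm` object.
#' @export
fit_mortality_curve <- function(ds, exposure_hr = 48, population = NULL) {
  stopifnot(inherits(ds, "tolerance_dataset"))
  if (!exposure_hr %in% c(48, 72, 96)) {
    stop("exposure_hr must be one of 48, 72, 96", call. = FALSE)
  }
  rec <- ds$records
  if (!is.null(population)) {
    rec <- rec[!is.na(rec$population) & rec$population == population, ]
    if (nrow(rec) == 0) stop("no records for population ", population,
                             call. = FALSE)
  }
  if (length(unique(rec$salinity)) < 2) {
    stop("need at least 2 distinct salinity doses to fit a curve",
         call. = FALSE)
  }
  col <- paste0("alive_", exposure_hr)
  dead <- rec$n_initial - rec[[col]]
  alive <- rec[[col]]
  prop <- dead / rec$n_initial
  dat <- data.frame(dead = dead, alive = alive, salinity = rec$salinity)
  fit <- suppressWarnings(
    glm(cbind(dead, alive) ~ salinity, family = binomial("logit"),
        data = dat, control = glm.control(epsilon = 1e-8, maxit = 100))
  )
  b <- unname(coef(fit))
  no_partial <- all(prop %in% c(0, 1))
  separated <- no_partial || any(abs(b) > 30)
  converged <- isTRUE(fit$converged) && !separated
  V <- vcov(fit)
  if (abs(b[2]) > 0) {
    lc50 <- -b[1] / b[2]
    grad <- c(-1 / b[2], b[1] / b[2]^2)
    lc50_se <- sqrt(drop(t(grad) %*% V %*% grad))
  } else {
    lc50 <- NA_real_
    lc50_se <- NA_real_
  }
  fitted_p <- unname(predict(fit, type = "response"))
  r2 <- if (sd(prop) > 0 && sd(fitted_p) > 0) {
    stats::cor(prop, fitted_p)^2
  } else {
    NA_real_
  }
  structure(
    list(beta0 = b[1], beta1 = b[2], vcov = V, lc50 = lc50,
         lc50_se = lc50_se, r2 = r2, exposure_hr = exposure_hr,
         population = population %||% unique(rec$population)[1],
         converged = converged, separated = separated,
         n_iter = fit$iter, model = fit, n_replicates = nrow(rec)),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> %s @ %d hr: LC50 = %.2f +/- %.2f ppt (R2 = %.3f)%s\n",
    x$population %||% "?", x$exposure_hr, x$lc50, x$lc50_se, x$r2,
    if (x$separated) " [separated]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LC50 from logistic coefficients
#'
#' The salinity at which modeled mortality is 0.5, i.e. the root of
#' `beta0 + beta1 * dose`.
#'
#' @param beta0 Intercept on the logit scale.
#' @param beta1 Slope per ppt; must be non-zero.
#' @return LC50 in ppt.
#' @export
lc50_from_fit <- function(beta0, beta1) {
  if (any(beta1 == 0)) {
    stop("LC50 is undefined for a zero slope", call. = FALSE)
  }
  -beta0 / beta1
}

#' Confidence interval for LC50
#'
#' Default is the delta-method interval, symmetric on the dose scale,
#' matching mean +/- SE reporting; Fieller's theorem is offered as an
#' alternative that respects the ratio's skew.
#'
#' @param fit A [fit_mortality_curve()] result.
#' @param level Confidence level in (0, 1).
#' @param method `"delta"` (default) or `"fieller"`.
#' @return List with `lo`, `hi` (ppt), `level`, `method`.
#' @export
lc50_confidence_interval <- function(fit, level = 0.95,
                                     method = c("delta", "fieller")) {
  stopifnot(inherits(fit, "dose_response_fit"), level > 0, level < 1)
  method <- match.arg(method)
  if (!is.finite(fit$lc50)) stop("LC50 undefined for this fit", call. = FALSE)
  V <- fit$vcov
  if (any(!is.finite(V)) || det(V) <= 0) {
    stop("singular coefficient covariance; interval unavailable",
         call. = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    lo <- fit$lc50 - z * fit$lc50_se
    hi <- fit$lc50 + z * fit$lc50_se
  } else {
    # Fieller: solve (b0 + b1 d)^2 = z^2 (v00 + 2 d v01 + d^2 v11) for d
    b0 <- fit$beta0; b1 <- fit$beta1
    v00 <- V[1, 1]; v01 <- V[1, 2]; v11 <- V[2, 2]
    A <- b1^2 - z^2 * v11
    B <- 2 * (b0 * b1 - z^2 * v01)
    C <- b0^2 - z^2 * v00
    disc <- B^2 - 4 * A * C
    if (A <= 0 || disc < 0) {
      stop("Fieller interval is unbounded at this confidence level",
           call. = FALSE)
    }
    roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    lo <- roots[1]; hi <- roots[2]
  }
  list(lo = lo, hi = hi, level = level, method = method)
}

#' Table of LC50 fits per population and exposure time
#'
#' Interval censoring across the 48/72/96 hr censuses is handled by
#' fitting each exposure time independently on cumulative survivors,
#' not by a joint time-to-event model.
#'
#' @param ds A [tolerance_dataset()] (one or more populations).
#' @param exposure_hours Census hours to fit.
#' @return Tibble with one row per population x exposure: `population`,
#'   `exposure_hr`, `lc50`, `lc50_se`, `r2`, `converged`, `separated`.
#' @export
lc50_table <- function(ds, exposure_hours = c(48, 72, 96)) {
  stopifnot(inherits(ds, "tolerance_dataset"))
  pops <- unique(ds$records$population)
  rows <- list()
  for (p in pops) {
    for (h in exposure_hours) {
      f <- fit_mortality_curve(ds, exposure_hr = h,
                               population = if (is.na(p)) NULL else p)
      rows[[length(rows) + 1]] <- tibble::tibble(
        population = p, exposure_hr = h, lc50 = f$lc50,
        lc50_se = f$lc50_se, r2 = f$r2, converged = f$converged,
        separated = f$separated)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare salinity tolerance between two populations
#'
#' Linear model on replicate-level survival proportions with salinity as
#' covariate, population as factor, and their interaction (an ANCOVA on
#' the same replicate units the curves are fit to), with sequential
#' F-tests and the full-model R2.
#'
#' @param ds A [tolerance_dataset()] holding exactly the populations to
#'   compare (at least two).
#' @param exposure_hr Census hour.
#' @return List of class `ancova_table` with `terms` (tibble: term, df,
#'   sum_sq, mean_sq, statistic, p), `residual`, `r2`, and the `lm` fit.
#' @export
lc50_comparison_model <- function(ds, exposure_hr = 48) {
  stopifnot(inherits(ds, "tolerance_dataset"))
  rec <- ds$records
  pops <- unique(rec$population[!is.na(rec$population)])
  if (length(pops) < 2) {
    stop("need at least two populations to compare", call. = FALSE)
  }
  shared <- Reduce(intersect,
                   lapply(pops, function(p) rec$salinity[rec$population == p]))
  if (length(unique(shared)) < 2) {
    stop("populations share fewer than 2 common doses", call. = FALSE)
  }
  col <- paste0("alive_", exposure_hr)
  d <- data.frame(
    prop_surv = rec[[col]] / rec$n_initial,
    salinity = rec$salinity,
    population = factor(rec$population))
  fit <- lm(prop_surv ~ salinity * population, data = d)
  a <- anova(fit)
  terms <- tibble::tibble(
    term = rownames(a)[-nrow(a)],
    df = a$Df[-nrow(a)],
    sum_sq = a$`Sum Sq`[-nrow(a)],
    mean_sq = a$`Mean Sq`[-nrow(a)],
    statistic = a$`F value`[-nrow(a)],
    p = a$`Pr(>F)`[-nrow(a)])
  structure(
    list(terms = terms,
         residual = list(df = a$Df[nrow(a)], sum_sq = a$`Sum Sq`[nrow(a)]),
         r2 = summary(fit)$r.squared,
         model = fit),
    class = "ancova_table")
}

#' @export
print.ancova_table <- function(x, ...) {
  cat("<ancova_table> sequential F-tests on replicate survival proportions\n")
  print(x$terms)
  cat(sprintf("residual df = %d, model R2 = %.3f\n", x$residual$df, x$r2))
  invisible(x)
}
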