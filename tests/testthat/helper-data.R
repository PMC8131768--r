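# In-code fixtures: small deterministic datasets built programmatically.

# Monotone head-count trajectory from n0 (day 0) to nf (final day).
count_traj <- function(n0, nf, days) {
  cummin(round(seq(n0, nf, length.out = days + 1)))
}

# One hand-built garden box with linear-ish adult decline.
make_box <- function(box_id, origin = "FW", treatment = 0,
                     n_m = 5, n_f = 5, m_final = 3, f_final = 2,
                     eggs = 78, days = 30, offspring = 3, f1 = NULL) {
  daily <- tibble::tibble(
    box_id = box_id,
    day = rep(0:days, 2),
    sex = rep(c("M", "F"), each = days + 1),
    n_alive = c(count_traj(n_m, m_final, days),
                count_traj(n_f, f_final, days)))
  boxes <- tibble::tibble(
    box_id = box_id, origin = origin, treatment = treatment,
    n_males = n_m, n_females = n_f, eggs_total = eggs,
    days_observed = days, n_offspring = offspring)
  list(boxes = boxes, daily = daily, f1 = f1)
}

# Assemble a garden_dataset from make_box() pieces.
toy_garden <- function(..., validate = TRUE) {
  parts <- list(...)
  f1 <- dplyr::bind_rows(lapply(parts, `[[`, "f1"))
  garden_dataset(
    boxes = dplyr::bind_rows(lapply(parts, `[[`, "boxes")),
    daily = dplyr::bind_rows(lapply(parts, `[[`, "daily")),
    f1 = if (ncol(f1) > 0) f1 else NULL,
    validate = validate)
}

# A tiny tolerance dataset from dose/death vectors (counts frozen at 48 hr).
toy_tolerance <- function(doses, deaths, n = 10, population = "FW") {
  tolerance_dataset(tibble::tibble(
    replicate_id = sprintf("%s_r%d", population, seq_along(doses)),
    population = population, salinity = doses, n_initial = n,
    alive_48 = n - deaths, alive_72 = n - deaths, alive_96 = n - deaths))
}

# Independent ML oracle: direct minimization of the binomial negative
# log-likelihood for the logit-linear mortality curve (BFGS with a
# Nelder-Mead polish).
logistic_nll_oracle <- function(dose, dead, alive, start = c(0, 0.1)) {
  nll <- function(b) {
    eta <- b[1] + b[2] * dose
    -sum(dead * plogis(eta, log.p = TRUE) +
           alive * plogis(-eta, log.p = TRUE))
  }
  o <- stats::optim(start, nll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 2000))
  stats::optim(o$par, nll, control = list(reltol = 1e-14, maxit = 5000))
}

# The logit-linear MLE is unique and interior only when the data are not
# (quasi-)separated; two doses with partial mortality guarantee a
# well-conditioned likelihood for the oracle comparison.
well_posed_tolerance <- function(deaths, n = 10) {
  sum(deaths > 0 & deaths < n) >= 2
}
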