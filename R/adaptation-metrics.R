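# Local adaptation (LA) and magnitude of maladaptation (MA) indices,
# trait averages, and the fitness trade-off quadrant classification.
#
# LA is the fitness difference between the focal (native) and foreign
# population at the focal population's site, normalized by the mean
# fitness of the two populations at that site:
#
#   LA = (W_native - W_foreign) / ((W_native + W_foreign) / 2)
#
# Positive LA indicates local adaptation of the focal population at
# that site, negative LA maladaptation; for non-negative fitness LA is
# bounded in [-2, 2]. MA standardizes the ancestral population's
# home-environment fitness to 1.0 and reports the proportional
# shortfall of the derived population in its own home environment:
#
#   MA = 1 - W_realized / W_ideal
#
# with 0 meaning no loss and 1 meaning 100% maladaptation.

#' Local adaptation index
#'
#' Normalized fitness difference between the focal (native) population
#' and the foreign population at the same site. When both fitness values
#' are zero the index carries no signal and is reported as undefined
#' (`defined = FALSE`, `la = NA`), not as 0.
#'
#' @param w_native Mean fitness of the focal population at the site
#'   (non-negative).
#' @param w_foreign Mean fitness of the foreign population at the same
#'   site (non-negative). Vectors are recycled in parallel.
#' @return Tibble `w_native`, `w_foreign`, `la`, `defined`.
#' @export
local_adaptation_index <- function(w_native, w_foreign) {
  if (any(!is.finite(w_native)) || any(!is.finite(w_foreign))) {
    stop("fitness values must be finite", call. = FALSE)
  }
  if (any(w_native < 0) || any(w_foreign < 0)) {
    stop("fitness values must be non-negative", call. = FALSE)
  }
  defined <- (w_native + w_foreign) > 0
  la <- ifelse(defined,
               (w_native - w_foreign) / ((w_native + w_foreign) / 2),
               NA_real_)
  tibble::tibble(w_native = w_native, w_foreign = w_foreign,
                 la = la, defined = defined)
}

#' Magnitude of maladaptation
#'
#' Proportional fitness shortfall of the derived population in its home
#' environment relative to the ancestral population's home-environment
#' fitness standardized to 1.0. A realized fitness exceeding the ideal
#' yields a negative MA, reported as-is with `exceeds_ideal = TRUE`
#' rather than clipped, since the `[0, 1]` interpretation assumes
#' realized <= ideal.
#'
#' @param w_ideal Ancestral population's fitness in its home environment
#'   (> 0).
#' @param w_realized Derived population's fitness in its own home
#'   environment (>= 0).
#' @return Tibble `w_ideal`, `w_realized`, `ma`, `exceeds_ideal`.
#' @export
maladaptation_magnitude <- function(w_ideal, w_realized) {
  if (any(!is.finite(w_ideal)) || any(!is.finite(w_realized))) {
    stop("fitness values must be finite", call. = FALSE)
  }
  if (any(w_ideal <= 0)) {
    stop("w_ideal must be positive (MA undefined otherwise)", call. = FALSE)
  }
  if (any(w_realized < 0)) {
    stop("w_realized must be non-negative", call. = FALSE)
  }
  ma <- 1 - w_realized / w_ideal
  tibble::tibble(w_ideal = w_ideal, w_realized = w_realized, ma = ma,
                 exceeds_ideal = ma < 0)
}

#' Average the LA index over traits
#'
#' Arithmetic mean of defined LA values for one population x site across
#' the supplied traits. Undefined (NA) entries are excluded; averaging
#' requires at least one defined value.
#'
#' @param la Numeric vector of LA values, optionally named by trait.
#' @return List `average`, `n_traits`, `traits` (contributing names).
#' @export
trait_average_la <- function(la) {
  if (length(la) == 0) stop("no LA values supplied", call. = FALSE)
  keep <- !is.na(la)
  if (!any(keep)) stop("no defined LA values to average", call. = FALSE)
  used <- la[keep]
  list(average = mean(used), n_traits = length(used),
       traits = names(used) %||% rep(NA_character_, length(used)))
}

TRADEOFF_QUADRANTS <- c("tradeoff_home", "inverse_tradeoff",
                        "no_tradeoff_both", "no_tradeoff_neither",
                        "boundary")

#' Classify a fitness trade-off from home and foreign LA
#'
#' Quadrant classification of a population's fitness advantage at home
#' versus away, determined solely by the signs of the two LA values:
#' advantage only at home (`tradeoff_home`), only away
#' (`inverse_tradeoff`), at both sites (`no_tradeoff_both`), at neither
#' (`no_tradeoff_neither`). Values within `tol` of zero on either axis
#' are `boundary`.
#'
#' @param la_home LA of the population at its home site.
#' @param la_foreign LA of the same population at a foreign site.
#' @param tol Half-width of the boundary band (default 0: only exact
#'   zeros are boundary).
#' @return Character vector of quadrant labels.
#' @export
classify_tradeoff <- function(la_home, la_foreign, tol = 0) {
  stopifnot(tol >= 0)
  n <- max(length(la_home), length(la_foreign))
  la_home <- rep_len(la_home, n)
  la_foreign <- rep_len(la_foreign, n)
  out <- character(n)
  for (i in seq_len(n)) {
    h <- la_home[i]; f <- la_foreign[i]
    out[i] <- if (is.na(h) || is.na(f)) {
      NA_character_
    } else if (abs(h) <= tol || abs(f) <= tol) {
      "boundary"
    } else if (h > 0 && f < 0) {
      "tradeoff_home"
    } else if (h < 0 && f > 0) {
      "inverse_tradeoff"
    } else if (h > 0 && f > 0) {
      "no_tradeoff_both"
    } else {
      "no_tradeoff_neither"
    }
  }
  out
}

#' Full adaptation report from fitness summaries
#'
#' Computes, from population x treatment x trait fitness means, the LA
#' index for every population at every site and trait, the trait-averaged
#' LA per population x site, the MA per trait (ancestral population at
#' its home site standardized to 1.0 against the derived population at
#' its own home site), and the trade-off quadrant for each population x
#' trait x foreign site.
#'
#' @param summaries Tibble in the [summarize_traits()] shape
#'   (`population`, `treatment`, `trait`, `mean`, ...).
#' @param home_map Named numeric vector mapping each population to its
#'   home treatment (ppt). The first entry is taken as the ancestral
#'   (reference) population for MA; default `c(FW = 0, BW = 1)`: the
#'   freshwater population is ancestral with home 0 ppt and the brackish
#'   population's home is the 1 ppt treatment.
#' @param traits Traits entering LA, averages and MA (default the four
#'   fitness surrogates; sex-specific survival is excluded).
#' @param exclude_traits Traits to drop from the trait averages (an
#'   explicit exclusion, never silent).
#' @param tol Boundary tolerance passed to [classify_tradeoff()].
#' @return List of class `adaptation_report` with tibbles `la`
#'   (`population`, `site`, `trait`, `w_native`, `w_foreign`, `la`,
#'   `defined`, `is_home`), `la_average` (`population`, `site`,
#'   `la_average`, `n_traits`), `ma` (`trait`, `w_ideal`, `w_realized`,
#'   `ma`, `exceeds_ideal`), and `tradeoffs` (`population`, `trait`,
#'   `site_foreign`, `la_home`, `la_foreign`, `quadrant`).
#' @export
adaptation_report <- function(summaries,
                              home_map = c(FW = 0, BW = 1),
                              traits = c("survival", "fecundity",
                                         "oviposition_rate", "n_immatures"),
                              exclude_traits = NULL,
                              tol = 0) {
  summaries <- tibble::as_tibble(summaries)
  pops <- names(home_map)
  if (length(pops) != 2) {
    stop("home_map must name exactly two populations", call. = FALSE)
  }
  empty_report <- function() {
    structure(list(
      la = tibble::tibble(population = character(), site = numeric(),
                          trait = character(), w_native = numeric(),
                          w_foreign = numeric(), la = numeric(),
                          defined = logical(), is_home = logical()),
      la_average = tibble::tibble(population = character(),
                                  site = numeric(), la_average = numeric(),
                                  n_traits = integer()),
      ma = tibble::tibble(trait = character(), w_ideal = numeric(),
                          w_realized = numeric(), ma = numeric(),
                          exceeds_ideal = logical()),
      tradeoffs = tibble::tibble(population = character(),
                                 trait = character(),
                                 site_foreign = numeric(),
                                 la_home = numeric(), la_foreign = numeric(),
                                 quadrant = character()),
      home_map = home_map), class = "adaptation_report")
  }
  if (nrow(summaries) == 0) return(empty_report())
  present <- intersect(pops, unique(summaries$population))
  if (length(present) < 2) {
    warning("summaries do not contain both populations; empty report",
            call. = FALSE)
    return(empty_report())
  }
  cell_mean <- function(pop, site, trait) {
    m <- summaries$mean[summaries$population == pop &
                          summaries$treatment == site &
                          summaries$trait == trait]
    if (length(m) == 0) NA_real_ else m[1]
  }
  sites <- sort(unique(summaries$treatment))
  la_rows <- list()
  for (pop in pops) {
    other <- setdiff(pops, pop)
    for (site in sites) {
      for (tr in traits) {
        wn <- cell_mean(pop, site, tr)
        wf <- cell_mean(other, site, tr)
        if (is.na(wn) || is.na(wf)) {
          warning(sprintf("missing cell for %s/%s at %g ppt; LA skipped",
                          pop, tr, site), call. = FALSE)
          next
        }
        est <- local_adaptation_index(wn, wf)
        la_rows[[length(la_rows) + 1]] <- tibble::tibble(
          population = pop, site = site, trait = tr,
          w_native = wn, w_foreign = wf, la = est$la,
          defined = est$defined, is_home = site == home_map[[pop]])
      }
    }
  }
  la <- dplyr::bind_rows(la_rows)
  avg_traits <- setdiff(traits, exclude_traits)
  la_average <- la |>
    dplyr::filter(.data$trait %in% avg_traits, .data$defined) |>
    dplyr::group_by(.data$population, .data$site) |>
    dplyr::summarise(la_average = mean(.data$la),
                     n_traits = dplyr::n(), .groups = "drop")
  ancestral <- pops[1]
  derived <- pops[2]
  ma_rows <- list()
  for (tr in traits) {
    wi <- cell_mean(ancestral, home_map[[ancestral]], tr)
    wr <- cell_mean(derived, home_map[[derived]], tr)
    if (is.na(wi) || is.na(wr) || wi <= 0) {
      warning(sprintf("MA for %s unavailable (missing cell or zero ideal)",
                      tr), call. = FALSE)
      next
    }
    ma_rows[[length(ma_rows) + 1]] <- cbind(tibble::tibble(trait = tr),
                                            maladaptation_magnitude(wi, wr))
  }
  ma <- dplyr::bind_rows(ma_rows)
  to_rows <- list()
  for (pop in pops) {
    home <- home_map[[pop]]
    for (tr in traits) {
      lh <- la$la[la$population == pop & la$site == home & la$trait == tr]
      if (length(lh) == 0) next
      for (site in setdiff(sites, home)) {
        lf <- la$la[la$population == pop & la$site == site & la$trait == tr]
        if (length(lf) == 0) next
        to_rows[[length(to_rows) + 1]] <- tibble::tibble(
          population = pop, trait = tr, site_foreign = site,
          la_home = lh, la_foreign = lf,
          quadrant = classify_tradeoff(lh, lf, tol))
      }
    }
  }
  structure(list(la = la, la_average = la_average, ma = ma,
                 tradeoffs = dplyr::bind_rows(to_rows),
                 home_map = home_map),
            class = "adaptation_report")
}

#' @export
print.adaptation_report <- function(x, ...) {
  cat("<adaptation_report>\n")
  cat("home treatments:",
      paste(names(x$home_map), x$home_map, sep = " = ", collapse = ", "),
      "ppt\n")
  cat(nrow(x$la), "LA estimates,", nrow(x$ma), "MA estimates,",
      nrow(x$tradeoffs), "trade-off classifications\n")
  invisible(x)
}
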