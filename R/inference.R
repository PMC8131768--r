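# Supporting statistics: one-way ANOVA with Tukey HSD, sequential
# factorial fixed-effects models, logistic survival curves, and Welch's
# t-test.
#
# Responses are box-level aggregates, so the box is the independent
# unit; random box effects are deliberately not modeled (the closest
# fixed-effects analog to a mixed model with a box-level random
# intercept on box-aggregated data).

new_anova_table <- function(terms, residual, total_sum_sq) {
  structure(list(terms = terms, residual = residual,
                 total_sum_sq = total_sum_sq),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("<anova_table>\n")
  print(x$terms)
  cat(sprintf("residual: SS = %.4g on %d df; total SS = %.4g\n",
              x$residual$sum_sq, x$residual$df, x$total_sum_sq))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Between/within decomposition with `F = MSB/MSW` and an upper-tail
#' p-value. When every observation is identical the decomposition is
#' degenerate and `F = 0`, `p = 1` is returned (not an error).
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty,
#'   total residual df >= 1).
#' @return An `anova_table` with a single `group` term.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 1)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups)
  n <- length(y)
  if (n - k < 1) stop("residual degrees of freedom must be >= 1",
                      call. = FALSE)
  if (var(y) == 0) {
    terms <- tibble::tibble(term = "group", sum_sq = 0, df = k - 1L,
                            statistic = 0, p = 1)
    return(new_anova_table(terms, list(sum_sq = 0, df = n - k),
                           total_sum_sq = 0))
  }
  a <- anova(lm(y ~ g))
  terms <- tibble::tibble(term = "group", sum_sq = a$`Sum Sq`[1],
                          df = a$Df[1], statistic = a$`F value`[1],
                          p = a$`Pr(>F)`[1])
  new_anova_table(terms,
                  list(sum_sq = a$`Sum Sq`[2], df = a$Df[2]),
                  total_sum_sq = sum(a$`Sum Sq`))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted comparisons of all unordered group pairs
#' (Tukey-Kramer for unequal group sizes): for each pair,
#' `q = |mean_a - mean_b| / sqrt(MSW/2 * (1/n_a + 1/n_b))` with the
#' adjusted p from the studentized-range distribution on (k, df_within).
#'
#' @param groups Named list of numeric samples (names default to
#'   `group1..k`).
#' @param alpha Familywise significance level for the `significant` flag.
#' @return List of class `tukey_result`: `pairs` tibble (`group_a`,
#'   `group_b`, `mean_diff` = mean_a - mean_b, `q_statistic`,
#'   `adjusted_p`, `significant`), plus `df_within`, `ms_within`,
#'   `alpha`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs at least 2 observations",
                        call. = FALSE)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  df_w <- sum(ns - 1)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  msw <- ssw / df_w
  if (msw == 0) stop("pooled within-group variance is zero", call. = FALSE)
  idx <- combn(k, 2)
  pairs <- lapply(seq_len(ncol(idx)), function(j) {
    a <- idx[1, j]; b <- idx[2, j]
    diff <- unname(means[a] - means[b])
    se <- sqrt(msw / 2 * (1 / ns[a] + 1 / ns[b]))
    q <- unname(abs(diff) / se)
    p <- ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    tibble::tibble(group_a = names(groups)[a], group_b = names(groups)[b],
                   mean_diff = unname(diff), q_statistic = unname(q),
                   adjusted_p = p, significant = p < alpha)
  })
  structure(list(pairs = dplyr::bind_rows(pairs), df_within = df_w,
                 ms_within = msw, alpha = alpha, group_means = means),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("<tukey_result> studentized-range comparisons, alpha =", x$alpha, "\n")
  print(x$pairs)
  invisible(x)
}

#' Compact significance letters from a Tukey result
#'
#' Groups sharing a letter are not significantly different. Ties are
#' resolved by lexicographic group order (insert-and-absorb assignment).
#'
#' @param result A [tukey_hsd()] result.
#' @return Named character vector of letter codes per group.
#' @export
tukey_letters <- function(result) {
  stopifnot(inherits(result, "tukey_result"))
  groups <- sort(names(result$group_means))
  differ <- function(a, b) {
    p <- result$pairs
    hit <- (p$group_a == a & p$group_b == b) |
      (p$group_a == b & p$group_b == a)
    any(p$significant[hit])
  }
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(vapply(sets[[i]], function(o) differ(g, o), logical(1)))) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Sequential factorial fixed-effects model on box-level responses
#'
#' Least-squares fit with sequential (Type I) sums of squares and
#' F-tests, factors entered in the order treatment, sex (if supplied),
#' origin, treatment:origin. Each term also carries a likelihood-ratio
#' chi-square (`n * log(RSS_reduced / RSS_full)` for the Gaussian model)
#' with its own p-value, mirroring reports that print both columns.
#'
#' @param data Data frame of box-level units.
#' @param response Name of the response column.
#' @param treatment,origin,sex Names of the factor columns (`sex = NULL`
#'   to omit).
#' @param with_interaction Include treatment:origin (default `TRUE`).
#' @return An `anova_table` whose `terms` also carry `chisq` and
#'   `p_chisq`.
#' @export
factorial_lm <- function(data, response, treatment = "treatment",
                         origin = "origin", sex = NULL,
                         with_interaction = TRUE) {
  data <- as.data.frame(data)
  for (v in c(response, treatment, origin, sex)) {
    if (!is.null(v) && !v %in% names(data)) {
      stop("column not found in data: ", v, call. = FALSE)
    }
  }
  term_names <- c(treatment, sex, origin,
                  if (with_interaction && !is.null(origin)) {
                    paste0(treatment, ":", origin)
                  })
  for (v in c(treatment, sex, origin)) {
    if (!is.null(v)) data[[v]] <- factor(data[[v]])
  }
  form <- stats::as.formula(paste(response, "~",
                                  paste(term_names, collapse = " + ")))
  fit <- lm(form, data = data)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  a <- anova(fit)
  nt <- nrow(a) - 1
  n <- nrow(data)
  # sequential LR chi-squares from the nested RSS path implied by Type I SS
  rss_full_path <- rev(cumsum(rev(a$`Sum Sq`)))  # RSS before adding term j
  rss_after <- rss_full_path - a$`Sum Sq`
  chisq <- n * log(rss_full_path[seq_len(nt)] / rss_after[seq_len(nt)])
  terms <- tibble::tibble(
    term = rownames(a)[seq_len(nt)],
    sum_sq = a$`Sum Sq`[seq_len(nt)],
    df = a$Df[seq_len(nt)],
    statistic = a$`F value`[seq_len(nt)],
    p = a$`Pr(>F)`[seq_len(nt)],
    chisq = chisq,
    p_chisq = pchisq(chisq, df = a$Df[seq_len(nt)], lower.tail = FALSE))
  new_anova_table(terms,
                  list(sum_sq = a$`Sum Sq`[nt + 1], df = a$Df[nt + 1]),
                  total_sum_sq = sum(a$`Sum Sq`))
}

#' Logistic survival curve along the salinity gradient
#'
#' Binomial maximum-likelihood fit (logit link) of the adult survival
#' proportion at the horizon day on salinity, optionally crossed with
#' sex, sharing the IRLS engine and separation rules of
#' [fit_mortality_curve()]. Sex-specific rows use that sex's initial
#' count as denominator (an individual-level survival probability), and
#' predicted curves carry pointwise 95% bands on the probability scale.
#'
#' @param ds A [garden_dataset()].
#' @param predictors `c("salinity")` or `c("salinity", "sex")`.
#' @param horizon_day Survival horizon (default 30).
#' @return List of class `logistic_survival_fit`: `coefficients` tibble
#'   (`term`, `estimate`, `se`, `z`, `p`), `curve` tibble (`salinity`,
#'   `sex` if requested, `fit`, `lo`, `hi`), `converged`, `separated`,
#'   and the `glm` object.
#' @export
logistic_survival_model <- function(ds, predictors = c("salinity"),
                                    horizon_day = 30) {
  stopifnot(inherits(ds, "garden_dataset"))
  if (!"salinity" %in% predictors) {
    stop("predictors must include 'salinity'", call. = FALSE)
  }
  by_sex <- "sex" %in% predictors
  b <- ds$boxes
  rows <- list()
  for (i in seq_len(nrow(b))) {
    sexes <- if (by_sex) c("M", "F") else NA_character_
    for (sx in sexes) {
      if (by_sex) {
        ini <- if (sx == "M") b$n_males[i] else b$n_females[i]
        alive <- ds$daily$n_alive[ds$daily$box_id == b$box_id[i] &
                                    ds$daily$day == horizon_day &
                                    ds$daily$sex == sx]
      } else {
        ini <- b$n_males[i] + b$n_females[i]
        alive <- sum(ds$daily$n_alive[ds$daily$box_id == b$box_id[i] &
                                        ds$daily$day == horizon_day])
      }
      if (length(alive) == 0) {
        stop("no census at day ", horizon_day, " for box ", b$box_id[i],
             call. = FALSE)
      }
      alive <- sum(alive)
      rows[[length(rows) + 1]] <- tibble::tibble(
        box_id = b$box_id[i], salinity = b$treatment[i], sex = sx,
        alive = alive, dead = ini - alive)
    }
  }
  d <- dplyr::bind_rows(rows)
  form <- if (by_sex) cbind(alive, dead) ~ salinity * sex else
    cbind(alive, dead) ~ salinity
  fit <- suppressWarnings(
    glm(form, family = binomial("logit"), data = d,
        control = glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- summary(fit)$coefficients
  separated <- any(abs(coef(fit)) > 30)
  grid <- expand.grid(
    salinity = seq(0, max(d$salinity), length.out = 101),
    sex = if (by_sex) c("M", "F") else NA_character_,
    stringsAsFactors = FALSE)
  pr <- predict(fit, newdata = grid, type = "link", se.fit = TRUE)
  curve <- tibble::as_tibble(grid)
  curve$fit <- plogis(pr$fit)
  curve$lo <- plogis(pr$fit - qnorm(0.975) * pr$se.fit)
  curve$hi <- plogis(pr$fit + qnorm(0.975) * pr$se.fit)
  if (!by_sex) curve$sex <- NULL
  structure(
    list(coefficients = tibble::tibble(term = rownames(cf),
                                       estimate = unname(cf[, 1]),
                                       se = unname(cf[, 2]),
                                       z = unname(cf[, 3]),
                                       p = unname(cf[, 4])),
         curve = curve, converged = isTRUE(fit$converged) && !separated,
         separated = separated, model = fit, data = d),
    class = "logistic_survival_fit")
}

#' Welch's unequal-variance t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom. Degenerate
#' zero-variance inputs are resolved deterministically: equal means give
#' `t = 0, p = 1`; unequal means give an infinite-t flag with `p = 0`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List of class `welch_test`: `t`, `df`, `p`, `mean_x`,
#'   `mean_y`, `infinite` flag.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y), infinite = FALSE)
    } else {
      res <- list(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = 0,
                  mean_x = mean(x), mean_y = mean(y), infinite = TRUE)
    }
    return(structure(res, class = "welch_test"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_x = mean(x), mean_y = mean(y),
                 infinite = FALSE),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("<welch_test> t = %.4f, df = %.2f, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}
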