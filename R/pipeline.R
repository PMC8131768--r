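# End-to-end pipeline over the analysis stages and deterministic report
# rendering. The pipeline is a pure function of (inputs, config, seed):
# repeated runs produce identical machine-readable outputs.

#' Pipeline configuration
#'
#' Inputs may be any subset of a tolerance CSV, the three garden CSVs,
#' and a pre-aggregated fitness-means CSV (the latter bypasses box-level
#' data so published cell means can be analyzed directly); sections
#' without inputs are skipped with a warning.
#'
#' @param tolerance_path Tolerance CSV, or `NULL`.
#' @param garden_boxes_path,garden_daily_path,garden_f1_path Garden CSVs,
#'   or `NULL`.
#' @param fitness_means_path Pre-aggregated means CSV, or `NULL`.
#' @param home_map Population -> home treatment map (ppt).
#' @param exposure_hours Census hours for LC50 fits.
#' @param alpha Significance level for tests in (0, 1).
#' @param out_dir Output directory for [render_report()].
#' @param digits Display rounding for rendered CSVs (full precision is
#'   always retained in the `_full` outputs).
#' @param seed Seed recorded for any resampling step.
#' @param strict Strict validation of loaded inputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tolerance_path = NULL,
                            garden_boxes_path = NULL,
                            garden_daily_path = NULL,
                            garden_f1_path = NULL,
                            fitness_means_path = NULL,
                            home_map = c(FW = 0, BW = 1),
                            exposure_hours = c(48, 72, 96),
                            alpha = 0.05, out_dir = NULL, digits = 2,
                            seed = 1, strict = TRUE) {
  stopifnot(alpha > 0, alpha < 1, digits >= 0)
  structure(list(tolerance_path = tolerance_path,
                 garden_boxes_path = garden_boxes_path,
                 garden_daily_path = garden_daily_path,
                 garden_f1_path = garden_f1_path,
                 fitness_means_path = fitness_means_path,
                 home_map = home_map, exposure_hours = exposure_hours,
                 alpha = alpha, out_dir = out_dir, digits = digits,
                 seed = seed, strict = strict),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' In order: input validation, LC50 table per population x exposure
#' (with the two-population ANCOVA when possible), fitness summary,
#' LA/MA/trade-off tables, and Kaplan-Meier curves for adults and F1.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_bundle` with elements `validation`,
#'   `lc50`, `lc50_comparison`, `fitness`, `adaptation`, `km_adults`,
#'   `km_f1` (unavailable sections are `NULL`), plus the `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validation <- no_violations()
  lc50 <- NULL; lc50_cmp <- NULL; fitness <- NULL
  adaptation <- NULL; km_a <- NULL; km_f <- NULL
  if (!is.null(cfg$tolerance_path)) {
    tol <- read_tolerance_csv(cfg$tolerance_path, strict = cfg$strict)
    validation <- dplyr::bind_rows(validation, validate_dataset(tol))
    lc50 <- lc50_table(tol, cfg$exposure_hours)
    pops <- unique(tol$records$population[!is.na(tol$records$population)])
    if (length(pops) >= 2) {
      lc50_cmp <- lc50_comparison_model(tol, cfg$exposure_hours[1])
    }
  } else {
    warning("no tolerance input; LC50 section skipped", call. = FALSE)
  }
  if (!is.null(cfg$garden_boxes_path)) {
    garden <- read_garden_csv(cfg$garden_boxes_path, cfg$garden_daily_path,
                              cfg$garden_f1_path, strict = cfg$strict)
    validation <- dplyr::bind_rows(validation, validate_dataset(garden))
    fitness <- summarize_traits(garden)
    km_a <- garden_km(garden, "adults")
    if (nrow(garden$f1) > 0) km_f <- garden_km(garden, "f1")
  } else if (!is.null(cfg$fitness_means_path)) {
    fitness <- read_fitness_means(cfg$fitness_means_path)
  } else {
    warning("no garden input; fitness and adaptation sections skipped",
            call. = FALSE)
  }
  if (!is.null(fitness)) {
    adaptation <- adaptation_report(fitness, home_map = cfg$home_map)
  }
  structure(list(validation = validation, lc50 = lc50,
                 lc50_comparison = lc50_cmp, fitness = fitness,
                 adaptation = adaptation, km_adults = km_a, km_f1 = km_f,
                 config = cfg),
            class = "pipeline_bundle")
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Render a pipeline bundle to CSV files and a plain-text summary
#'
#' File names and column orders are deterministic; display CSVs are
#' rounded to the configured number of digits while `_full`
#' counterparts keep full precision. Rendering the same bundle twice
#' yields byte-identical files.
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed); defaults to the
#'   bundle config's `out_dir`.
#' @param digits Display rounding; defaults to the config's.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(bundle, out_dir = NULL, digits = NULL) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  out_dir <- out_dir %||% bundle$config$out_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  digits <- digits %||% bundle$config$digits
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character()
  emit <- function(df, name, with_full = FALSE) {
    p <- file.path(out_dir, name)
    readr::write_csv(round_df(df, digits), p, progress = FALSE)
    paths <<- c(paths, p)
    if (with_full) {
      pf <- file.path(out_dir, sub("\\.csv$", "_full.csv", name))
      readr::write_csv(df, pf, progress = FALSE)
      paths <<- c(paths, pf)
    }
  }
  emit(bundle$validation, "validation_log.csv")
  summary_lines <- c("osmofit pipeline report",
                     sprintf("validation violations: %d",
                             nrow(bundle$validation)))
  if (!is.null(bundle$lc50)) {
    emit(bundle$lc50, "lc50_table.csv", with_full = TRUE)
    summary_lines <- c(summary_lines,
                       sprintf("LC50 fits: %d", nrow(bundle$lc50)))
  }
  if (!is.null(bundle$lc50_comparison)) {
    emit(bundle$lc50_comparison$terms, "lc50_comparison.csv")
  }
  if (!is.null(bundle$fitness)) {
    emit(bundle$fitness, "fitness_summary.csv", with_full = TRUE)
    summary_lines <- c(summary_lines,
                       sprintf("fitness cells: %d", nrow(bundle$fitness)))
  }
  if (!is.null(bundle$adaptation)) {
    emit(bundle$adaptation$la, "adaptation_la.csv", with_full = TRUE)
    emit(bundle$adaptation$la_average, "adaptation_la_average.csv",
         with_full = TRUE)
    emit(bundle$adaptation$ma, "adaptation_ma.csv", with_full = TRUE)
    emit(bundle$adaptation$tradeoffs, "adaptation_tradeoffs.csv")
    summary_lines <- c(summary_lines,
                       sprintf("LA estimates: %d; MA estimates: %d",
                               nrow(bundle$adaptation$la),
                               nrow(bundle$adaptation$ma)))
  }
  if (!is.null(bundle$km_adults)) {
    emit(bundle$km_adults$curves, "km_adults.csv")
    emit(bundle$km_adults$medians, "km_adults_medians.csv")
  }
  if (!is.null(bundle$km_f1)) {
    emit(bundle$km_f1$curves, "km_f1.csv")
    emit(bundle$km_f1$medians, "km_f1_medians.csv")
  }
  if (nrow(bundle$validation) == 0 && is.null(bundle$lc50) &&
      is.null(bundle$fitness)) {
    summary_lines <- c(summary_lines, "zero records processed")
  }
  sp <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, sp)
  paths <- c(paths, sp)
  invisible(paths)
}
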