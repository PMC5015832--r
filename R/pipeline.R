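# One-command orchestration: read or generate a survey bundle, compute
# indicators, build the design, estimate the system, run diagnostics, and
# write descriptive and estimation reports.

mean_sd <- function(x) c(mean = mean(x), sd = stats::sd(x))

group_cells <- function(index) {
  # market-shed x season cells plus season totals
  cells <- expand.grid(market_shed = c("urban", "semi_urban", "rural", "all"),
                       season = c("dry", "wet"), stringsAsFactors = FALSE)
  sel <- lapply(seq_len(nrow(cells)), function(i) {
    ok <- index$season == cells$season[i]
    if (cells$market_shed[i] != "all")
      ok <- ok & index$market_shed == cells$market_shed[i]
    which(ok)
  })
  cells$rows <- sel
  cells
}

cell_frame <- function(index, stat_fn, value_names) {
  cells <- group_cells(index)
  vals <- lapply(cells$rows, function(rows)
    if (!length(rows)) rep(NA_real_, length(value_names)) else stat_fn(rows))
  out <- cbind(cells[c("market_shed", "season")],
               n = vapply(cells$rows, length, integer(1)),
               do.call(rbind, lapply(vals, function(v) {
                 v <- as.numeric(v)
                 stats::setNames(as.data.frame(t(v)), value_names)
               })))
  rownames(out) <- NULL
  out
}

#' Descriptive summaries by market-shed and season
#'
#' Produces the descriptive tables of the analysis: household covariate means
#' and SDs (landholding means exclude landless households, which are reported
#' as a percentage), on-farm diversity means (excluding households that grew
#' or collected nothing, reported as `NA` when a cell is empty), the
#' distinct-food source profile (survey bundles only), per-food-group
#' consumption percentages under the gram threshold rule, the mean dietary
#' diversity score and the share meeting MDD-W.
#'
#' @param bundle A [survey_bundle()], or a household table data frame (count
#'   mode, in which case the food-source and food-group tables are omitted).
#' @param indicators Indicator table from [compute_indicators()] (or the
#'   generator).
#' @param threshold_g Gram threshold used in the food-group percentage table.
#' @return Named list of data frames: `households`, `ofd`, `diet`, and for
#'   survey bundles `food_sources`, `food_groups`.
#' @export
summarize_descriptives <- function(bundle, indicators, threshold_g = 15) {
  household <- if (inherits(bundle, "survey_bundle")) bundle$household else bundle
  stopifnot(is.data.frame(household), is.data.frame(indicators))
  idx <- merge(indicators,
               unique(household[c("household_id", "season", "market_shed")]),
               by = c("household_id", "season"), sort = FALSE)
  hh <- merge(household, indicators[c("mother_id", "season", "WDD", "MDDW",
                                      "MD", "OFD")],
              by = c("mother_id", "season"), sort = FALSE)

  households <- cell_frame(hh, function(rows) {
    d <- hh[rows, ]
    landed <- d$landholdings > 0
    c(mean_sd(d$mother_age), mean_sd(d$mother_education),
      mean_sd(d$family_size),
      if (any(landed)) mean_sd(d$landholdings[landed]) else c(NA, NA),
      pct_landless = 100 * mean(!landed),
      mean_sd(d$travel_time))
  }, c("mother_age_mean", "mother_age_sd", "mother_education_mean",
       "mother_education_sd", "family_size_mean", "family_size_sd",
       "landholdings_mean", "landholdings_sd", "pct_landless",
       "travel_time_mean", "travel_time_sd"))

  # species means exclude non-growing households
  ofd_tab <- cell_frame(idx, function(rows) {
    v <- idx$OFD[rows]
    grew <- v > 0
    c(if (any(grew)) mean_sd(v[grew]) else c(NA, NA),
      pct_growing = 100 * mean(grew))
  }, c("ofd_mean_excl_zero", "ofd_sd_excl_zero", "pct_growing"))

  diet <- cell_frame(idx, function(rows) {
    d <- idx[rows, ]
    c(mean_sd(d$WDD), pct_mddw = 100 * mean(d$MDDW), mean_sd(d$MD))
  }, c("wdd_mean", "wdd_sd", "pct_mddw", "md_mean", "md_sd"))

  out <- list(households = households, ofd = ofd_tab, diet = diet)

  if (inherits(bundle, "survey_bundle")) {
    items <- bundle$food_items
    prof_by_mother <- do.call(rbind, lapply(
      split(items, interaction(items$mother_id, items$season, drop = TRUE)),
      function(d) data.frame(mother_id = d$mother_id[1], season = d$season[1],
                             t(compute_source_profile(d)))))
    prof <- merge(idx[c("mother_id", "season", "market_shed")], prof_by_mother,
                  by = c("mother_id", "season"), all.x = TRUE, sort = FALSE)
    for (cc in c("overall", "purchased", "self_produced", "gathered", "gift"))
      prof[[cc]][is.na(prof[[cc]])] <- 0
    out$food_sources <- cell_frame(prof, function(rows) {
      d <- prof[rows, ]
      unlist(lapply(c("overall", "purchased", "self_produced", "gathered",
                      "gift"), function(cc) mean_sd(d[[cc]])))
    }, as.vector(t(outer(c("overall", "purchased", "self_produced",
                           "gathered", "gift"), c("mean", "sd"),
                         paste, sep = "_"))))

    rec <- bundle$recall
    gidx <- recall_group_index(rec$food_group)
    key <- paste(idx$mother_id, idx$season)
    rid <- paste(rec$mother_id, rec$season)
    cons <- matrix(0, nrow(idx), 10)
    hit <- rec$grams >= threshold_g
    pos <- match(rid[hit], key)
    ok <- !is.na(pos)
    cons[cbind(pos[ok], gidx[hit][ok])] <- 1
    out$food_groups <- cell_frame(idx, function(rows)
      100 * colMeans(cons[rows, , drop = FALSE]), mddw_food_groups())
  }
  out
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads a survey bundle from CSV files (or generates a synthetic one),
#' computes indicators, builds the design, estimates the three-equation
#' system by two-step GMM, runs the diagnostics battery, and writes all
#' report artifacts to `output_dir`: `indicators.csv`, descriptive tables,
#' `coefficients.csv` (three-outcome layout with significance stars),
#' `results.json`, `diagnostics.json` and a machine-readable `run_log.json`
#' recording the seed, variant, cluster level and dropped-row count.
#'
#' @param output_dir Output directory (created if needed).
#' @param input_dir Directory with the four bundle CSVs; exactly one of
#'   `input_dir` / `synthetic` must be given.
#' @param synthetic A [synth_config()] to generate data instead of reading
#'   it.
#' @param variant Model variant, see [model_spec()].
#' @param cluster Clustering level, see [model_spec()].
#' @param spec Optional ready-made [model_spec()] overriding
#'   `variant`/`cluster`.
#' @param threshold_g Gram threshold for food-group scoring.
#' @param weighting GMM weighting scheme, see [fit_gmm_system()].
#' @return Invisibly, a list with `bundle`/`household`, `indicators`,
#'   `design`, `fit`, `diagnostics`, `descriptives`, `log`.
#' @export
run_pipeline <- function(output_dir, input_dir = NULL, synthetic = NULL,
                         variant = "baseline", cluster = "household_id",
                         spec = NULL, threshold_g = 15,
                         weighting = "two_step") {
  if (is.null(input_dir) == is.null(synthetic))
    stop("supply exactly one of `input_dir` or `synthetic`", call. = FALSE)
  if (is.null(spec)) spec <- model_spec(variant = variant, cluster = cluster)

  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synth_config"))
    sim <- stage("simulate", synth_generate(synthetic, mode = "survey"))
    bundle <- sim$bundle
    seed <- synthetic$seed
  } else {
    bundle <- stage("read", read_survey_bundle(input_dir))
    seed <- NA_integer_
  }
  indicators <- stage("indicators", compute_indicators(bundle, threshold_g))
  design <- stage("design", build_design(bundle$household, indicators, spec))
  fit <- stage("estimate", fit_gmm_system(design, weighting = weighting))
  diagnostics <- stage("diagnose", diagnose(design, fit))
  descriptives <- stage("describe",
                        summarize_descriptives(bundle, indicators, threshold_g))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(indicators, file.path(output_dir, "indicators.csv"),
                   row.names = FALSE)
  for (nm in names(descriptives))
    utils::write.csv(descriptives[[nm]],
                     file.path(output_dir, paste0("descriptives_", nm, ".csv")),
                     row.names = FALSE)
  write_gmm_results(fit, output_dir)
  jsonlite::write_json(list(
    durbin_wu_hausman = diagnostics$dwh,
    sargan_hansen = diagnostics$sargan,
    first_stage = diagnostics$first_stage
  ), file.path(output_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")

  spec_file <- file.path(output_dir, "model_spec.yaml")
  write_model_spec(spec, spec_file)
  log <- list(seed = seed, variant = spec$variant, cluster = spec$cluster,
              spec_md5 = unname(tools::md5sum(spec_file)),
              n_rows_input = nrow(indicators),
              n_rows_estimation = fit$n_obs,
              n_dropped = design$n_dropped,
              n_clusters = fit$n_clusters,
              converged = fit$converged,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(bundle = bundle, indicators = indicators, design = design,
                 fit = fit, diagnostics = diagnostics,
                 descriptives = descriptives, log = log))
}
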