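# Survey bundle: the four linked flat tables the pipeline consumes, with the
# key relationships mother <-> household <-> village <-> season.

bundle_required_cols <- list(
  household = c("household_id", "mother_id", "village_id", "market_shed",
                "season", "travel_time", "landholdings",
                "father_nonag_sources", "father_ag_importance",
                "mother_nonag_sources", "mother_ag_importance",
                "mother_age", "mother_education", "mother_ethnicity",
                "family_size", "temp_range", "precip_cv", "precip_range"),
  food_items = c("mother_id", "season", "food_name", "source"),
  recall     = c("mother_id", "season", "food_group", "grams"),
  species    = c("household_id", "season", "species_name", "use")
)

#' Assemble and validate a survey bundle
#'
#' A survey bundle holds the four flat tables of the household survey:
#' the household table (one row per household-season, including the six
#' asset-count columns of [ses_asset_types()]), the 7-day food-item table,
#' the 24-hour recall table (grams per MDD-W food group) and the species
#' inventory table.
#'
#' @param household,food_items,recall,species Data frames; see package
#'   vignette for the column contracts.
#' @return An object of class `survey_bundle` (a named list of the four
#'   tables).
#' @export
survey_bundle <- function(household, food_items, recall, species) {
  tabs <- list(household = household, food_items = food_items,
               recall = recall, species = species)
  for (nm in names(tabs)) {
    stopifnot(is.data.frame(tabs[[nm]]))
    miss <- setdiff(bundle_required_cols[[nm]], names(tabs[[nm]]))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  miss_assets <- setdiff(ses_asset_types(), names(household))
  if (length(miss_assets))
    stop("household table lacks asset column(s): ",
         paste(miss_assets, collapse = ", "), call. = FALSE)
  bad_season <- setdiff(
    unique(c(household$season, food_items$season, recall$season, species$season)),
    c("dry", "wet"))
  if (length(bad_season))
    stop("season must be 'dry' or 'wet'; found: ",
         paste(bad_season, collapse = ", "), call. = FALSE)
  if (anyDuplicated(household[c("household_id", "season")]))
    stop("household table must have one row per household-season", call. = FALSE)
  structure(tabs, class = "survey_bundle")
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat("Survey bundle\n")
  cat(sprintf("  households x seasons : %d rows (%d households, %d villages)\n",
              nrow(x$household), length(unique(x$household$household_id)),
              length(unique(x$household$village_id))))
  cat(sprintf("  7-day food items     : %d rows\n", nrow(x$food_items)))
  cat(sprintf("  24-h recall          : %d rows\n", nrow(x$recall)))
  cat(sprintf("  species inventory    : %d rows\n", nrow(x$species)))
  invisible(x)
}

#' Read a survey bundle from four CSV files
#'
#' @param dir Directory containing `household.csv`, `food_items.csv`,
#'   `recall.csv` and `species.csv` (UTF-8, header row).
#' @return A [survey_bundle()].
#' @export
read_survey_bundle <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  survey_bundle(rd("household.csv"), rd("food_items.csv"),
                rd("recall.csv"), rd("species.csv"))
}

#' Write a survey bundle to four CSV files
#'
#' @param bundle A [survey_bundle()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survey_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "survey_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle))
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

recall_group_index <- function(food_group) {
  if (is.numeric(food_group)) {
    idx <- as.integer(food_group)
  } else {
    idx <- match(food_group, mddw_food_groups())
  }
  if (anyNA(idx) || any(idx < 1L | idx > 10L))
    stop("recall food_group must be 1..10 or a name from mddw_food_groups()",
         call. = FALSE)
  idx
}

#' Aggregate item-level recall grams into the ten MDD-W food groups
#'
#' Maps item-level 24-hour intake records onto the ten food groups through a
#' user-supplied lookup and sums grams within group, yielding the long recall
#' table the scoring functions expect. The package ships no authoritative
#' food list; a small synthetic illustration is in
#' `system.file("extdata", "food_groups_synthetic.csv", package = "divtriad")`.
#'
#' @param items Data frame with columns `mother_id`, `season`, `food_name`,
#'   `grams`.
#' @param lookup Data frame with columns `food_name`, `group_index` (1-10),
#'   e.g. from [utils::read.csv()].
#' @return Recall table with columns `mother_id`, `season`, `food_group`,
#'   `grams`, one row per mother-season-group with nonzero intake.
#' @export
aggregate_recall_items <- function(items, lookup) {
  stopifnot(is.data.frame(items), is.data.frame(lookup))
  if (!all(c("food_name", "group_index") %in% names(lookup)))
    stop("lookup needs columns food_name, group_index", call. = FALSE)
  idx <- lookup$group_index[match(items$food_name, lookup$food_name)]
  if (anyNA(idx))
    stop("lookup lacks food(s): ",
         paste(unique(items$food_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(
    grams ~ mother_id + season + food_group,
    data = data.frame(items[c("mother_id", "season", "grams")],
                      food_group = as.integer(idx)),
    FUN = sum)
  agg[order(agg$mother_id, agg$season, agg$food_group), , drop = FALSE]
}

#' Compute the full indicator table from a survey bundle
#'
#' Applies the indicator definitions row-set-wise: WDD and MDD-W from the
#' 24-hour recall, market diversity from purchased 7-day food items, on-farm
#' diversity from the species inventory, and the socioeconomic index from the
#' household asset counts pooled over both seasons (asset counts are taken
#' from each household's first row).
#'
#' @param bundle A [survey_bundle()].
#' @param threshold_g Gram threshold for counting a food group (default 15).
#' @return Data frame with one row per mother-season: `mother_id`,
#'   `household_id`, `season`, `WDD`, `MDDW`, `MD`, `OFD`, `SES`.
#' @export
compute_indicators <- function(bundle, threshold_g = 15) {
  stopifnot(inherits(bundle, "survey_bundle"))
  hh <- bundle$household
  key <- hh[c("mother_id", "household_id", "season")]

  # WDD: spread each mother-season's recall over the 10 groups
  rec <- bundle$recall
  gidx <- recall_group_index(rec$food_group)
  rid <- paste(rec$mother_id, rec$season)
  kid <- paste(key$mother_id, key$season)
  wdd <- vapply(seq_len(nrow(key)), function(i) {
    sel <- which(rid == kid[i])
    grams <- numeric(10)
    if (length(sel)) {
      if (anyDuplicated(gidx[sel]))
        stop("recall has duplicate food-group rows for mother ",
             key$mother_id[i], " (", key$season[i], ")", call. = FALSE)
      grams[gidx[sel]] <- rec$grams[sel]
    }
    compute_wdd(grams, threshold_g)
  }, integer(1))

  fid <- paste(bundle$food_items$mother_id, bundle$food_items$season)
  md <- vapply(seq_len(nrow(key)), function(i) {
    compute_market_diversity(bundle$food_items[fid == kid[i], , drop = FALSE])
  }, integer(1))

  sid <- paste(bundle$species$household_id, bundle$species$season)
  hkey <- paste(key$household_id, key$season)
  ofd <- vapply(seq_len(nrow(key)), function(i) {
    compute_ofd(bundle$species[sid == hkey[i], , drop = FALSE])
  }, integer(1))

  assets <- hh[!duplicated(hh$household_id),
               c("household_id", ses_asset_types())]
  ses <- compute_ses_index(assets)

  out <- data.frame(key, WDD = wdd, MDDW = compute_mddw(wdd), MD = md,
                    OFD = ofd,
                    SES = ses$ses[match(key$household_id, ses$household_id)])
  rownames(out) <- NULL
  out
}
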