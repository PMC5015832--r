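# Diversity indicators: dietary diversity score (WDD, 0-10 food groups),
# Minimum Dietary Diversity-Women (MDD-W), market diversity (distinct
# purchased foods over 7 days), on-farm diversity (distinct species grown or
# collected) and an asset-based socioeconomic index.

#' The ten MDD-W food groups
#'
#' Canonical ordering of the ten food groups used to score a mother's 24-hour
#' dietary recall.
#'
#' @return Character vector of length 10.
#' @export
mddw_food_groups <- function() {
  c("grains_roots_tubers",
    "legumes",
    "nuts_seeds",
    "milk_products",
    "meats_fish_seafood",
    "eggs",
    "vitamin_a_leafy_vegetables",
    "other_vitamin_a_vegetables_fruits",
    "other_vegetables",
    "other_fruits")
}

#' The six household asset types used for the socioeconomic index
#' @return Character vector of length 6.
#' @export
ses_asset_types <- function() {
  c("bicycles", "motorcycles", "motor_vehicles", "radios", "tvs", "cellphones")
}

#' Women's dietary diversity score (WDD)
#'
#' Scores a 24-hour recall: a food group counts towards the score when at
#' least `threshold_g` grams of it were consumed (the boundary is inclusive).
#' The score is the number of the ten MDD-W food groups meeting the
#' threshold, so it ranges from 0 to 10.
#'
#' @param grams Numeric vector of length 10: grams consumed per MDD-W food
#'   group, ordered as [mddw_food_groups()].
#' @param threshold_g Consumption threshold in grams (default 15).
#' @return Integer in 0..10.
#' @export
compute_wdd <- function(grams, threshold_g = 15) {
  if (!is.numeric(grams) || length(grams) != 10L)
    stop("`grams` must be a numeric vector with one entry per MDD-W food group (10)",
         call. = FALSE)
  if (anyNA(grams) || any(grams < 0))
    stop("`grams` must be non-negative and free of missing values", call. = FALSE)
  if (!is.numeric(threshold_g) || length(threshold_g) != 1L || threshold_g <= 0)
    stop("`threshold_g` must be a single positive number", call. = FALSE)
  as.integer(sum(grams >= threshold_g))
}

#' Minimum Dietary Diversity-Women indicator
#'
#' Binary indicator equal to 1 when a mother consumed at least 5 of the 10
#' food groups (WDD >= 5).
#'
#' @param wdd Integer dietary diversity score in 0..10 (vectorised).
#' @return Integer vector of 0/1.
#' @export
compute_mddw <- function(wdd) {
  if (!is.numeric(wdd) || anyNA(wdd) || any(wdd < 0 | wdd > 10))
    stop("`wdd` must lie in [0, 10]", call. = FALSE)
  as.integer(wdd >= 5)
}

food_sources <- c("purchase", "self_production", "gathering", "gift")

check_item_records <- function(items) {
  stopifnot(is.data.frame(items))
  need <- c("mother_id", "food_name", "source")
  miss <- setdiff(need, names(items))
  if (length(miss))
    stop("food-item records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(items)) {
    if (length(unique(items$mother_id)) > 1L)
      stop("food-item records mix several mothers; supply one mother-season at a time",
           call. = FALSE)
    bad <- setdiff(unique(items$source), food_sources)
    if (length(bad))
      stop("unknown food source(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(items)
}

#' Market diversity: distinct purchased foods over a 7-day recall
#'
#' Counts the distinct food items a mother consumed that were sourced by
#' purchase. Repeat purchases of the same food count once; the same food
#' obtained through another source (gift, self-production, gathering) does
#' not add to the purchase tally.
#'
#' @param items Data frame of 7-day food-item records for one mother-season
#'   with columns `mother_id`, `food_name`, `source` (one of purchase,
#'   self_production, gathering, gift).
#' @return Non-negative integer count.
#' @export
compute_market_diversity <- function(items) {
  check_item_records(items)
  if (!nrow(items)) return(0L)
  length(unique(items$food_name[items$source == "purchase"]))
}

#' Distinct-food counts by source
#'
#' Counts the distinct foods a mother consumed over the 7-day recall overall
#' and separately for each source. A food consumed under several sources
#' counts once per source and once overall, so the per-source counts can sum
#' to more than the overall count.
#'
#' @inheritParams compute_market_diversity
#' @return Named integer vector: overall, purchased, self_produced, gathered,
#'   gift.
#' @export
compute_source_profile <- function(items) {
  check_item_records(items)
  cnt <- function(src) {
    if (!nrow(items)) return(0L)
    length(unique(items$food_name[items$source == src]))
  }
  c(overall       = if (nrow(items)) length(unique(items$food_name)) else 0L,
    purchased     = cnt("purchase"),
    self_produced = cnt("self_production"),
    gathered      = cnt("gathering"),
    gift          = cnt("gift"))
}

#' On-farm diversity: distinct species grown or collected by a household
#'
#' Counts distinct plant species a household (mother and father jointly) grew
#' or collected in a season, pooling cultivated, semi-wild and wild species
#' and all use categories (self-consumption, sale, both). Zero is a valid
#' value: landless or non-growing households occur.
#'
#' @param records Data frame of species records for one household-season with
#'   columns `household_id`, `species_name` and optionally `use`.
#' @return Non-negative integer count.
#' @export
compute_ofd <- function(records) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(c("household_id", "species_name"), names(records))
  if (length(miss))
    stop("species records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(records)) return(0L)
  if (length(unique(records$household_id)) > 1L)
    stop("species records mix several households; supply one household-season at a time",
         call. = FALSE)
  if ("use" %in% names(records)) {
    bad <- setdiff(unique(records$use), c("self_consumption", "sale", "both"))
    if (length(bad))
      stop("unknown species use(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  length(unique(records$species_name))
}

#' Asset-based socioeconomic index
#'
#' Fits a one-factor model to the six standardized household asset counts
#' (bicycles, motorcycles, motor vehicles, radios, TVs, cellphones) pooled
#' over both survey rounds and returns the predicted first-factor score per
#' household. The score is oriented so that it correlates positively with
#' total asset ownership and has mean approximately zero over the sample.
#' When the factor solution is degenerate (non-convergence, Heywood case) or
#' there are fewer households than asset types, the first principal component
#' of the standardized counts is used instead, with a warning.
#'
#' @param assets Data frame with column `household_id` and the six asset-count
#'   columns named as in [ses_asset_types()], one row per household (pooled
#'   across seasons).
#' @return Data frame with columns `household_id`, `ses`.
#' @export
compute_ses_index <- function(assets) {
  stopifnot(is.data.frame(assets))
  cols <- ses_asset_types()
  miss <- setdiff(c("household_id", cols), names(assets))
  if (length(miss))
    stop("asset table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(assets$household_id))
    stop("asset table must have one pooled row per household", call. = FALSE)
  x <- as.matrix(assets[cols])
  if (nrow(x) < 2L)
    stop("at least two households are needed for the socioeconomic index",
         call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("asset counts must be non-negative integers without missing values",
         call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep))
    stop("all asset columns are constant; the socioeconomic index is undefined",
         call. = FALSE)
  xs <- scale(x[, keep, drop = FALSE])

  score <- NULL
  if (nrow(xs) <= ncol(xs)) {
    warning("fewer households than asset types; using first principal component")
  } else {
    fa <- tryCatch(
      stats::factanal(xs, factors = 1, scores = "regression"),
      error = function(e) NULL)
    if (!is.null(fa)) {
      # Heywood guard: uniquenesses pinned at the optimizer floor signal a
      # degenerate solution
      if (all(fa$uniquenesses > 1e-3)) score <- as.numeric(fa$scores[, 1L])
    }
    if (is.null(score))
      warning("one-factor solution degenerate; using first principal component")
  }
  if (is.null(score)) {
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    score <- as.numeric(pc$x[, 1L])
  }
  total <- rowSums(x)
  if (stats::sd(total) > 0 && stats::cor(score, total) < 0) score <- -score
  data.frame(household_id = assets$household_id, ses = score - mean(score))
}
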