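# Hand-built micro-survey used for indicator exactness checks. Expected
# indicator values are computed by hand in the tests that use it.

tiny_household <- function() {
  assets <- rbind(
    hh1 = c(1, 0, 0, 1, 0, 2),
    hh2 = c(0, 0, 0, 0, 0, 0),
    hh3 = c(3, 2, 1, 2, 1, 4))
  colnames(assets) <- ses_asset_types()
  base <- data.frame(
    household_id = c("hh1", "hh1", "hh2", "hh3"),
    mother_id    = c("m1", "m1", "m2", "m3"),
    village_id   = c("v1", "v1", "v1", "v2"),
    market_shed  = c("urban", "urban", "urban", "rural"),
    season       = c("dry", "wet", "dry", "wet"),
    travel_time  = c(30, 30, 30, 55),
    landholdings = c(2, 2, 0, 1.5),
    father_nonag_sources = c(1, 1, 0, 2),
    father_ag_importance = c("very_important", "very_important", "minor", "important"),
    mother_nonag_sources = c(2, 2, 1, 0),
    mother_ag_importance = c("important", "important", "not_important", "very_important"),
    mother_age = c(28, 28, 34, 22),
    mother_education = c(2, 2, 0, 5),
    mother_ethnicity = c(1, 1, 0, 0),
    family_size = c(6, 6, 4, 7),
    temp_range = c(9, 9, 9, 9.2),
    precip_cv = c(54, 54, 54, 56),
    precip_range = c(168, 168, 168, 174),
    stringsAsFactors = FALSE)
  cbind(base, as.data.frame(assets[base$household_id, , drop = FALSE],
                            row.names = seq_len(nrow(base))))
}

tiny_recall <- function() {
  rbind(
    data.frame(mother_id = "m1", season = "dry",
               food_group = c(1, 2, 3), grams = c(200, 15, 14.999)),
    data.frame(mother_id = "m1", season = "wet",
               food_group = 1:5, grams = rep(15, 5)),
    data.frame(mother_id = "m3", season = "wet",
               food_group = 1:10, grams = rep(20, 10)))
}

tiny_food_items <- function() {
  rbind(
    data.frame(mother_id = "m1", season = "dry",
               food_name = c("rice", "rice", "maize"),
               source = c("purchase", "purchase", "self_production")),
    data.frame(mother_id = "m1", season = "wet",
               food_name = c("okra", "okra", "bean"),
               source = c("purchase", "gift", "purchase")),
    data.frame(mother_id = "m3", season = "wet",
               food_name = c("fish", "oil", "salt", "leaf"),
               source = c("purchase", "purchase", "purchase", "gathering")))
}

tiny_species <- function() {
  rbind(
    data.frame(household_id = "hh1", season = "dry",
               species_name = c("maize", "maize"),
               use = c("sale", "self_consumption")),
    data.frame(household_id = "hh1", season = "wet",
               species_name = paste0("sp", 1:5), use = "both"),
    data.frame(household_id = "hh3", season = "wet",
               species_name = c("yam", "okra"), use = "self_consumption"))
}

tiny_bundle <- function() {
  survey_bundle(tiny_household(), tiny_food_items(), tiny_recall(),
                tiny_species())
}

# expected indicator table for the micro-survey, worked out by hand:
#   m1 dry: groups >= 15 g are 1 and 2 -> WDD 2; purchased distinct = rice -> MD 1
#   m1 wet: 5 groups at exactly 15 g -> WDD 5, MDDW 1; purchased okra+bean -> MD 2
#   m2 dry: no recall rows, no foods -> WDD 0, MD 0
#   m3 wet: all 10 groups -> WDD 10; fish/oil/salt purchased -> MD 3
#   hh1 dry: maize under two uses -> OFD 1; hh1 wet: 5 species -> OFD 5
#   hh2 dry: none -> OFD 0; hh3 wet: 2 species -> OFD 2
tiny_expected <- function() {
  data.frame(
    mother_id = c("m1", "m1", "m2", "m3"),
    season = c("dry", "wet", "dry", "wet"),
    WDD = c(2L, 5L, 0L, 10L),
    MDDW = c(0L, 1L, 0L, 1L),
    MD = c(1L, 2L, 0L, 3L),
    OFD = c(1L, 5L, 0L, 2L),
    stringsAsFactors = FALSE)
}

# single linear just-identified equation with known OLS solution
linear_test_equation <- function(n = 200, seed = 1) {
  set.seed(seed)
  X <- cbind(constant = 1, x1 = rnorm(n, 2, 1.5), x2 = runif(n))
  y <- drop(X %*% c(0.5, 1.2, -0.8)) + rnorm(n)
  list(eq = list(lin = list(y = y, W = X, Z = X, link = "linear")), X = X, y = y)
}
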