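# Synthetic household-survey generator. Emulates the statistical structure
# the three-equation analysis assumes: villages nested in three market-sheds,
# two survey rounds with partial panel overlap, a point mass of landless
# households, asset counts driven by a latent wealth factor, village-level
# travel times (with quadratic effects) and climate, and a shared latent
# household shock that enters all three outcome equations and makes on-farm
# and market diversity endogenous in the dietary-diversity equation.
#
# Count mode draws the three outcomes directly from the structural equations;
# survey mode additionally realizes item-level 7-day food records, a 24-hour
# gram recall and a species inventory whose recomputed indicators reproduce
# the generated counts exactly (round-trip identity).

synth_params_default <- function() {
  list(
    dd_x = c(urban_shed = 0.093, semiurban_shed = -0.023,
             travel_time = 0.007, travel_time_sq = -0.0006,
             father_nonag_sources = -0.013,
             father_ag_very_important = -0.054, father_ag_important = -0.08,
             mother_nonag_sources = -0.025,
             mother_ag_very_important = -0.009, mother_ag_important = -0.052,
             mother_age = -0.001, mother_education = 0.002,
             mother_ethnicity = 0.062, family_size = -0.001,
             temp_range = -0.297, precip_cv = -0.039, precip_range = 0.004,
             season_dry = 0.208),
    md_x = c(urban_shed = -0.794, semiurban_shed = -2.653,
             travel_time = -0.196, travel_time_sq = 0.001,
             father_nonag_sources = 0.285,
             father_ag_very_important = -0.27, father_ag_important = -0.225,
             mother_nonag_sources = 0.225,
             mother_ag_very_important = -2.512, mother_ag_important = -0.507,
             mother_age = 0.097, mother_education = 0.306,
             mother_ethnicity = -3.026, family_size = 0.053,
             temp_range = -5.349, precip_cv = 0.711, precip_range = -0.06,
             season_dry = -1.153),
    ofd_x = c(urban_shed = 0.543, semiurban_shed = -0.083,
              travel_time = 0.016, travel_time_sq = -0.0002,
              father_nonag_sources = 0.018,
              father_ag_very_important = 0.5, father_ag_important = 0.485,
              mother_nonag_sources = 0.153,
              mother_ag_very_important = 0.362, mother_ag_important = 0.383,
              mother_age = -0.007, mother_education = -0.004,
              mother_ethnicity = 0.051, family_size = 0.031,
              temp_range = -1.247, precip_cv = -0.038, precip_range = 0.001,
              season_dry = -0.516),
    md_z = c(landholdings = -0.315, landholdings_sq = 0.002, SES = 1.148),
    ofd_z = c(landholdings = 0.11, landholdings_sq = -0.005, SES = -0.017),
    delta = 0.036,
    zeta = 0.023
  )
}

#' Configuration of the synthetic survey generator
#'
#' Defaults mirror the study layout: 9/11/13 villages in the urban,
#' semi-urban and rural market-sheds, about 15 households interviewed per
#' village and season, two seasons with a panel-overlap fraction of 302/652,
#' a landless point mass, and structural slope coefficients taken from the
#' estimated system (equation intercepts are calibrated at generation time so
#' the mean outcomes land at their survey levels). The shared household
#' shock has unit scale with loadings `kappa` per equation; exponential-link
#' loadings are mean-centered so the structural residuals stay mean zero
#' given the exogenous variables.
#'
#' @param villages_per_shed Named integer vector (urban, semi_urban, rural).
#' @param households_per_village Distinct households per village (each
#'   appears in one or both seasons according to `panel_overlap`).
#' @param panel_overlap Probability a household is interviewed in both
#'   seasons.
#' @param n_rows If given, `households_per_village` is rescaled so the
#'   expected number of mother-season rows is about `n_rows`.
#' @param params List of true parameter vectors (see
#'   `divtriad:::synth_params_default`).
#' @param sigma_eta Scale of the shared household shock (0 switches
#'   endogeneity off).
#' @param kappa Named loadings of the shock in the dd, md and ofd equations.
#' @param landless_prob Probability a household holds no land.
#' @param landholding_meanlog,landholding_sdlog Log-normal landholdings (ha)
#'   for non-landless households.
#' @param travel_mean,travel_sd,travel_range Village travel time to the
#'   reference market (minutes), truncated normal.
#' @param md_noise_sd Standard deviation of the market-diversity noise.
#' @param target_means Named vector of calibration targets for the mean
#'   outcomes (dd, md, ofd).
#' @param dd_family Conditional family of the dietary-diversity draw.
#'   `"binomial"` (default) draws the 0-10 score as 10 group indicators with
#'   common success probability `exp(index)/10`, the count-mode counterpart
#'   of the survey-mode per-group indicators; it reproduces the
#'   underdispersion of an observed group-count score and keeps the
#'   exponential mean exact wherever the mean stays below 10.  `"poisson"`
#'   draws an unbounded count with the same mean and truncates it at 10,
#'   which reintroduces the tension between a Poisson specification and a
#'   bounded score.
#' @param cap_dd If `TRUE` (default) the score is kept within 0-10 (the
#'   binomial family satisfies this by construction; the Poisson family is
#'   truncated); `FALSE` with the Poisson family leaves the draw uncapped,
#'   which makes the exponential-mean model exactly correct and is useful
#'   for estimator-consistency checks.
#' @param dd_instrument_leak Optional named vector over instrument names
#'   (`landholdings`, `landholdings_sq`, `SES`) added to the
#'   dietary-diversity linear index. A nonzero leak violates the exclusion
#'   restriction, which the overidentification test should detect; the
#'   default `NULL` keeps the instruments valid.
#' @param use_true_wealth If `TRUE` the latent wealth factor itself is used
#'   as the socioeconomic index; by default the index is re-estimated from
#'   the generated asset counts by factor analysis, mimicking the
#'   generated-regressor situation of real data.
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(villages_per_shed = c(urban = 9, semi_urban = 11,
                                               rural = 13),
                         households_per_village = 15,
                         panel_overlap = 302 / 652,
                         n_rows = NULL,
                         params = synth_params_default(),
                         sigma_eta = 1,
                         kappa = c(dd = 0.25, md = 1.5, ofd = 0.25),
                         landless_prob = 0.25,
                         landholding_meanlog = 0.45,
                         landholding_sdlog = 0.75,
                         travel_mean = 31, travel_sd = 12,
                         travel_range = c(5, 60),
                         md_noise_sd = 5,
                         target_means = c(dd = 4.5, md = 17.9, ofd = 5),
                         dd_instrument_leak = NULL,
                         use_true_wealth = FALSE,
                         dd_family = c("binomial", "poisson"),
                         cap_dd = TRUE,
                         seed = 1L) {
  dd_family <- match.arg(dd_family)
  stopifnot(sigma_eta >= 0, panel_overlap >= 0, panel_overlap <= 1,
            landless_prob >= 0, landless_prob <= 1,
            landholding_sdlog > 0, travel_sd > 0, md_noise_sd > 0,
            all(c("dd", "md", "ofd") %in% names(kappa)))
  if (!is.null(n_rows)) {
    expected_per_hh <- 1 + panel_overlap
    households_per_village <- max(
      2L, round(n_rows / (sum(villages_per_shed) * expected_per_hh)))
  }
  structure(list(
    villages_per_shed = villages_per_shed,
    households_per_village = households_per_village,
    panel_overlap = panel_overlap,
    params = params, sigma_eta = sigma_eta, kappa = kappa,
    landless_prob = landless_prob,
    landholding_meanlog = landholding_meanlog,
    landholding_sdlog = landholding_sdlog,
    travel_mean = travel_mean, travel_sd = travel_sd,
    travel_range = travel_range,
    md_noise_sd = md_noise_sd, target_means = target_means,
    dd_instrument_leak = dd_instrument_leak,
    use_true_wealth = use_true_wealth, dd_family = dd_family, cap_dd = cap_dd,
    study_exact = FALSE, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Configuration reproducing the study's sample shape
#'
#' A preset with 33 villages, 652 distinct households of which exactly 302
#' appear in both seasons (472 dry-season and 482 wet-season interviews), so
#' the generated bundle has exactly 954 mother-season rows before any
#' missingness.
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_study <- function(seed = 1L, ...) {
  cfg <- synth_config(seed = seed, ...)
  cfg$study_exact <- TRUE
  cfg$study_counts <- list(n_households = 652L, n_both = 302L,
                           n_dry_only = 170L, n_wet_only = 180L)
  cfg
}

#' Configuration with strong, well-instrumented endogeneity
#'
#' A named scenario for endogeneity-power experiments: the shared household
#' shock gets large loadings in all three equations (`kappa = c(dd = 0.4,
#' md = 4, ofd = 0.8)`) and the excluded instruments' structural slopes are
#' multiplied by `z_mult`, since a control-function test can only detect
#' endogeneity through the variation its instruments explain. The
#' dietary-diversity loading stays moderate because the bounded 0-10 score
#' cannot carry an arbitrarily large multiplicative shock.
#'
#' @param seed Integer seed.
#' @param z_mult Multiplier on the instrument slopes (default 3).
#' @param ... Further arguments passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_endogenous <- function(seed = 1L, z_mult = 3, ...) {
  p <- synth_params_default()
  p$md_z <- p$md_z * z_mult
  p$ofd_z <- p$ofd_z * z_mult
  synth_config(seed = seed, params = p,
               kappa = c(dd = 0.4, md = 4, ofd = 0.8), ...)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

asset_model_default <- function() {
  list(intercepts = c(bicycles = -0.36, motorcycles = -1.05,
                      motor_vehicles = -3.5, radios = -0.22,
                      tvs = -2.1, cellphones = -0.7),
       loadings = c(bicycles = 0.9, motorcycles = 1.2, motor_vehicles = 1.3,
                    radios = 1.0, tvs = 1.3, cellphones = 1.2))
}

#' Generate a synthetic survey data set
#'
#' @param config A [synth_config()].
#' @param mode `"count"` draws the three outcomes directly from the
#'   structural equations and returns them as a ready indicator table;
#'   `"survey"` additionally realizes the item-level food, gram-recall and
#'   species tables, so the whole bundle can be pushed through
#'   [compute_indicators()].
#' @return Object of class `synth_data`: list with `household` (household
#'   table), `indicators` (indicator table with the generated counts),
#'   `bundle` (a [survey_bundle()], survey mode only), `truth` (true
#'   parameters including calibrated intercepts, the shared shock `eta`, the
#'   latent wealth `w`, and the cap-saturation share) and `config`.
#' @export
synth_generate <- function(config, mode = c("count", "survey")) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  set.seed(config$seed)
  prm <- config$params

  ## villages ------------------------------------------------------------
  shed <- rep(names(config$villages_per_shed), config$villages_per_shed)
  n_vil <- length(shed)
  vil <- data.frame(
    village_id = sprintf("v%02d", seq_len(n_vil)),
    market_shed = shed,
    travel_time = rtruncnorm1(n_vil, config$travel_mean, config$travel_sd,
                              config$travel_range[1], config$travel_range[2]),
    # villages lie in three adjacent districts of one agro-ecological zone,
    # so interpolated climate varies little between them
    temp_range = stats::rnorm(n_vil, 9, 0.2),
    precip_cv = stats::rnorm(n_vil, 55, 2),
    precip_range = stats::rnorm(n_vil, 170, 8),
    stringsAsFactors = FALSE)

  ## households ----------------------------------------------------------
  if (isTRUE(config$study_exact)) {
    sc <- config$study_counts
    n_hh <- sc$n_households
    base <- n_hh %/% n_vil
    extra <- n_hh %% n_vil
    hh_village <- rep(vil$village_id, times = base +
                        (seq_len(n_vil) <= extra))
    membership <- sample(rep(c("both", "dry", "wet"),
                             c(sc$n_both, sc$n_dry_only, sc$n_wet_only)))
  } else {
    hh_village <- rep(vil$village_id, each = config$households_per_village)
    n_hh <- length(hh_village)
    membership <- ifelse(stats::runif(n_hh) < config$panel_overlap, "both",
                         sample(c("dry", "wet"), n_hh, replace = TRUE))
  }
  n_hh <- length(hh_village)
  am <- asset_model_default()
  w <- stats::rnorm(n_hh)
  eta <- if (config$sigma_eta > 0)
    stats::rnorm(n_hh, 0, config$sigma_eta) else numeric(n_hh)
  assets <- vapply(names(am$intercepts), function(a)
    stats::rpois(n_hh, exp(am$intercepts[[a]] + am$loadings[[a]] * w)),
    numeric(n_hh))
  landless <- stats::runif(n_hh) < config$landless_prob
  land <- ifelse(landless, 0,
                 stats::rlnorm(n_hh, config$landholding_meanlog,
                               config$landholding_sdlog))
  hh <- data.frame(
    household_id = sprintf("hh%05d", seq_len(n_hh)),
    mother_id = sprintf("m%05d", seq_len(n_hh)),
    village_id = hh_village,
    landholdings = land,
    mother_age = round(rtruncnorm1(n_hh, 29.5, 6, 15, 49)),
    mother_education = stats::rpois(n_hh, 1.2),
    mother_ethnicity = stats::rbinom(n_hh, 1, 0.4),
    family_size = 2 + stats::rpois(n_hh, 4),
    stringsAsFactors = FALSE)
  hh <- cbind(hh, as.data.frame(assets))

  ## household-season rows ----------------------------------------------
  seasons <- lapply(seq_len(n_hh), function(i) switch(membership[i],
    both = c("dry", "wet"), dry = "dry", wet = "wet"))
  row_hh <- rep(seq_len(n_hh), lengths(seasons))
  df <- hh[row_hh, , drop = FALSE]
  df$season <- unlist(seasons)
  df <- cbind(df, vil[match(df$village_id, vil$village_id),
                      c("market_shed", "travel_time", "temp_range",
                        "precip_cv", "precip_range")])
  rownames(df) <- NULL
  n <- nrow(df)
  ag_levels <- ag_importance_levels
  df$father_nonag_sources <- stats::rpois(n, 1.0)
  df$mother_nonag_sources <- stats::rpois(n, 1.4)
  df$father_ag_importance <- sample(ag_levels, n, replace = TRUE,
                                    prob = c(0.35, 0.30, 0.20, 0.15))
  df$mother_ag_importance <- sample(ag_levels, n, replace = TRUE,
                                    prob = c(0.20, 0.20, 0.30, 0.30))

  ## structural indexes --------------------------------------------------
  dx <- df
  dx$urban_shed <- as.numeric(dx$market_shed == "urban")
  dx$semiurban_shed <- as.numeric(dx$market_shed == "semi_urban")
  dx$travel_time_sq <- dx$travel_time^2
  dx$season_dry <- as.numeric(dx$season == "dry")
  dx$father_ag_very_important <- as.numeric(dx$father_ag_importance == "very_important")
  dx$father_ag_important <- as.numeric(dx$father_ag_importance == "important")
  dx$mother_ag_very_important <- as.numeric(dx$mother_ag_importance == "very_important")
  dx$mother_ag_important <- as.numeric(dx$mother_ag_importance == "important")
  xmat <- function(coefs) drop(as.matrix(dx[names(coefs)]) %*% coefs)
  w_row <- w[row_hh]
  eta_row <- eta[row_hh]
  zmat <- function(coefs) {
    zd <- cbind(landholdings = df$landholdings,
                landholdings_sq = df$landholdings^2, SES = w_row)
    drop(zd[, names(coefs), drop = FALSE] %*% coefs)
  }
  kap <- config$kappa
  s2 <- config$sigma_eta^2
  # exponential-link shock terms are centered so E[exp(.)] = 1
  sh_ofd <- kap[["ofd"]] * eta_row - kap[["ofd"]]^2 * s2 / 2
  sh_dd  <- kap[["dd"]]  * eta_row - kap[["dd"]]^2  * s2 / 2

  tg <- config$target_means
  idx_ofd <- xmat(prm$ofd_x) + zmat(prm$ofd_z) + sh_ofd
  int_ofd <- log(tg[["ofd"]]) - log(mean(exp(idx_ofd)))
  OFD <- stats::rpois(n, exp(int_ofd + idx_ofd))

  idx_md <- xmat(prm$md_x) + zmat(prm$md_z) + kap[["md"]] * eta_row
  int_md <- tg[["md"]] - mean(idx_md)
  MD <- as.integer(pmax(0, round(int_md + idx_md +
                                   stats::rnorm(n, 0, config$md_noise_sd))))

  idx_dd <- xmat(prm$dd_x) + prm$delta * OFD + prm$zeta * MD + sh_dd
  if (!is.null(config$dd_instrument_leak))
    idx_dd <- idx_dd + zmat(config$dd_instrument_leak)
  int_dd <- log(tg[["dd"]]) - log(mean(exp(idx_dd)))
  mu_dd <- exp(int_dd + idx_dd)
  if (identical(config$dd_family, "poisson")) {
    DD_raw <- stats::rpois(n, mu_dd)
    saturation <- mean(DD_raw > 10)
    DD <- if (isTRUE(config$cap_dd)) pmin(DD_raw, 10L) else DD_raw
  } else {
    DD <- stats::rbinom(n, 10L, pmin(mu_dd / 10, 1))
    saturation <- mean(mu_dd > 10)
  }
  if (saturation > 0.2)
    warning(sprintf(
      "dietary-diversity mean exceeds the 10-group bound for %.1f%% of rows; the exponential-mean model is a poor approximation under this config",
      100 * saturation))

  ## SES: estimated factor score (default) or true latent wealth ---------
  asset_tab <- data.frame(household_id = hh$household_id,
                          hh[names(am$intercepts)])
  ses_hh <- if (config$use_true_wealth) {
    data.frame(household_id = hh$household_id, ses = w - mean(w))
  } else {
    stats::setNames(compute_ses_index(asset_tab), c("household_id", "ses"))
  }
  SES <- ses_hh$ses[match(df$household_id, ses_hh$household_id)]

  indicators <- data.frame(
    mother_id = df$mother_id, household_id = df$household_id,
    season = df$season, WDD = DD, MDDW = compute_mddw(pmin(DD, 10L)), MD = MD,
    OFD = OFD, SES = SES, stringsAsFactors = FALSE)

  household <- df[c("household_id", "mother_id", "village_id", "market_shed",
                    "season", "travel_time", "landholdings",
                    "father_nonag_sources", "father_ag_importance",
                    "mother_nonag_sources", "mother_ag_importance",
                    "mother_age", "mother_education", "mother_ethnicity",
                    "family_size", "temp_range", "precip_cv", "precip_range",
                    names(am$intercepts))]

  truth <- list(
    params = prm,
    intercepts = c(dd = unname(int_dd), md = unname(int_md),
                   ofd = unname(int_ofd)),
    eta = eta, w = w, household_id = hh$household_id,
    saturation = saturation)

  out <- list(mode = mode, household = household, indicators = indicators,
              truth = truth, config = config)
  if (mode == "survey")
    out$bundle <- realize_survey_tables(household, indicators)
  class(out) <- "synth_data"
  out
}

# Build item-level tables whose recomputed indicators reproduce the generated
# counts exactly.
realize_survey_tables <- function(household, indicators) {
  n <- nrow(indicators)
  food_pool <- sprintf("food_%03d", 1:210)
  species_pool <- sprintf("species_%02d", 1:65)
  groups <- mddw_food_groups()
  # per-group propensities shaped like the observed consumption profile:
  # staples always, flesh foods and leafy vegetables common, dairy and eggs rare
  group_w <- c(1e6, 0.5, 0.4, 0.02, 0.7, 0.02, 0.55, 0.2, 0.45, 0.55)

  items <- vector("list", n)
  recall <- vector("list", n)
  species <- vector("list", n)
  for (i in seq_len(n)) {
    mid <- indicators$mother_id[i]
    hid <- indicators$household_id[i]
    sea <- indicators$season[i]
    md <- indicators$MD[i]
    wdd <- indicators$WDD[i]
    ofd <- indicators$OFD[i]

    src_n <- c(purchase = md,
               self_production = stats::rpois(1, 3.5),
               gathering = stats::rpois(1, 1.6),
               gift = stats::rpois(1, 1.3))
    rows <- lapply(names(src_n), function(s) {
      k <- min(src_n[[s]], length(food_pool))
      if (k == 0) return(NULL)
      data.frame(mother_id = mid, season = sea,
                 food_name = sample(food_pool, k), source = s,
                 stringsAsFactors = FALSE)
    })
    it <- do.call(rbind, rows)
    if (!is.null(it) && nrow(it) > 2 && stats::runif(1) < 0.3) {
      # duplicated record of an already-listed item (repeat purchase etc.)
      it <- rbind(it, it[sample(nrow(it), 1L), ])
    }
    items[[i]] <- it

    if (wdd > 0) {
      consumed <- c(1L, sample(2:10, wdd - 1L, prob = group_w[2:10]))[seq_len(wdd)]
    } else {
      consumed <- integer()
    }
    grams <- ifelse(seq_len(10) %in% consumed,
                    15 + stats::rexp(10, 1 / 110),
                    ifelse(stats::runif(10) < 0.7, 0,
                           stats::runif(10, 0, 14.9)))
    keep <- grams > 0
    if (any(keep))
      recall[[i]] <- data.frame(mother_id = mid, season = sea,
                                food_group = which(keep),
                                grams = grams[keep],
                                stringsAsFactors = FALSE)

    if (ofd > 0) {
      sp <- sample(species_pool, min(ofd, length(species_pool)))
      species[[i]] <- data.frame(
        household_id = hid, season = sea, species_name = sp,
        use = sample(c("self_consumption", "both", "sale"), length(sp),
                     replace = TRUE, prob = c(0.45, 0.40, 0.15)),
        stringsAsFactors = FALSE)
    }
  }
  survey_bundle(household,
                do.call(rbind, items),
                do.call(rbind, recall),
                do.call(rbind, species))
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("Synthetic survey data (%s mode): %d mother-season rows, %d households, %d villages\n",
              x$mode, nrow(x$indicators),
              length(unique(x$indicators$household_id)),
              length(unique(x$household$village_id))))
  cat(sprintf("  mean DD %.2f | mean MD %.2f | mean OFD %.2f | cap saturation %.2f%%\n",
              mean(x$indicators$WDD), mean(x$indicators$MD),
              mean(x$indicators$OFD), 100 * x$truth$saturation))
  invisible(x)
}

#' Write synthetic data to disk
#'
#' Writes the four bundle CSVs (survey mode) or the household and indicator
#' CSVs (count mode), plus `truth.json` holding the true parameters,
#' calibrated intercepts, shared shock and latent wealth for oracle checks.
#'
#' @param sim A `synth_data` object from [synth_generate()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synth_data <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$bundle)) {
    write_survey_bundle(sim$bundle, dir)
  } else {
    utils::write.csv(sim$household, file.path(dir, "household.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(sim$indicators, file.path(dir, "indicators.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a generator configuration from YAML
#'
#' Reads a YAML file whose fields are arguments of [synth_config()] (the
#' optional field `study_shape: true` selects [synth_config_study()]). A
#' study-shape preset ships with the package:
#' `system.file("extdata", "preset_study.yaml", package = "divtriad")`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  study <- isTRUE(raw$study_shape)
  raw$study_shape <- NULL
  for (nm in c("villages_per_shed", "kappa", "target_means",
               "dd_instrument_leak"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$params))
    raw$params <- utils::modifyList(synth_params_default(),
                                    lapply(raw$params, unlist))
  if (!is.null(seed)) raw$seed <- seed
  do.call(if (study) synth_config_study else synth_config, raw)
}

#' Generate a bundle with the study's sample shape
#'
#' Convenience wrapper: [synth_config_study()] plus [synth_generate()].
#'
#' @param seed Integer seed.
#' @param mode Passed to [synth_generate()].
#' @param ... Passed to [synth_config_study()].
#' @return A `synth_data` object.
#' @export
emulate_study_shape <- function(seed = 1L, mode = "survey", ...) {
  synth_generate(synth_config_study(seed = seed, ...), mode = mode)
}
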