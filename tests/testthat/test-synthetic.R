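test_that("generation is deterministic given a seed", {
  a <- synth_generate(synth_config(n_rows = 300, seed = 61), mode = "survey")
  b <- synth_generate(synth_config(n_rows = 300, seed = 61), mode = "survey")
  expect_identical(a$indicators, b$indicators)
  expect_identical(a$household, b$household)
  for (nm in names(a$bundle)) expect_identical(a$bundle[[nm]], b$bundle[[nm]])
  c_ <- synth_generate(synth_config(n_rows = 300, seed = 62), mode = "count")
  expect_false(identical(a$indicators$WDD, c_$indicators$WDD))
})

test_that("study-shape preset reproduces the survey layout", {
  sim <- emulate_study_shape(seed = 63, mode = "count")
  ind <- sim$indicators
  expect_identical(length(unique(sim$household$village_id)), 33L)
  expect_true(nrow(ind) >= 940 && nrow(ind) <= 960)
  n_dry <- sum(ind$season == "dry")
  n_wet <- sum(ind$season == "wet")
  expect_lt(abs(n_dry - 472) / 472, 0.02)
  expect_lt(abs(n_wet - 482) / 482, 0.02)
  both <- sum(table(ind$household_id) == 2)
  expect_lt(abs(both - 302) / 302, 0.02)
  # landless share within the survey's observed range
  hh <- sim$household[!duplicated(sim$household$household_id), ]
  expect_gt(mean(hh$landholdings == 0), 0.13)
  expect_lt(mean(hh$landholdings == 0), 0.35)
})

test_that("survey-mode bundles reproduce the generated counts through the indicator module", {
  sim <- emulate_study_shape(seed = 64, mode = "survey")
  ind <- compute_indicators(sim$bundle)
  key <- paste(ind$mother_id, ind$season)
  gen <- sim$indicators[match(key, paste(sim$indicators$mother_id,
                                         sim$indicators$season)), ]
  expect_identical(ind$WDD, gen$WDD)
  expect_identical(ind$MDDW, gen$MDDW)
  expect_identical(ind$MD, gen$MD)
  expect_identical(ind$OFD, gen$OFD)
  expect_equal(ind$SES, gen$SES, tolerance = 1e-10)
})

test_that("the shared shock is the only cross-equation link", {
  sim <- synth_generate(synth_config(n_rows = 5000, seed = 65, sigma_eta = 0),
                        mode = "count")
  des <- build_design(sim$household, sim$indicators)
  eq <- des$equations
  e <- eq$dd$y - suppressWarnings(
    stats::glm.fit(eq$dd$W, eq$dd$y, family = stats::quasipoisson()))$fitted.values
  u <- stats::lm.fit(eq$md$W, eq$md$y)$residuals
  v <- eq$ofd$y - suppressWarnings(
    stats::glm.fit(eq$ofd$W, eq$ofd$y, family = stats::quasipoisson()))$fitted.values
  expect_lt(abs(cor(e, u)), 0.05)
  expect_lt(abs(cor(e, v)), 0.05)
  expect_lt(abs(cor(u, v)), 0.05)
})

test_that("zero structural effects decouple the score from the diversity measures", {
  # with the shared shock off, delta = zeta = 0 makes the score independent
  # of the realized diversities given the covariates
  prm <- divtriad:::synth_params_default()
  prm$delta <- 0
  prm$zeta <- 0
  sim <- synth_generate(synth_config(n_rows = 5000, seed = 66, params = prm,
                                     sigma_eta = 0),
                        mode = "count")
  des <- build_design(sim$household, sim$indicators)
  eq <- des$equations
  x_cols <- setdiff(colnames(eq$dd$W), c("OFD", "MD"))
  e <- stats::lm.fit(eq$dd$W[, x_cols], eq$dd$y)$residuals
  ofd_r <- stats::lm.fit(eq$dd$W[, x_cols], eq$dd$W[, "OFD"])$residuals
  md_r <- stats::lm.fit(eq$dd$W[, x_cols], eq$dd$W[, "MD"])$residuals
  expect_lt(abs(cor(e, ofd_r)), 0.05)
  expect_lt(abs(cor(e, md_r)), 0.05)
})

test_that("the score's mean stays inside the 10-group bound for almost all rows", {
  # the exceedance share varies with the village-level draw; it stays small
  sim <- synth_generate(synth_config(n_rows = 4000, seed = 67), mode = "count")
  expect_lt(sim$truth$saturation, 0.06)
  expect_true(all(sim$indicators$WDD >= 0 & sim$indicators$WDD <= 10))
  expect_equal(mean(sim$indicators$WDD),
               unname(synth_config()$target_means["dd"]), tolerance = 0.15)
})

test_that("stronger shared shocks inflate the naive estimate monotonically", {
  naive_delta <- function(sigma) {
    mean(sapply(1:50, function(s) {
      sim <- synth_generate(synth_config(n_rows = 1200, seed = 400 + s,
                                         sigma_eta = sigma), mode = "count")
      des <- build_design(sim$household, sim$indicators)
      eq <- des$equations$dd
      suppressWarnings(stats::glm.fit(
        eq$W, eq$y, family = stats::quasipoisson()))$coefficients[["OFD"]]
    }))
  }
  b0 <- naive_delta(0)
  b1 <- naive_delta(1)
  b2 <- naive_delta(1.6)
  expect_lt(b0, b1)
  expect_lt(b1, b2)
})

test_that("synthetic data writes to disk with a truth record", {
  sim <- synth_generate(synth_config(n_rows = 200, seed = 68), mode = "survey")
  dir <- withr::local_tempdir()
  write_synth_data(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "household.csv", "food_items.csv", "recall.csv", "species.csv",
    "indicators.csv", "truth.json")))))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$params$delta, 0.036)
  expect_equal(tr$params$zeta, 0.023)
})

test_that("the YAML study preset loads into the exact study shape", {
  cfg <- read_synth_config(system.file("extdata", "preset_study.yaml",
                                       package = "divtriad"), seed = 69)
  sim <- synth_generate(cfg, mode = "count")
  expect_identical(nrow(sim$indicators), 954L)
})
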