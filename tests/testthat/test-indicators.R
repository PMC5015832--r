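test_that("dietary diversity score counts groups at or above the gram threshold", {
  expect_identical(compute_wdd(rep(0, 10)), 0L)
  expect_identical(compute_wdd(rep(15, 10)), 10L)
  expect_identical(compute_wdd(rep(1000, 10)), 10L)
  # 15 g boundary is inclusive; 14.999 g does not count
  expect_identical(compute_wdd(c(15, 14.999, rep(0, 8))), 1L)
  expect_identical(compute_wdd(c(10, 20, rep(0, 8)), threshold_g = 10), 2L)
})

test_that("dietary diversity score rejects malformed recalls", {
  expect_error(compute_wdd(rep(15, 9)), "10")
  expect_error(compute_wdd(c(rep(15, 9), -1)), "non-negative")
  expect_error(compute_wdd(c(rep(15, 9), NA)), "non-negative")
  expect_error(compute_wdd(rep(15, 10), threshold_g = 0), "positive")
})

test_that("dietary diversity score is monotone in every gram entry", {
  set.seed(41)
  for (i in 1:50) {
    g <- runif(10, 0, 40)
    base <- compute_wdd(g)
    j <- sample(10, 1)
    g2 <- g
    g2[j] <- g2[j] + runif(1, 0, 30)
    expect_gte(compute_wdd(g2), base)
  }
})

test_that("MDD-W flags five or more food groups", {
  expect_identical(compute_mddw(5L), 1L)
  expect_identical(compute_mddw(4L), 0L)
  expect_identical(compute_mddw(10L), 1L)
  expect_identical(compute_mddw(c(0, 4, 5, 9)), c(0L, 0L, 1L, 1L))
  expect_error(compute_mddw(11), "\\[0, 10\\]")
  expect_error(compute_mddw(-1), "\\[0, 10\\]")
})

test_that("market diversity counts distinct purchased foods only", {
  items <- data.frame(mother_id = "m", season = "dry",
                      food_name = c("rice", "rice", "maize"),
                      source = c("purchase", "purchase", "self_production"))
  expect_identical(compute_market_diversity(items), 1L)
  empty <- items[0, ]
  expect_identical(compute_market_diversity(empty), 0L)
  multi <- data.frame(mother_id = "m", season = "dry",
                      food_name = c("okra", "okra"),
                      source = c("purchase", "gift"))
  expect_identical(compute_market_diversity(multi), 1L)
  mixed <- rbind(items, data.frame(mother_id = "m2", season = "dry",
                                   food_name = "x", source = "gift"))
  expect_error(compute_market_diversity(mixed), "one mother")
  bad <- data.frame(mother_id = "m", food_name = "x", source = "barter")
  expect_error(compute_market_diversity(bad), "source")
})

test_that("source profile deduplicates within source and stays consistent", {
  one_each <- data.frame(
    mother_id = "m", food_name = c("a", "b", "c", "d"),
    source = c("purchase", "self_production", "gathering", "gift"))
  expect_identical(compute_source_profile(one_each),
                   c(overall = 4L, purchased = 1L, self_produced = 1L,
                     gathered = 1L, gift = 1L))
  two_src <- data.frame(mother_id = "m", food_name = c("a", "a"),
                        source = c("purchase", "gathering"))
  prof <- compute_source_profile(two_src)
  expect_identical(unname(prof["overall"]), 1L)
  expect_identical(unname(prof["purchased"]), 1L)
  expect_identical(unname(prof["gathered"]), 1L)
  expect_identical(compute_source_profile(one_each[0, ]),
                   c(overall = 0L, purchased = 0L, self_produced = 0L,
                     gathered = 0L, gift = 0L))
})

test_that("purchased count in the profile equals market diversity, order-invariantly", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(0:15, 1)
    items <- data.frame(
      mother_id = rep("m", n),
      food_name = sample(letters[1:6], n, replace = TRUE),
      source = sample(c("purchase", "self_production", "gathering", "gift"),
                      n, replace = TRUE))
    md <- compute_market_diversity(items)
    expect_identical(unname(compute_source_profile(items)["purchased"]), md)
    perm <- items[sample(nrow(items)), , drop = FALSE]
    expect_identical(compute_market_diversity(perm), md)
    expect_identical(compute_source_profile(perm)[["overall"]],
                     compute_source_profile(items)[["overall"]])
  }
})

test_that("on-farm diversity counts distinct species across uses", {
  expect_identical(compute_ofd(data.frame(household_id = character(),
                                          species_name = character())), 0L)
  dup <- data.frame(household_id = "h",
                    species_name = c("maize", "maize"),
                    use = c("sale", "self_consumption"))
  expect_identical(compute_ofd(dup), 1L)
  five <- data.frame(household_id = "h", species_name = paste0("s", 1:5),
                     use = "both")
  expect_identical(compute_ofd(five), 5L)
  expect_error(compute_ofd(data.frame(household_id = c("a", "b"),
                                      species_name = c("x", "y"))),
               "one household")
})

test_that("socioeconomic index orients, centers and rejects degenerate input", {
  flat <- data.frame(household_id = c("a", "b", "c"),
                     matrix(1L, 3, 6, dimnames = list(NULL, ses_asset_types())))
  expect_error(compute_ses_index(flat), "constant")

  two <- data.frame(household_id = c("poor", "rich"),
                    rbind(rep(0L, 6), rep(1L, 6)))
  names(two)[-1] <- ses_asset_types()
  res <- suppressWarnings(compute_ses_index(two))
  expect_gt(res$ses[res$household_id == "rich"],
            res$ses[res$household_id == "poor"])
  expect_lt(abs(mean(res$ses)), 1e-10)
})

test_that("socioeconomic index recovers a latent wealth ordering", {
  # independent oracle: simulate asset counts from a one-factor log-linear
  # model and check the fitted score tracks the latent draw
  set.seed(11)
  n <- 500
  w <- rnorm(n)
  loadings <- c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2)
  intercepts <- c(0, -0.3, -1, 0, -1, -0.2)
  counts <- sapply(1:6, function(j) rpois(n, exp(intercepts[j] + loadings[j] * w)))
  colnames(counts) <- ses_asset_types()
  assets <- data.frame(household_id = sprintf("h%03d", 1:n), counts)
  res <- compute_ses_index(assets)
  expect_gt(cor(res$ses, w, method = "spearman"), 0.8)
  expect_lt(abs(mean(res$ses)), 1e-8)
})

test_that("socioeconomic index is invariant to positive rescaling of an asset column", {
  set.seed(12)
  n <- 120
  w <- rnorm(n)
  counts <- sapply(1:6, function(j) rpois(n, exp(0.8 * w)))
  colnames(counts) <- ses_asset_types()
  assets <- data.frame(household_id = sprintf("h%03d", 1:n), counts)
  scaled <- assets
  scaled$bicycles <- scaled$bicycles * 3L
  expect_equal(compute_ses_index(assets)$ses, compute_ses_index(scaled)$ses,
               tolerance = 1e-8)
})
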