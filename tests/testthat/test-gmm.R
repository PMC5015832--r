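test_that("residuals and fitted means use the stated links", {
  sim <- synth_generate(synth_config(n_rows = 150, seed = 31), mode = "count")
  des <- build_design(sim$household, sim$indicators)
  p <- sum(vapply(des$equations, function(eq) ncol(eq$W), integer(1)))
  zero <- rep(0, p)
  r <- gmm_residuals(zero, des)
  expect_equal(r$dd, des$equations$dd$y - 1)   # exp(0) = 1
  expect_equal(r$md, des$equations$md$y)       # identity link at 0
  expect_equal(r$ofd, des$equations$ofd$y - 1)
  f <- fitted_means(zero, des)
  expect_true(all(f$dd == 1))
  set.seed(1)
  any_params <- rnorm(p, 0, 0.01)
  f2 <- fitted_means(any_params, des)
  expect_true(all(f2$dd > 0))
  expect_true(all(f2$ofd > 0))
})

test_that("overflowing linear indices are reported, not silently exponentiated", {
  eq <- list(e = list(y = c(1, 2), W = cbind(constant = c(1000, 1000)),
                      Z = cbind(constant = c(1, 1)), link = "exponential"))
  expect_error(gmm_residuals(1, list(equations = eq)), "overflow")
})

test_that("moment matrix has the bookkeeping dimensions and the mean-residual column", {
  sim <- synth_generate(synth_config(n_rows = 150, seed = 32), mode = "count")
  des <- build_design(sim$household, sim$indicators)
  p <- sum(vapply(des$equations, function(eq) ncol(eq$W), integer(1)))
  m <- sum(vapply(des$equations, function(eq) ncol(eq$Z), integer(1)))
  g <- gmm_moments(rep(0, p), des)
  expect_identical(ncol(g$g), m)
  expect_identical(ncol(g$g), p + 1L)  # one overidentifying restriction
  expect_equal(g$gbar, colMeans(g$g))
  # the constant instrument column carries the mean residual
  r <- gmm_residuals(rep(0, p), des)
  expect_equal(unname(g$gbar["md.constant"]), mean(r$md))
})

test_that("sample moments vanish at the true parameters as n grows", {
  norm_at_truth <- function(n, seed) {
    cfg <- synth_config(n_rows = n, seed = seed, use_true_wealth = TRUE,
                        dd_family = "poisson", cap_dd = FALSE)
    sim <- synth_generate(cfg, mode = "count")
    des <- build_design(sim$household, sim$indicators)
    tr <- sim$truth
    theta <- c(tr$intercepts[["dd"]], tr$params$dd_x, tr$params$delta,
               tr$params$zeta,
               tr$intercepts[["md"]], tr$params$md_x, tr$params$md_z,
               tr$intercepts[["ofd"]], tr$params$ofd_x, tr$params$ofd_z)
    g <- gmm_moments(theta, des)
    # scale-free: norm of the standardized mean moments
    sds <- apply(g$g, 2, sd)
    sqrt(sum((g$gbar / sds)^2) / length(g$gbar))
  }
  small <- norm_at_truth(1000, 33)
  big <- norm_at_truth(10000, 34)
  expect_lt(big, small)
  expect_lt(big, 0.05)   # ~ 1/sqrt(n) scale at n = 1e4
  expect_lt(small, 0.12)
})

test_that("a just-identified linear equation reproduces least squares exactly", {
  fx <- linear_test_equation()
  fit <- fit_gmm_equations(fx$eq)
  ols <- stats::lm.fit(fx$X, fx$y)$coefficients
  expect_lt(max(abs(coef(fit) - ols)), 1e-8)
  expect_lt(fit$J, 1e-10)
  expect_identical(fit$dof_overid, 0L)
})

test_that("a just-identified exponential equation reproduces the Poisson fit", {
  set.seed(35)
  n <- 400
  X <- cbind(constant = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rpois(n, exp(drop(X %*% c(1, 0.3, -0.5))))
  eq <- list(pois = list(y = y, W = X, Z = X, link = "exponential"))
  fit <- fit_gmm_equations(eq)
  oracle <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::quasipoisson()))$coefficients
  expect_lt(max(abs(coef(fit) - oracle)), 1e-6)
})

test_that("J and estimates are invariant to instrument transformations", {
  set.seed(36)
  n <- 500
  x <- rnorm(n)
  z2 <- 0.7 * x + rnorm(n)
  z3 <- 0.5 * x + rnorm(n)
  y <- 1 + x + rnorm(n)
  Z <- cbind(constant = 1, z2 = z2, z3 = z3)
  W <- cbind(constant = 1, x = x)
  fit <- fit_gmm_equations(list(e = list(y = y, W = W, Z = Z, link = "linear")))

  # nonsingular recombination of the instruments
  A <- matrix(c(1, 0.5, -0.2, 0, 2, 0.3, 0, 0, -1.5), 3, 3)
  fit2 <- fit_gmm_equations(list(e = list(y = y, W = W, Z = Z %*% A,
                                          link = "linear")))
  expect_lt(abs(fit$J - fit2$J) / max(fit$J, 1e-12), 1e-6)
  expect_lt(max(abs(coef(fit) - coef(fit2))), 1e-6)

  # positive rescaling of one instrument column
  Zs <- Z
  Zs[, "z3"] <- Zs[, "z3"] * 40
  fit3 <- fit_gmm_equations(list(e = list(y = y, W = W, Z = Zs,
                                          link = "linear")))
  expect_lt(max(abs(coef(fit) - coef(fit3))), 1e-6)
})

test_that("singleton clusters reduce to the heteroskedasticity-robust covariance", {
  fx <- linear_test_equation(n = 150, seed = 5)
  f_null <- fit_gmm_equations(fx$eq, cluster = NULL)
  f_single <- fit_gmm_equations(fx$eq, cluster = seq_along(fx$y))
  expect_equal(vcov(f_null), vcov(f_single), tolerance = 1e-12)
})

test_that("re-iterating the weight matrix barely moves a well-separated optimum", {
  sim <- synth_generate(synth_config(n_rows = 1500, seed = 37), mode = "count")
  des <- build_design(sim$household, sim$indicators)
  two <- fit_gmm_system(des, weighting = "two_step")
  iter <- fit_gmm_system(des, weighting = "iterated")
  scale <- pmax(abs(coef(two)), 0.05)
  expect_lt(max(abs(coef(two) - coef(iter)) / scale), 0.05)
  expect_true(two$converged)
  expect_true(iter$converged)
})

test_that("system results serialize to CSV and JSON", {
  sim <- synth_generate(synth_config(n_rows = 400, seed = 38), mode = "count")
  des <- build_design(sim$household, sim$indicators)
  fit <- fit_gmm_system(des)
  dir <- withr::local_tempdir()
  write_gmm_results(fit, dir)
  tab <- utils::read.csv(file.path(dir, "coefficients.csv"))
  expect_identical(nrow(tab), length(unique(sub("^[a-z]+\\.", "",
                                                names(coef(fit))))))
  expect_true(all(c("dd_estimate", "md_estimate", "ofd_estimate",
                    "dd_stars") %in% names(tab)))
  js <- jsonlite::read_json(file.path(dir, "results.json"))
  expect_equal(js$J, fit$J, tolerance = 1e-10)
  expect_identical(js$n_obs, fit$n_obs)
  # stars implied by the reported p-values
  stars <- tab$dd_stars[match("OFD", tab$variable)]
  p <- fit$p["dd.OFD"]
  expect_identical(stars,
                   if (p < 0.001) "***" else if (p < 0.01) "**"
                   else if (p < 0.05) "*" else "")
})
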