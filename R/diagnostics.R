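# Specification tests: control-function Durbin-Wu-Hausman endogeneity test,
# Sargan-Hansen overidentification test, and first-stage weak-instrument
# diagnostics, all with cluster-robust covariances.

dd_equation_parts <- function(design) {
  eq <- design$equations$dd
  k_end <- eq$n_endogenous
  k <- ncol(eq$W)
  endog_names <- if (k_end > 0) colnames(eq$W)[(k - k_end + 1L):k] else character()
  list(eq = eq, endog = endog_names)
}

cluster_wald <- function(coefs, V, idx, label) {
  b <- coefs[idx]
  Vb <- V[idx, idx, drop = FALSE]
  Vb_inv <- tryCatch(solve(Vb), error = function(e)
    stop(label, ": singular covariance of the tested coefficients ",
         "(collinear columns?)", call. = FALSE))
  drop(t(b) %*% Vb_inv %*% b)
}

glm_frame <- function(y, X) {
  # X includes a constant column; drop it and let the formula add an intercept
  keep <- colnames(X) != "constant"
  df <- as.data.frame(X[, keep, drop = FALSE])
  names(df) <- make.names(colnames(X)[keep], unique = TRUE)
  df$.y <- y
  df
}

#' Durbin-Wu-Hausman endogeneity test (control-function form)
#'
#' Tests whether the endogenous regressors of the outcome (DD) equation are
#' in fact exogenous. Each endogenous regressor is first regressed on the
#' full exogenous set (covariates plus instruments), the first-stage
#' residuals are appended to the outcome equation, the augmented equation is
#' fitted, and the residual coefficients are jointly tested by a
#' cluster-robust Wald test. Small p-values indicate endogeneity
#' (inconsistency of the uninstrumented fit).
#'
#' By default every first stage is a linear projection, whose in-sample
#' residual is exactly orthogonal to the exogenous set and therefore keeps
#' the test correctly sized even when a first-stage mean model is
#' misspecified (e.g. when an instrument such as the estimated
#' socioeconomic index carries measurement noise).
#' `first_stage = "exponential"` instead uses an exponential-mean
#' (Poisson-type) fit with response residuals for the on-farm-diversity
#' count, matching that equation's structural link; simulation shows this
#' variant over-rejects under generated-regressor noise, so it is not the
#' default.
#'
#' @param design A `triad_design` from [build_design()].
#' @param first_stage `"linear"` (default) or `"exponential"`.
#' @return List with `stat` (chi-square), `dof`, `p`.
#' @export
durbin_wu_hausman <- function(design,
                              first_stage = c("linear", "exponential")) {
  first_stage <- match.arg(first_stage)
  stopifnot(inherits(design, "triad_design"))
  parts <- dd_equation_parts(design)
  eq <- parts$eq
  if (!length(parts$endog))
    stop("the outcome equation has no endogenous regressors", call. = FALSE)
  Z <- eq$Z
  cl <- design$cluster

  resid_cols <- sapply(parts$endog, function(nm) {
    v <- eq$W[, nm]
    if (first_stage == "exponential" && nm == "OFD") {
      fs <- suppressWarnings(stats::glm.fit(Z, v, family = stats::quasipoisson()))
      v - fs$fitted.values
    } else {
      v - stats::lm.fit(Z, v)$fitted.values
    }
  })
  colnames(resid_cols) <- paste0("cf_resid_", parts$endog)

  df <- glm_frame(eq$y, cbind(eq$W, resid_cols))
  fam <- if (eq$link == "exponential") stats::quasipoisson() else stats::gaussian()
  aug <- suppressWarnings(stats::glm(.y ~ ., family = fam, data = df))
  V <- sandwich::vcovCL(aug, cluster = cl)
  cf <- stats::coef(aug)
  idx <- match(make.names(colnames(resid_cols)), names(cf))
  if (anyNA(idx) || anyNA(cf[idx]))
    stop("first-stage residuals are collinear with the outcome equation",
         call. = FALSE)
  stat <- cluster_wald(cf, V, idx, "Durbin-Wu-Hausman")
  dof <- length(idx)
  list(stat = stat, dof = dof, p = stats::pchisq(stat, dof, lower.tail = FALSE))
}

#' Sargan-Hansen test of overidentifying restrictions
#'
#' Uses the J statistic from the step-2 GMM objective. Under valid
#' instruments J is asymptotically chi-square with degrees of freedom equal
#' to the number of overidentifying restrictions. Small p-values indicate
#' instrument inconsistency. For a just-identified system (zero
#' overidentification degrees) the p-value is not applicable and reported as
#' `NA`.
#'
#' @param fit A `triad_gmm` fit.
#' @return List with `J`, `dof`, `p` (`NA` when `dof == 0`).
#' @export
sargan_hansen <- function(fit) {
  stopifnot(inherits(fit, "triad_gmm"))
  dof <- fit$dof_overid
  if (dof < 0L) stop("negative overidentification degree", call. = FALSE)
  p <- if (dof == 0L) NA_real_ else stats::pchisq(fit$J, dof, lower.tail = FALSE)
  list(J = fit$J, dof = dof, p = p)
}

#' First-stage weak-instrument diagnostics
#'
#' For each endogenous regressor of the outcome equation, fits the linear
#' first stage on the exogenous covariates plus the excluded instruments and
#' reports a cluster-robust F statistic on the excluded instruments together
#' with the partial R-squared (share of the covariate-residualized variation
#' explained by the instruments). The common rule of thumb flags F below
#' about 10 as weak. The linear projection is used for the count regressor
#' as well, since the first-stage F statistic is defined for linear first
#' stages.
#'
#' @param design A `triad_design`.
#' @return Data frame with one row per endogenous regressor: `endogenous`,
#'   `F`, `df1`, `df2`, `p`, `partial_r2`.
#' @export
weak_instruments <- function(design) {
  stopifnot(inherits(design, "triad_design"))
  parts <- dd_equation_parts(design)
  eq <- parts$eq
  if (!length(parts$endog))
    stop("the outcome equation has no endogenous regressors", call. = FALSE)
  spec_dd <- design$spec$equations$dd
  excl <- spec_dd$instruments
  if (!length(excl))
    stop("the outcome equation has no excluded instruments", call. = FALSE)
  Z <- eq$Z
  x_cols <- setdiff(colnames(Z), excl)
  cl <- design$cluster
  n_cl <- length(unique(cl))

  rows <- lapply(parts$endog, function(nm) {
    v <- eq$W[, nm]
    df <- glm_frame(v, Z)
    fs <- stats::lm(.y ~ ., data = df)
    V <- sandwich::vcovCL(fs, cluster = cl)
    cf <- stats::coef(fs)
    idx <- match(make.names(excl), names(cf))
    if (anyNA(idx) || anyNA(cf[idx]))
      stop("excluded instruments are collinear in the first stage", call. = FALSE)
    q <- length(idx)
    wald <- cluster_wald(cf, V, idx, "weak-instrument test")
    Fstat <- wald / q
    df2 <- n_cl - 1L
    e_x <- stats::lm.fit(Z[, x_cols, drop = FALSE], v)$residuals
    e_xz <- fs$residuals
    partial_r2 <- 1 - sum(e_xz^2) / sum(e_x^2)
    data.frame(endogenous = nm, F = Fstat, df1 = q, df2 = df2,
               p = stats::pf(Fstat, q, df2, lower.tail = FALSE),
               partial_r2 = partial_r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full diagnostics battery
#'
#' @param design A `triad_design`.
#' @param fit The corresponding `triad_gmm` fit (for the Sargan-Hansen J).
#' @param dwh_first_stage Passed to [durbin_wu_hausman()].
#' @return Object of class `triad_diagnostics`: list with `dwh`, `sargan`,
#'   `first_stage`.
#' @export
diagnose <- function(design, fit, dwh_first_stage = "linear") {
  out <- list(dwh = durbin_wu_hausman(design, first_stage = dwh_first_stage),
              sargan = sargan_hansen(fit),
              first_stage = weak_instruments(design))
  class(out) <- "triad_diagnostics"
  out
}

#' @export
print.triad_diagnostics <- function(x, ...) {
  cat("Specification diagnostics\n")
  cat(sprintf("  Durbin-Wu-Hausman: chi2(%d) = %.3f, p = %.4g (small p: endogeneity)\n",
              x$dwh$dof, x$dwh$stat, x$dwh$p))
  if (is.na(x$sargan$p)) {
    cat(sprintf("  Sargan-Hansen: J = %.3g, just-identified (p not applicable)\n",
                x$sargan$J))
  } else {
    cat(sprintf("  Sargan-Hansen: J = %.3f, chi2(%d), p = %.4g (small p: invalid instruments)\n",
                x$sargan$J, x$sargan$dof, x$sargan$p))
  }
  cat("  First-stage F on excluded instruments:\n")
  for (i in seq_len(nrow(x$first_stage)))
    cat(sprintf("    %-12s F(%d, %d) = %.2f, p = %.4g, partial R2 = %.3f\n",
                x$first_stage$endogenous[i], x$first_stage$df1[i],
                x$first_stage$df2[i], x$first_stage$F[i],
                x$first_stage$p[i], x$first_stage$partial_r2[i]))
  invisible(x)
}
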