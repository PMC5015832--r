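# Two-step GMM for the simultaneous three-equation system with mixed
# exponential / linear mean functions, stacked instrument-orthogonality
# moment conditions and cluster-robust sandwich inference.
#
# The moment vector stacks, per equation, the per-observation products of the
# equation's residual with its instrument row (exogenous covariates plus
# excluded instruments). Each equation's moments depend only on its own
# parameters, so the Jacobian of the mean moment is block diagonal; the
# equations are tied together through the joint weighting matrix, which
# exploits cross-equation error correlation (the full-information property).

eq_param_names <- function(equations) {
  unlist(lapply(names(equations), function(nm)
    paste(nm, colnames(equations[[nm]]$W), sep = ".")), use.names = FALSE)
}

eq_offsets <- function(equations) {
  p <- vapply(equations, function(eq) ncol(eq$W), integer(1))
  end <- cumsum(p)
  data.frame(eq = names(equations), first = end - p + 1L, last = end)
}

split_params <- function(params, equations) {
  off <- eq_offsets(equations)
  out <- lapply(seq_len(nrow(off)), function(k)
    params[off$first[k]:off$last[k]])
  names(out) <- off$eq
  out
}

linear_index <- function(eq, b, clip = Inf) {
  eta <- unname(drop(eq$W %*% b))
  if (is.finite(clip)) eta <- pmin(pmax(eta, -clip), clip)
  eta
}

eq_mean <- function(eq, b, clip = Inf) {
  eta <- linear_index(eq, b, clip)
  if (eq$link == "exponential") exp(eta) else eta
}

#' Residuals of the three-equation system
#'
#' Computes the per-equation residuals at a given stacked parameter vector:
#' outcome minus the exponential of the linear index for the
#' exponential-link equations (DD, OFD) and outcome minus the linear index
#' for the linear equation (MD).
#'
#' @param params Stacked parameter vector ordered as the design's equations
#'   (use [fit_gmm_system()] coefficients, or any numeric vector of the right
#'   length).
#' @param design A `triad_design` from [build_design()], or any list with an
#'   `equations` element of the same shape.
#' @return Named list of residual vectors, one per equation.
#' @export
gmm_residuals <- function(params, design) {
  eqs <- design$equations
  bs <- split_params(params, eqs)
  out <- lapply(names(eqs), function(nm) {
    eq <- eqs[[nm]]
    eta <- linear_index(eq, bs[[nm]])
    if (eq$link == "exponential" && any(eta > 700)) {
      bad <- which(eta > 700)
      stop("linear index overflows exp() in equation '", nm, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "", call. = FALSE)
    }
    eq$y - (if (eq$link == "exponential") exp(eta) else eta)
  })
  names(out) <- names(eqs)
  out
}

#' Fitted mean outcomes of the three-equation system
#'
#' @inheritParams gmm_residuals
#' @return Named list of fitted-mean vectors (strictly positive for the
#'   exponential-link equations).
#' @export
fitted_means <- function(params, design) {
  eqs <- design$equations
  bs <- split_params(params, eqs)
  out <- lapply(names(eqs), function(nm) eq_mean(eqs[[nm]], bs[[nm]]))
  names(out) <- names(eqs)
  out
}

#' Per-observation moment conditions
#'
#' Stacks, per equation, residual times instrument row. The sample mean of
#' the returned matrix is the moment vector whose weighted norm the GMM
#' estimator minimizes.
#'
#' @inheritParams gmm_residuals
#' @return List with `g` (n x n_moments matrix) and `gbar` (its column
#'   means).
#' @export
gmm_moments <- function(params, design) {
  eqs <- design$equations
  res <- gmm_residuals(params, design)
  g <- do.call(cbind, lapply(names(eqs), function(nm) {
    m <- eqs[[nm]]$Z * res[[nm]]
    colnames(m) <- paste(nm, colnames(eqs[[nm]]$Z), sep = ".")
    m
  }))
  list(g = g, gbar = colMeans(g))
}

# --- internal machinery ------------------------------------------------------

# center and scale design columns for optimization (near-constant covariates
# otherwise make the moment system badly conditioned); slopes are recovered by
# dividing by the scale and the intercept absorbs the centering shift
scale_equations <- function(equations) {
  lapply(equations, function(eq) {
    # centering is an admissible reparametrization only when an explicit
    # constant column can absorb the shift (regressors) or carry the level
    # moment (instruments); without one, only rescale
    is_const <- apply(eq$W, 2, function(v) all(v == v[1L]) && v[1L] != 0)
    mW <- if (any(is_const)) colMeans(eq$W) else rep(0, ncol(eq$W))
    mW[is_const] <- 0
    eq$W <- sweep(eq$W, 2, mW, "-")
    sW <- sqrt(colMeans(eq$W^2)); sW[sW == 0] <- 1
    eq$W <- sweep(eq$W, 2, sW, "/")
    is_const_z <- apply(eq$Z, 2, function(v) all(v == v[1L]) && v[1L] != 0)
    mZ <- if (any(is_const_z)) colMeans(eq$Z) else rep(0, ncol(eq$Z))
    mZ[is_const_z] <- 0
    eq$Z <- sweep(eq$Z, 2, mZ, "-")
    sZ <- sqrt(colMeans(eq$Z^2)); sZ[sZ == 0] <- 1
    eq$Z <- sweep(eq$Z, 2, sZ, "/")
    eq$center_W <- mW
    eq$scale_W <- sW
    eq$const_col <- which(is_const)[1L]
    eq
  })
}

# linear map from scaled-basis coefficients to original-basis coefficients:
# slopes divide by their scale, the intercept absorbs the centering shift
unscale_transform <- function(scaled) {
  blocks <- lapply(scaled, function(eq) {
    k <- ncol(eq$W)
    Tm <- diag(1 / eq$scale_W, k)
    cc <- eq$const_col
    if (!is.na(cc)) {
      Tm[cc, ] <- -eq$center_W / eq$scale_W
      Tm[cc, cc] <- 1
    }
    Tm
  })
  m <- vapply(blocks, nrow, integer(1))
  Tfull <- matrix(0, sum(m), sum(m))
  at <- c(0L, cumsum(m))
  for (k in seq_along(blocks))
    Tfull[(at[k] + 1L):at[k + 1L], (at[k] + 1L):at[k + 1L]] <- blocks[[k]]
  Tfull
}

moments_raw <- function(equations, bs, clip = Inf) {
  do.call(cbind, lapply(names(equations), function(nm) {
    eq <- equations[[nm]]
    r <- eq$y - eq_mean(eq, bs[[nm]], clip)
    eq$Z * r
  }))
}

# block-diagonal Jacobian of the mean moment vector wrt the stacked params
moments_jacobian <- function(equations, bs, clip = Inf) {
  n <- length(equations[[1L]]$y)
  blocks <- lapply(names(equations), function(nm) {
    eq <- equations[[nm]]
    if (eq$link == "exponential") {
      mu <- eq_mean(eq, bs[[nm]], clip)
      -crossprod(eq$Z, eq$W * mu) / n
    } else {
      -crossprod(eq$Z, eq$W) / n
    }
  })
  m <- vapply(equations, function(eq) ncol(eq$Z), integer(1))
  p <- vapply(equations, function(eq) ncol(eq$W), integer(1))
  G <- matrix(0, sum(m), sum(p))
  mi <- c(0L, cumsum(m)); pi <- c(0L, cumsum(p))
  for (k in seq_along(blocks))
    G[(mi[k] + 1L):mi[k + 1L], (pi[k] + 1L):pi[k + 1L]] <- blocks[[k]]
  G
}

cluster_meat <- function(g, cluster) {
  gc <- rowsum(g, group = cluster, reorder = FALSE)
  crossprod(gc) / nrow(g)
}

safe_inverse <- function(S, what = "weighting matrix") {
  out <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(out)) {
    warning(sprintf("singular %s; applying ridge regularization", what))
    ridge <- 1e-8 * mean(diag(S))
    out <- chol2inv(chol(S + diag(ridge, nrow(S))))
  }
  out
}

# Gauss-Newton minimization of gbar' Wt gbar with step halving
gn_minimize <- function(equations, theta0, Wt, clip, tol, max_iter) {
  n <- length(equations[[1L]]$y)
  L <- chol(Wt)
  obj <- function(bs) {
    gbar <- colMeans(moments_raw(equations, bs, clip))
    sum((L %*% gbar)^2)
  }
  theta <- theta0
  bs <- split_params(theta, equations)
  q <- obj(bs)
  converged <- FALSE
  iter <- 0L
  grad_norm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    gbar <- colMeans(moments_raw(equations, bs, clip))
    G <- moments_jacobian(equations, bs, clip)
    grad <- 2 * crossprod(G, Wt %*% gbar)
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < tol) { converged <- TRUE; break }
    LG <- L %*% G
    d <- tryCatch(-qr.solve(crossprod(LG), crossprod(LG, L %*% gbar)),
                  error = function(e) -0.5 * grad)
    step <- 1
    repeat {
      theta_new <- theta + step * drop(d)
      bs_new <- split_params(theta_new, equations)
      q_new <- obj(bs_new)
      if (is.finite(q_new) &&
          q_new <= q + 1e-4 * step * sum(grad * d)) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) {
      # no descent step found: at numerical optimum
      converged <- grad_norm < sqrt(tol)
      break
    }
    theta <- theta + step * drop(d)
    bs <- split_params(theta, equations)
    q <- q_new
  }
  list(theta = theta, objective = q, converged = converged,
       iterations = iter, grad_norm = grad_norm)
}

default_start <- function(equations) {
  unlist(lapply(equations, function(eq) {
    if (eq$link == "linear") {
      stats::lm.fit(eq$W, eq$y)$coefficients
    } else {
      # Poisson-style IRLS start, ignoring endogeneity
      fit <- suppressWarnings(
        stats::glm.fit(eq$W, eq$y, family = stats::quasipoisson()))
      fit$coefficients
    }
  }), use.names = FALSE)
}

#' Estimate a system of moment-condition equations by two-step GMM
#'
#' Generic core estimator: takes a list of equations (each with outcome `y`,
#' regressor matrix `W`, instrument matrix `Z` and `link` either
#' `"exponential"` or `"linear"`) and minimizes the weighted norm of the
#' stacked instrument-orthogonality moment conditions by Gauss-Newton with
#' an analytic moment Jacobian. Step 1 uses the identity weight from
#' equation-by-equation starting values (least squares for linear links,
#' Poisson-style iteratively reweighted fits for exponential links); step 2
#' re-minimizes with the inverse of the cluster-aggregated moment covariance
#' evaluated at the step-1 estimates. With `weighting = "iterated"` the
#' weight update is repeated until the estimates stabilize.
#'
#' @param equations Named list of equations as above.
#' @param cluster Cluster id vector (sandwich covariance aggregates moment
#'   contributions within clusters); `NULL` treats every row as its own
#'   cluster (heteroskedasticity-robust).
#' @param weighting `"two_step"` (default) or `"iterated"`.
#' @param start Optional stacked starting vector.
#' @param control List: `tol` (gradient-norm convergence threshold, default
#'   1e-8), `max_iter` (default 500), `clip` (overflow guard on the linear
#'   index inside exp during optimization, default 30).
#' @return Object of class `triad_gmm`.
#' @export
fit_gmm_equations <- function(equations, cluster = NULL,
                              weighting = c("two_step", "iterated"),
                              start = NULL, control = list()) {
  weighting <- match.arg(weighting)
  ctl <- utils::modifyList(list(tol = 1e-8, max_iter = 500L, clip = 30), control)
  n <- length(equations[[1L]]$y)
  stopifnot(all(vapply(equations, function(eq)
    length(eq$y) == n && nrow(eq$W) == n && nrow(eq$Z) == n, logical(1))))
  if (is.null(cluster)) cluster <- seq_len(n)
  if (is.null(names(equations)))
    names(equations) <- paste0("eq", seq_along(equations))

  for (nm in names(equations)) {
    Z <- equations[[nm]]$Z
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      kappa_z <- kappa(Z)
      warning(sprintf(
        "instrument matrix of equation '%s' is rank deficient (condition number %.3g)",
        nm, kappa_z))
    }
  }

  scaled <- scale_equations(equations)
  p <- sum(vapply(scaled, function(eq) ncol(eq$W), integer(1)))
  m <- sum(vapply(scaled, function(eq) ncol(eq$Z), integer(1)))
  n_clusters <- length(unique(cluster))
  if (n_clusters < p)
    warning("fewer clusters than parameters; cluster-robust inference is fragile")

  Tfull <- unscale_transform(scaled)
  theta0 <- if (is.null(start)) default_start(scaled)
            else drop(solve(Tfull, start))

  # step 1: two-stage-least-squares-type weight, block diagonal over
  # equations; unlike the identity it makes the first step (and therefore the
  # whole two-step estimator) invariant to re-combinations of the instruments
  W1 <- matrix(0, m, m)
  at <- c(0L, cumsum(vapply(scaled, function(eq) ncol(eq$Z), integer(1))))
  for (k in seq_along(scaled)) {
    idx <- (at[k] + 1L):at[k + 1L]
    W1[idx, idx] <- safe_inverse(crossprod(scaled[[k]]$Z) / n,
                                 "step-1 instrument moment matrix")
  }
  s1 <- gn_minimize(scaled, theta0, W1, ctl$clip, ctl$tol, ctl$max_iter)
  theta <- s1$theta
  iterations <- s1$iterations
  converged <- s1$converged

  # step 2 (repeated under iterated weighting): efficient weight from the
  # cluster-aggregated outer product of moments
  max_weight_updates <- if (weighting == "two_step") 1L else 20L
  Wt <- NULL
  for (it in seq_len(max_weight_updates)) {
    g <- moments_raw(scaled, split_params(theta, scaled), ctl$clip)
    S <- cluster_meat(g, cluster)
    Wt <- safe_inverse(S, "moment covariance")
    sk <- gn_minimize(scaled, theta, Wt, ctl$clip, ctl$tol, ctl$max_iter)
    iterations <- iterations + sk$iterations
    converged <- sk$converged
    delta <- max(abs(sk$theta - theta))
    theta <- sk$theta
    if (weighting == "iterated" && delta < 1e-7) break
  }

  bs <- split_params(theta, scaled)
  # overflow-guard flag: a solution pinned at the clip boundary is not trusted
  on_clip <- any(vapply(names(scaled), function(nm) {
    eq <- scaled[[nm]]
    eq$link == "exponential" && any(abs(drop(eq$W %*% bs[[nm]])) >= ctl$clip)
  }, logical(1)))
  if (on_clip) {
    warning("linear index hit the overflow clip at the solution; flagged non-converged")
    converged <- FALSE
  }

  gbar <- colMeans(moments_raw(scaled, bs, ctl$clip))
  G <- moments_jacobian(scaled, bs, ctl$clip)
  J <- n * drop(crossprod(gbar, Wt %*% gbar))
  S_hat <- cluster_meat(moments_raw(scaled, bs, ctl$clip), cluster)
  A <- crossprod(G, Wt %*% G)
  A_inv <- safe_inverse(A, "GMM bread")
  B <- crossprod(G, Wt %*% S_hat %*% Wt %*% G)
  V_scaled <- A_inv %*% B %*% A_inv / n

  # back-transform to original column units
  coefs <- drop(Tfull %*% theta)
  V <- Tfull %*% V_scaled %*% t(Tfull)
  nms <- eq_param_names(equations)
  names(coefs) <- nms
  dimnames(V) <- list(nms, nms)
  se <- sqrt(pmax(diag(V), 0))
  zval <- coefs / se
  pval <- 2 * stats::pnorm(-abs(zval))

  structure(list(
    coefficients = coefs, vcov = V, se = se, z = zval, p = pval,
    J = J, dof_overid = m - p, n_moments = m, n_obs = n,
    n_clusters = n_clusters, converged = converged, iterations = iterations,
    weighting = weighting, equations = names(equations),
    equation_info = lapply(equations, function(eq)
      list(outcome = eq$outcome, link = eq$link, k = ncol(eq$W))),
    offsets = eq_offsets(equations)
  ), class = "triad_gmm")
}

#' Estimate the three-equation diversity system
#'
#' Convenience wrapper applying [fit_gmm_equations()] to a `triad_design`
#' built by [build_design()], clustering at the level named in the model
#' spec (household by default).
#'
#' @param design A `triad_design`.
#' @param weighting,start,control Passed to [fit_gmm_equations()].
#' @return Object of class `triad_gmm`.
#' @export
fit_gmm_system <- function(design, weighting = c("two_step", "iterated"),
                           start = NULL, control = list()) {
  stopifnot(inherits(design, "triad_design"))
  fit <- fit_gmm_equations(design$equations, cluster = design$cluster,
                           weighting = match.arg(weighting),
                           start = start, control = control)
  fit$spec <- design$spec
  fit$n_dropped <- design$n_dropped
  fit
}

#' @export
coef.triad_gmm <- function(object, ...) object$coefficients

#' @export
vcov.triad_gmm <- function(object, ...) object$vcov

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Coefficient table in three-outcome layout
#'
#' Arranges the stacked system estimates as one row per variable and one
#' column pair (estimate, stars) per outcome equation, with significance
#' stars at the 0.05 / 0.01 / 0.001 levels from two-tailed normal p-values.
#'
#' @param fit A `triad_gmm` fit.
#' @param digits Rounding for display columns (default no rounding).
#' @return Data frame.
#' @export
coef_table <- function(fit, digits = NULL) {
  stopifnot(inherits(fit, "triad_gmm"))
  off <- fit$offsets
  vars <- unique(unlist(lapply(seq_len(nrow(off)), function(k)
    sub(paste0("^", off$eq[k], "\\."), "",
        names(fit$coefficients)[off$first[k]:off$last[k]]))))
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(off))) {
    nm <- off$eq[k]
    idx <- off$first[k]:off$last[k]
    v <- sub(paste0("^", nm, "\\."), "", names(fit$coefficients)[idx])
    est <- fit$coefficients[idx][match(vars, v)]
    if (!is.null(digits)) est <- round(est, digits)
    out[[paste0(nm, "_estimate")]] <- est
    out[[paste0(nm, "_stars")]] <-
      ifelse(is.na(est), "", significance_stars(fit$p[idx][match(vars, v)]))
  }
  out
}

#' @export
print.triad_gmm <- function(x, ...) {
  cat(sprintf("System GMM fit (%s weighting): %d obs, %d clusters\n",
              x$weighting, x$n_obs, x$n_clusters))
  cat(sprintf("  %d parameters, %d moments (overidentification dof %d)\n",
              length(x$coefficients), x$n_moments, x$dof_overid))
  cat(sprintf("  J = %.4f, converged: %s (%d iterations)\n",
              x$J, x$converged, x$iterations))
  invisible(x)
}

#' @export
summary.triad_gmm <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    z = object$z, p = object$p,
                    stars = significance_stars(object$p))
  structure(list(fit = object, table = tab), class = "summary.triad_gmm")
}

#' @export
print.summary.triad_gmm <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(as.matrix(x$table[c("estimate", "se", "z", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Serialize estimation results
#'
#' Writes the three-outcome coefficient table as CSV and the full results
#' (coefficients, covariance, J statistic, convergence metadata) as JSON.
#'
#' @param fit A `triad_gmm` fit.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_gmm_results <- function(fit, dir) {
  stopifnot(inherits(fit, "triad_gmm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(coef_table(fit), file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se), p = as.list(fit$p),
    vcov = fit$vcov, J = fit$J, dof_overid = fit$dof_overid,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    n_moments = fit$n_moments, converged = fit$converged,
    iterations = fit$iterations, weighting = fit$weighting
  ), file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
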