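# Design builder: merges the household table with the indicator table,
# expands categoricals to dummies and builds quadratics, applies listwise
# deletion, and realizes per-equation outcome vectors, regressor matrices and
# instrument matrices.

ag_importance_levels <- c("very_important", "important", "minor", "not_important")

# Derived columns available to model specs, computed from the raw merged frame
derive_design_columns <- function(df) {
  bad_shed <- setdiff(unique(stats::na.omit(df$market_shed)),
                      c("urban", "semi_urban", "rural"))
  if (length(bad_shed))
    stop("unknown market_shed value(s): ", paste(bad_shed, collapse = ", "),
         call. = FALSE)
  for (col in c("father_ag_importance", "mother_ag_importance")) {
    bad <- setdiff(unique(stats::na.omit(df[[col]])), ag_importance_levels)
    if (length(bad))
      stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  # rural market-shed is the omitted reference level; the two low agriculture
  # -importance ratings pool into the reference category
  df$urban_shed     <- as.numeric(df$market_shed == "urban")
  df$semiurban_shed <- as.numeric(df$market_shed == "semi_urban")
  df$rural_shed     <- as.numeric(df$market_shed == "rural")
  df$travel_time_sq <- df$travel_time^2
  df$landholdings_sq <- df$landholdings^2
  df$season_dry     <- as.numeric(df$season == "dry")
  df$father_ag_very_important <- as.numeric(df$father_ag_importance == "very_important")
  df$father_ag_important      <- as.numeric(df$father_ag_importance == "important")
  df$mother_ag_very_important <- as.numeric(df$mother_ag_importance == "very_important")
  df$mother_ag_important      <- as.numeric(df$mother_ag_importance == "important")
  df$OFD_x_rural <- df$OFD * df$rural_shed
  for (zc in default_z_terms)
    df[[paste0(zc, "_x_rural")]] <- df[[zc]] * df$rural_shed
  df
}

#' Build per-equation design data from household and indicator tables
#'
#' Merges the household table with the indicator table on household, mother
#' and season; expands the market-shed and agriculture-importance categoricals
#' to dummies (rural shed and the pooled minor/not-important ratings are the
#' reference levels; the season dummy is 1 in the dry season); builds squared
#' travel-time and landholdings terms; drops rows with any missing value among
#' the used columns (listwise across all three equations, so every equation
#' shares one row set); and realizes, for each equation, the outcome vector
#' `y`, the regressor matrix `W` (exogenous covariates plus, for DD, the
#' endogenous columns) and the instrument matrix `Z` (exogenous covariates
#' plus excluded instruments).
#'
#' @param household Household table (one row per household-season).
#' @param indicators Indicator table from [compute_indicators()], or any data
#'   frame with `mother_id`, `household_id`, `season`, `WDD`, `MDDW`, `MD`,
#'   `OFD`, `SES`.
#' @param spec A [model_spec()].
#' @return An object of class `triad_design`: list with `equations` (each
#'   with `y`, `W`, `Z`, `link`, `outcome`), `cluster`, `index`, `n_dropped`,
#'   `spec`.
#' @export
build_design <- function(household, indicators, spec = model_spec()) {
  stopifnot(is.data.frame(household), is.data.frame(indicators),
            inherits(spec, "triad_model_spec"))
  df <- merge(household, indicators,
              by = c("household_id", "mother_id", "season"), sort = FALSE)
  if (!nrow(df))
    stop("household and indicator tables share no mother-season rows",
         call. = FALSE)
  df <- derive_design_columns(df)

  used <- unique(unlist(lapply(spec$equations, function(eq)
    c(eq$outcome, eq$x, eq$endogenous, eq$instruments))))
  used <- c(used, spec$cluster)
  unresolved <- setdiff(used, names(df))
  if (length(unresolved))
    stop("model spec names unresolved column(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)

  complete <- stats::complete.cases(df[used])
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (!nrow(df))
    stop("all rows dropped by listwise deletion; design is empty", call. = FALSE)

  mat <- function(cols, data) {
    m <- cbind(constant = 1, as.matrix(data[cols]))
    storage.mode(m) <- "double"
    m
  }
  equations <- lapply(spec$equations, function(eq) {
    # equations without endogenous regressors take the instruments as
    # regressors too (just-identified); the outcome equation excludes them
    reg_cols <- if (length(eq$endogenous)) c(eq$x, eq$endogenous)
                else c(eq$x, eq$instruments)
    W <- mat(reg_cols, df)
    Z <- mat(c(eq$x, eq$instruments), df)
    dum <- intersect(c("urban_shed", "semiurban_shed", "season_dry",
                       "father_ag_very_important", "father_ag_important",
                       "mother_ag_very_important", "mother_ag_important"),
                     colnames(W))
    if (length(dum) && !all(W[, dum] %in% c(0, 1)))
      stop("dummy columns must be 0/1", call. = FALSE)
    list(y = as.numeric(df[[eq$outcome]]), W = W, Z = Z,
         link = eq$link, outcome = eq$outcome,
         n_endogenous = length(eq$endogenous))
  })
  structure(list(
    equations = equations,
    cluster = df[[spec$cluster]],
    index = df[c("mother_id", "household_id", "village_id", "season")],
    n_dropped = n_dropped,
    spec = spec
  ), class = "triad_design")
}

#' @export
print.triad_design <- function(x, ...) {
  n <- length(x$equations[[1L]]$y)
  cat(sprintf("Design data: %d rows (%d dropped), %d clusters\n",
              n, x$n_dropped, length(unique(x$cluster))))
  for (nm in names(x$equations)) {
    eq <- x$equations[[nm]]
    cat(sprintf("  %-3s (%s, %s link): %d regressors, %d instruments\n",
                toupper(nm), eq$outcome, eq$link, ncol(eq$W), ncol(eq$Z)))
  }
  invisible(x)
}
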