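# Symbolic description of the three-equation system: which columns enter each
# equation as regressors, which are endogenous, which serve as instruments,
# which link each equation uses, and the clustering variable.

default_x_terms <- c(
  "urban_shed", "semiurban_shed", "travel_time", "travel_time_sq",
  "father_nonag_sources", "father_ag_very_important", "father_ag_important",
  "mother_nonag_sources", "mother_ag_very_important", "mother_ag_important",
  "mother_age", "mother_education", "mother_ethnicity", "family_size",
  "temp_range", "precip_cv", "precip_range", "season_dry")

default_z_terms <- c("landholdings", "landholdings_sq", "SES")

#' Build a model specification for the three-equation diversity system
#'
#' The system regresses dietary diversity (DD, exponential mean) on the
#' exogenous covariates plus the two endogenous diversity measures (on-farm
#' diversity OFD and market diversity MD), while MD (linear mean) and OFD
#' (exponential mean) are regressed on the same covariates plus the
#' instruments (landholdings, its square, and the socioeconomic index).
#' The instruments are excluded from the DD equation's regressors, which is
#' what identifies the effects of OFD and MD on DD.
#'
#' @param variant `"baseline"` for the default system; `"interaction"` adds
#'   an OFD-by-rural-market-shed interaction to the DD equation (instrumented
#'   by the rural interactions of the excluded instruments);
#'   `"mddw_outcome"` replaces the DD count outcome with the binary MDD-W
#'   indicator, fitted with the same exponential-mean moment structure.
#' @param cluster Clustering variable for the sandwich covariance:
#'   `"household_id"` (default) or `"village_id"`.
#' @param x Character vector of exogenous covariate names (post-expansion
#'   column names of the design frame); default mirrors the full household
#'   covariate set.
#' @param z Character vector of instrument names.
#' @return An object of class `triad_model_spec`.
#' @export
model_spec <- function(variant = c("baseline", "interaction", "mddw_outcome"),
                       cluster = c("household_id", "village_id"),
                       x = default_x_terms,
                       z = default_z_terms) {
  variant <- match.arg(variant)
  cluster <- match.arg(cluster)
  if (!length(z))
    stop("at least one instrument is required", call. = FALSE)
  dd_outcome <- if (variant == "mddw_outcome") "MDDW" else "WDD"
  dd_endog <- c("OFD", "MD")
  dd_z <- z
  if (variant == "interaction") {
    dd_endog <- c(dd_endog, "OFD_x_rural")
    dd_z <- c(dd_z, paste0(z, "_x_rural"))
  }
  spec <- list(
    equations = list(
      dd  = list(outcome = dd_outcome, link = "exponential", x = x,
                 endogenous = dd_endog, instruments = dd_z),
      md  = list(outcome = "MD", link = "linear", x = x,
                 endogenous = character(), instruments = z),
      ofd = list(outcome = "OFD", link = "exponential", x = x,
                 endogenous = character(), instruments = z)
    ),
    cluster = cluster,
    variant = variant
  )
  class(spec) <- "triad_model_spec"
  spec
}

#' @export
print.triad_model_spec <- function(x, ...) {
  cat(sprintf("Three-equation diversity system spec (variant: %s)\n", x$variant))
  for (nm in names(x$equations)) {
    eq <- x$equations[[nm]]
    cat(sprintf("  %-3s: %s ~ %s link, %d covariates, %d endogenous, %d instruments\n",
                toupper(nm), eq$outcome, eq$link, length(eq$x),
                length(eq$endogenous), length(eq$instruments)))
  }
  cat(sprintf("  cluster: %s\n", x$cluster))
  invisible(x)
}

#' Read / write a model specification as YAML
#'
#' @param path File path.
#' @return `read_model_spec` returns a `triad_model_spec`;
#'   `write_model_spec` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("equations", "cluster", "variant")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("model spec file lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in c("dd", "md", "ofd")) {
    eq <- raw$equations[[nm]]
    if (is.null(eq))
      stop("model spec file lacks equation: ", nm, call. = FALSE)
    raw$equations[[nm]]$x <- as.character(eq$x)
    raw$equations[[nm]]$endogenous <- as.character(eq$endogenous)
    raw$equations[[nm]]$instruments <- as.character(eq$instruments)
  }
  class(raw) <- "triad_model_spec"
  raw
}

#' @rdname read_model_spec
#' @param spec A `triad_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "triad_model_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
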