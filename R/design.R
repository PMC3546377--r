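#' Specify the mean model of a multivariate meta-analysis or meta-regression
#'
#' Each outcome always receives its own intercept. Study-level covariates
#' may additionally enter any subset of the outcome equations, giving one
#' regression coefficient per (outcome, covariate) pair. With no covariate
#' terms this is the plain meta-analysis mean model (one pooled mean per
#' outcome).
#'
#' @param space An [outcome_space()].
#' @param terms Named list mapping outcome names to character vectors of
#'   covariate names entering that outcome's equation. Empty (default) for
#'   plain meta-analysis.
#' @param covariates Data frame of per-study covariate values; must contain
#'   a `study` column. Required when `terms` is non-empty.
#' @return An object of class `"design_spec"` with fields `space`, `terms`,
#'   `covariates`, `q` (total coefficient count) and `coef_names`.
#' @examples
#' sp <- outcome_space(c("y1", "y2"))
#' design_spec(sp)  # intercept-only
#' @export
design_spec <- function(space, terms = list(), covariates = NULL) {
  if (!inherits(space, "outcome_space")) stop("'space' must be an outcome_space")
  if (length(terms)) {
    if (is.null(names(terms)) || !all(names(terms) %in% space$names))
      stop("names of 'terms' must be outcome names")
    if (is.null(covariates) || !("study" %in% names(covariates)))
      stop("'covariates' data frame with a 'study' column is required")
    covariates$study <- as.character(covariates$study)
    for (cv in unique(unlist(terms)))
      if (!cv %in% names(covariates))
        stop("covariate '", cv, "' not found in the covariates table")
  }
  coef_names <- character(0)
  for (nm in space$names) {
    coef_names <- c(coef_names, nm)
    for (cv in terms[[nm]]) coef_names <- c(coef_names, paste0(nm, ":", cv))
  }
  structure(list(space = space, terms = terms, covariates = covariates,
                 q = length(coef_names), coef_names = coef_names),
            class = "design_spec")
}

#' Build the per-study design blocks
#'
#' Expands a [design_spec()] into one k_i x q design matrix per study, one
#' row per observed outcome component. With an intercept-only spec the
#' blocks are the outcome selection matrices, so the plain meta-analysis is
#' recovered exactly.
#'
#' @param d An `mv_dataset`.
#' @param spec A [design_spec()] for the same outcome space.
#' @return List of design matrices, one per study, with column names
#'   `spec$coef_names`.
#' @export
build_design <- function(d, spec) {
  if (!identical(d$space$names, spec$space$names))
    stop("design_spec and dataset use different outcome spaces")
  q <- spec$q
  cov_row <- function(study_id, cv) {
    i <- match(study_id, spec$covariates$study)
    if (is.na(i) || is.na(spec$covariates[[cv]][i]))
      stop("missing value of covariate '", cv, "' for study '", study_id, "'")
    spec$covariates[[cv]][i]
  }
  lapply(d$studies, function(s) {
    X <- matrix(0, length(s$observed), q,
                dimnames = list(NULL, spec$coef_names))
    for (r in seq_along(s$observed)) {
      nm <- d$space$names[s$observed[r]]
      X[r, nm] <- 1
      for (cv in spec$terms[[nm]])
        X[r, paste0(nm, ":", cv)] <- cov_row(s$study_id, cv)
    }
    X
  })
}
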