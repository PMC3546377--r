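#' Multivariate meta-regression with heterogeneity report
#'
#' Fits the random-effects (REML or ML) and fixed-effects models under a
#' mean model with study-level covariates ([design_spec()]), and computes
#' the heterogeneity report for the full coefficient vector. All statistics
#' treat intercepts and covariate effects alike: `v = N_obs - q` counts all
#' coefficients, `H2`/`I2_H` are reported for the full set only, and
#' `R`/`I2_R` are available for any coefficient subset or contrast (for
#' example, all coefficients belonging to one outcome).
#'
#' @param d An `mv_dataset`.
#' @param spec A [design_spec()] for `d`'s outcome space.
#' @param opts [fit_options()]; `method` selects REML (default) or ML.
#' @param sels Optional extra selections passed to
#'   [heterogeneity_report()].
#' @return List with elements `fit` (the random-effects `"mvmeta_fit"`),
#'   `fixed` (the fixed-effects fit) and `report` (the `"het_report"`).
#' @export
metareg_fit_and_report <- function(d, spec, opts = fit_options("reml"),
                                   sels = NULL) {
  if (d$N_obs - spec$q < 1L)
    stop("model saturates the data: v = N_obs - q = ",
         d$N_obs - spec$q, " < 1")
  fit <- switch(opts$method,
                reml = reml_fit(d, spec, opts),
                ml = ml_fit(d, spec, opts),
                stop("opts$method must be 'reml' or 'ml'"))
  fe <- fixed_effects_fit(d, spec)
  rep_ <- heterogeneity_report(d, fit, fe, sels = sels, design = spec,
                               per_outcome = length(spec$terms) == 0L)
  list(fit = fit, fixed = fe, report = rep_)
}
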