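#' Select a subset of coefficients for a heterogeneity statistic
#'
#' @param indices Integer indices of the coefficients (for a plain
#'   meta-analysis, the outcomes) the statistic should apply to.
#' @param label Optional display label.
#' @return A `"het_selection"` of kind `"subset"`.
#' @export
subset_selection <- function(indices, label = NULL) {
  indices <- as.integer(indices)
  if (length(indices) < 1L || anyDuplicated(indices) || any(indices < 1L))
    stop("indices must be a non-empty set of positive integers")
  structure(list(kind = "subset", indices = indices, A = NULL,
                 p_eff = length(indices),
                 label = label %||% paste0("{", paste(indices, collapse = ","), "}")),
            class = "het_selection")
}

#' Select linear combinations of coefficients for a heterogeneity statistic
#'
#' Heterogeneity can be quantified for any contrasts `A %*% beta` (for
#' example a difference of two outcomes): the covariance matrices of the
#' contrast estimates under random and fixed effects are `A C A'`.
#'
#' @param A A k x q matrix of full row rank.
#' @param label Optional display label.
#' @return A `"het_selection"` of kind `"contrast"`.
#' @export
contrast_selection <- function(A, label = NULL) {
  A <- as.matrix(A)
  if (qr(A)$rank < nrow(A)) stop("contrast matrix must have full row rank")
  structure(list(kind = "contrast", indices = NULL, A = A, p_eff = nrow(A),
                 label = label %||% paste0("contrast[", nrow(A), "x", ncol(A), "]")),
            class = "het_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.select_cov <- function(C, sel) {
  if (is.null(sel)) return(C)
  if (sel$kind == "subset") {
    if (any(sel$indices > nrow(C))) stop("selection index out of range")
    C[sel$indices, sel$indices, drop = FALSE]
  } else {
    if (ncol(sel$A) != nrow(C)) stop("contrast matrix has wrong column count")
    sel$A %*% C %*% t(sel$A)
  }
}

.logdet <- function(M, what = "matrix") {
  R <- tryCatch(chol(M), error = function(e)
    stop("selected ", what, " is singular", call. = FALSE))
  2 * sum(log(diag(R)))
}

#' Generalised-variance ratio statistic R
#'
#' The ratio of the volumes of the confidence ellipsoids for the selected
#' coefficients under the random- and fixed-effects models, raised to the
#' power `1/p`:
#' `R = (det(D_R) / det(D_F))^(1/(2p))`,
#' where `D_R`, `D_F` are the selected p x p blocks (or contrast
#' transforms) of the random- and fixed-effects coefficient covariance
#' matrices. For `p = 1` this is the ratio of the two standard errors, the
#' square root of the classical univariate R-squared. Determinants are
#' computed through triangular factorisation of each submatrix for
#' stability near singularity.
#'
#' @param C_R Coefficient covariance from the random-effects fit.
#' @param C_F Coefficient covariance from the fixed-effects fit.
#' @param sel A [subset_selection()] or [contrast_selection()], or `NULL`
#'   for all coefficients.
#' @return Scalar R > 0.
#' @examples
#' multivariate_R(diag(c(4, 9)), diag(2))  # (36)^(1/4) = sqrt(6)
#' @export
multivariate_R <- function(C_R, C_F, sel = NULL) {
  D_R <- .select_cov(as.matrix(C_R), sel)
  D_F <- .select_cov(as.matrix(C_F), sel)
  p <- nrow(D_R)
  exp((.logdet(D_R, "random-effects block") -
         .logdet(D_F, "fixed-effects block")) / (2 * p))
}

#' I-squared derived from the R statistic
#'
#' `I2_R = (R^2 - 1) / R^2`, truncated at zero: the proportion of the
#' (geometric-mean) variance of the pooled estimates under the random
#' effects model that is attributable to between-study heterogeneity.
#'
#' @param R Scalar R statistic (> 0).
#' @return Value in `[0, 1)`.
#' @export
i2_from_R <- function(R) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  max(0, (R^2 - 1) / R^2)
}

#' Scalar multivariate heterogeneity statistic Q_s
#'
#' The weighted sum of squared fixed-effects residuals
#' `Q_s = sum_i (y_i - X_i beta_F)' S_i^-1 (y_i - X_i beta_F)`,
#' a chi-squared test statistic for the null hypothesis of no between-study
#' heterogeneity, with degrees of freedom `v = N_obs - q` (total univariate
#' estimates minus coefficients). With missing outcomes, each study
#' contributes only its observed block. Reduces to Cochran's Q univariately.
#'
#' @param d An `mv_dataset`.
#' @param design The [design_spec()] used for the fixed-effects fit;
#'   intercept-only by default.
#' @param fe The fixed-effects `"mvmeta_fit"` on the same data and design.
#' @return List with elements `Q_s` and `v`.
#' @export
q_s <- function(d, design = NULL, fe = NULL) {
  if (is.null(design)) design <- design_spec(d$space)
  if (is.null(fe)) fe <- fixed_effects_fit(d, design)
  if (fe$method != "fixed") stop("fe must be a fixed-effects fit")
  if (!identical(names(fe$beta), design$coef_names))
    stop("fit and design disagree on the coefficient layout")
  Xlist <- build_design(d, design)
  Qs <- 0
  for (i in seq_along(d$studies)) {
    r <- d$studies[[i]]$y - drop(Xlist[[i]] %*% fe$beta)
    Qs <- Qs + drop(crossprod(r, solve(d$studies[[i]]$S, r)))
  }
  v <- d$N_obs - design$q
  if (v < 1L) stop("model saturates the data: no residual degrees of freedom")
  list(Q_s = Qs, v = as.integer(v))
}

#' Multivariate H-squared and its I-squared
#'
#' `H2 = Q_s / v`, the relative excess of the heterogeneity statistic over
#' its degrees of freedom (1 in expectation under homogeneity), and
#' `I2_H = max(0, (H2 - 1)/H2)`.
#'
#' @param Q_s Scalar heterogeneity statistic (>= 0).
#' @param v Its degrees of freedom (>= 1).
#' @return List with `H2` and `I2_H`.
#' @export
h2_stats <- function(Q_s, v) {
  if (v < 1) stop("v must be >= 1 (model saturates the data)")
  if (Q_s < 0) stop("Q_s must be non-negative")
  H2 <- Q_s / v
  list(H2 = H2, I2_H = max(0, (H2 - 1) / H2))
}

#' Typical within-study variance
#'
#' The Higgins-Thompson summary of within-study precision,
#' `s2 = (n - 1) sum(w) / ((sum w)^2 - sum(w^2))` with `w = 1/var`. Equals
#' the common variance when all studies have it.
#'
#' @param var Positive within-study variances (length >= 2).
#' @return Scalar s2.
#' @export
typical_within_variance <- function(var) {
  if (length(var) < 2L) stop("need at least 2 variances")
  if (any(var <= 0)) stop("all variances must be positive")
  w <- 1 / var
  (length(var) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Classical univariate heterogeneity statistics
#'
#' Cochran's Q, `H2 = Q/(n-1)`, the Q-based `I2 = max(0, (H2-1)/H2)`, the
#' variance-based `I2 = tau2/(tau2 + s2)` with s2 the typical within-study
#' variance, and the univariate R (ratio of random- to fixed-effects
#' standard errors of the pooled mean, using the supplied `tau2`).
#'
#' @param y Study estimates.
#' @param var Their within-study variances.
#' @param tau2 Between-study variance to use for `I2_tau` and `R_u`
#'   (REML or DerSimonian-Laird, at the caller's choice; >= 0).
#' @return List with `Q`, `H2_u`, `I2_Q`, `I2_tau`, `R_u`, `s2`,
#'   `tau2_dl`, `mu_fixed`.
#' @export
univariate_stats <- function(y, var, tau2) {
  if (tau2 < 0) stop("tau2 must be >= 0")
  dl <- dl_univariate(y, var)
  n <- length(y)
  H2_u <- dl$Q / (n - 1)
  s2 <- typical_within_variance(var)
  v_F <- 1 / sum(1 / var)
  v_R <- 1 / sum(1 / (var + tau2))
  list(Q = dl$Q, H2_u = H2_u, I2_Q = max(0, (H2_u - 1) / H2_u),
       I2_tau = tau2 / (tau2 + s2), R_u = sqrt(v_R / v_F), s2 = s2,
       tau2_dl = dl$tau2_dl, mu_fixed = dl$mu_fixed)
}

#' Per-outcome I-squared from the marginal between-study variances
#'
#' For each outcome j, `I2_j = Sigma_jj / (Sigma_jj + s2_j)`, where
#' `Sigma_jj` is the marginal between-study variance from the multivariate
#' fit and `s2_j` the typical within-study variance over the studies that
#' observed outcome j. These statistics use the multivariate estimate of
#' the between-study covariance but are functions of its marginal variances
#' only. An outcome observed by fewer than two studies yields `NA`.
#'
#' @param Sigma Estimated between-study covariance (full outcome
#'   dimension, PSD).
#' @param d The `mv_dataset`.
#' @return Named numeric vector of per-outcome I-squared values.
#' @export
whites_i2 <- function(Sigma, d) {
  Sigma <- as.matrix(Sigma)
  p <- d$space$p_full
  out <- setNames(rep(NA_real_, p), d$space$names)
  for (j in seq_len(p)) {
    v <- unlist(lapply(d$studies, function(s) {
      m <- match(j, s$observed)
      if (is.na(m)) NULL else s$S[m, m]
    }))
    if (length(v) >= 2L) {
      s2 <- typical_within_variance(v)
      out[j] <- Sigma[j, j] / (Sigma[j, j] + s2)
    }
  }
  out
}

#' Scale an R statistic for t-based confidence regions
#'
#' Users who build random-effects confidence intervals with t rather than
#' normal quantiles can inflate R by the ratio of the two quantiles at the
#' given coverage.
#'
#' @param R The R statistic.
#' @param v Degrees of freedom for the t quantile (>= 1).
#' @param level Two-sided coverage in (0, 1), default 0.95.
#' @return Scaled R.
#' @export
t_scaled_R <- function(R, v, level = 0.95) {
  if (v < 1) stop("v must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 + level) / 2
  R * stats::qt(a, df = v) / stats::qnorm(a)
}

#' Full heterogeneity report for a multivariate meta-analysis
#'
#' Assembles all heterogeneity statistics from a random-effects and a
#' fixed-effects fit on the same data and design: the joint `Q_s`, `v`,
#' `H2` and `I2_H`; `R` and `I2_R` for each singleton coefficient, the full
#' coefficient set and any requested subsets or contrasts; and per-outcome
#' univariate statistics (classical Q-based and variance-based I-squared,
#' computed on the studies observing each outcome, with the univariate REML
#' between-study variance) alongside the per-outcome I-squared from the
#' multivariate fit's marginal between-study variances.
#'
#' @param d An `mv_dataset`.
#' @param re Random-effects `"mvmeta_fit"` (e.g. from [reml_fit()]).
#' @param fe Fixed-effects `"mvmeta_fit"` on the same data/design, or
#'   `NULL` to fit it.
#' @param sels Optional list of extra [subset_selection()] /
#'   [contrast_selection()] objects.
#' @param design The [design_spec()] shared by both fits; intercept-only by
#'   default.
#' @param per_outcome Compute the per-outcome univariate statistics
#'   (requires a univariate REML fit per outcome; default `TRUE`).
#' @return An object of class `"het_report"`.
#' @examples
#' d <- berkey_periodontal()
#' re <- reml_fit(d)
#' heterogeneity_report(d, re)
#' @export
heterogeneity_report <- function(d, re, fe = NULL, sels = NULL,
                                 design = NULL, per_outcome = TRUE) {
  if (is.null(design)) design <- design_spec(d$space)
  if (is.null(fe)) fe <- fixed_effects_fit(d, design)
  if (!identical(names(re$beta), names(fe$beta)))
    stop("random- and fixed-effects fits disagree on the coefficient layout")
  q <- design$q
  qs <- q_s(d, design, fe)
  h2 <- h2_stats(qs$Q_s, qs$v)

  all_sels <- c(lapply(seq_len(q), function(j)
    subset_selection(j, label = design$coef_names[j])),
    list(subset_selection(seq_len(q), label = "all")),
    sels)
  entries <- do.call(rbind, lapply(all_sels, function(sel) {
    R <- multivariate_R(re$C, fe$C, sel)
    data.frame(selection = sel$label, kind = sel$kind, p = sel$p_eff,
               R = R, I2_R = i2_from_R(R), convention = re$cov_method,
               stringsAsFactors = FALSE)
  }))

  po <- NULL
  if (per_outcome) {
    white <- whites_i2(re$Sigma, d)
    rows <- lapply(seq_len(d$space$p_full), function(j) {
      obs <- Filter(function(s) j %in% s$observed, d$studies)
      if (length(obs) < 2L)
        return(data.frame(outcome = d$space$names[j], n = length(obs),
                          tau2_reml = NA, tau2_dl = NA, Q = NA, I2_Q = NA,
                          I2_tau = NA, I2_white = white[j], s2_typical = NA,
                          stringsAsFactors = FALSE))
      y <- vapply(obs, function(s) s$y[match(j, s$observed)], numeric(1))
      v <- vapply(obs, function(s) s$S[match(j, s$observed),
                                       match(j, s$observed)], numeric(1))
      uf <- univariate_reml(y, v)
      us <- univariate_stats(y, v, uf$tau2)
      data.frame(outcome = d$space$names[j], n = length(obs),
                 tau2_reml = uf$tau2, tau2_dl = us$tau2_dl, Q = us$Q,
                 I2_Q = us$I2_Q, I2_tau = us$I2_tau, I2_white = white[j],
                 s2_typical = us$s2, stringsAsFactors = FALSE)
    })
    po <- do.call(rbind, rows)
  }

  structure(list(Q_s = qs$Q_s, v = qs$v, H2 = h2$H2, I2_H = h2$I2_H,
                 entries = entries, per_outcome = po,
                 convention = re$cov_method),
            class = "het_report")
}

#' Univariate random-effects meta-analysis by REML
#'
#' Convenience wrapper fitting the one-outcome random-effects model through
#' the multivariate machinery.
#'
#' @param y Study estimates.
#' @param var Their within-study variances.
#' @param cov_method Covariance convention for the pooled mean's standard
#'   error, as in [fit_options()].
#' @return List with `mu`, `se`, `tau2` and the full `"mvmeta_fit"`.
#' @export
univariate_reml <- function(y, var, cov_method = "obsinfo") {
  sp <- outcome_space("y")
  studies <- lapply(seq_along(y), function(i)
    study_record(i, 1L, y[i], matrix(var[i], 1, 1)))
  d <- mv_dataset(studies, sp)
  fit <- reml_fit(d, opts = fit_options("reml", cov_method = cov_method))
  list(mu = unname(fit$beta[1L]), se = sqrt(fit$C[1L, 1L]),
       tau2 = fit$Sigma[1L, 1L], fit = fit)
}

#' @export
print.het_report <- function(x, digits = 3, ...) {
  cat("Multivariate heterogeneity report (covariance convention: ",
      x$convention, ")\n", sep = "")
  cat(sprintf("  Q_s = %.*f on v = %d df;  H2 = %.*f;  I2_H = %.*f\n",
              digits, x$Q_s, x$v, digits, x$H2, digits, x$I2_H))
  cat("R / I2_R by selection:\n")
  e <- x$entries
  e$R <- round(e$R, digits); e$I2_R <- round(e$I2_R, digits)
  print(e, row.names = FALSE)
  if (!is.null(x$per_outcome)) {
    cat("Per-outcome univariate statistics:\n")
    po <- x$per_outcome
    num <- vapply(po, is.numeric, logical(1))
    po[num] <- lapply(po[num], round, digits = digits)
    print(po, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a heterogeneity report to one row per statistic
#'
#' @param x A `"het_report"`.
#' @param row.names,optional,... Ignored; S3 compatibility.
#' @return Data frame with columns statistic, selection, p, value,
#'   convention.
#' @export
as.data.frame.het_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list(
    data.frame(statistic = c("Q_s", "v", "H2", "I2_H"),
               selection = "all", p = NA_integer_,
               value = c(x$Q_s, x$v, x$H2, x$I2_H),
               convention = c("-", "-", "-", "-"),
               stringsAsFactors = FALSE))
  for (i in seq_len(nrow(x$entries))) {
    e <- x$entries[i, ]
    rows[[length(rows) + 1L]] <-
      data.frame(statistic = c("R", "I2_R"), selection = e$selection,
                 p = e$p, value = c(e$R, e$I2_R), convention = e$convention,
                 stringsAsFactors = FALSE)
  }
  if (!is.null(x$per_outcome)) {
    for (i in seq_len(nrow(x$per_outcome))) {
      po <- x$per_outcome[i, ]
      stats_ <- c("tau2_reml", "tau2_dl", "Q", "I2_Q", "I2_tau",
                  "I2_white", "s2_typical")
      rows[[length(rows) + 1L]] <-
        data.frame(statistic = stats_, selection = po$outcome, p = 1L,
                   value = unlist(po[stats_], use.names = FALSE),
                   convention = "-", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
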