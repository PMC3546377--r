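#' Specify a synthetic multivariate meta-analysis generator
#'
#' Datasets are generated under the standard two-stage model: each study's
#' true effect vector is drawn from `N(mu, Sigma)`; its estimate vector is
#' then drawn from a normal around the true effect with a known
#' within-study covariance built from per-outcome variances (uniform on
#' `s_range`) and a common within-study correlation. Outcomes are then
#' masked independently, completely at random, with probability
#' `miss_prob`.
#'
#' @param mu True mean vector (length p).
#' @param Sigma True between-study covariance (p x p, PSD).
#' @param n Number of studies (>= 2).
#' @param s_range Within-study variance range `c(lo, hi)`, `0 < lo <= hi`,
#'   shared by all outcomes, or a p x 2 matrix of per-outcome ranges.
#' @param within_corr Common within-study correlation in (-1, 1).
#' @param miss_prob Per-outcome probability of being unobserved (MCAR);
#'   scalar or length-p vector, each < 1.
#' @param seed Integer seed; identical specs yield identical datasets.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(mu, Sigma, n, s_range = c(0.01, 0.05),
                            within_corr = 0, miss_prob = 0, seed = 1L) {
  mu <- as.numeric(mu)
  p <- length(mu)
  Sigma <- as.matrix(Sigma)
  if (!all(dim(Sigma) == c(p, p))) stop("Sigma must be ", p, "x", p)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("Sigma must be PSD")
  if (n < 2L) stop("need n >= 2 studies")
  if (is.matrix(s_range)) {
    if (!all(dim(s_range) == c(p, 2L))) stop("s_range matrix must be p x 2")
  } else {
    s_range <- matrix(rep(as.numeric(s_range), each = p), p, 2L)
  }
  if (any(s_range[, 1L] <= 0) || any(s_range[, 2L] < s_range[, 1L]))
    stop("s_range must satisfy 0 < lo <= hi")
  if (abs(within_corr) >= 1) stop("within_corr must lie in (-1, 1)")
  miss_prob <- rep_len(as.numeric(miss_prob), p)
  if (any(miss_prob < 0) || any(miss_prob >= 1))
    stop("miss_prob must lie in [0, 1) per outcome")
  structure(list(mu = mu, Sigma = (Sigma + t(Sigma)) / 2, n = as.integer(n),
                 s_range = s_range, within_corr = within_corr,
                 miss_prob = miss_prob, seed = as.integer(seed)),
            class = "simulation_spec")
}

.sigma_sqrt <- function(Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma)) %*% t(e$vectors)
}

#' Draw one synthetic dataset
#'
#' Generates an `mv_dataset` according to a [simulation_spec()]. The
#' within-study covariances are drawn once per study and thereafter treated
#' as fixed and known, as in the estimation model. Draws in which a study
#' loses all its outcomes or an outcome is observed by fewer than two
#' studies are rejected and redrawn (up to 1000 attempts).
#'
#' @param spec A [simulation_spec()].
#' @return An `mv_dataset`.
#' @examples
#' sp <- simulation_spec(c(0, 0), diag(0.1, 2), n = 6, seed = 42)
#' simulate_dataset(sp)
#' @export
simulate_dataset <- function(spec) {
  if (!inherits(spec, "simulation_spec")) stop("'spec' must be a simulation_spec")
  set.seed(spec$seed)
  p <- length(spec$mu)
  Ls <- .sigma_sqrt(spec$Sigma)
  Corr <- matrix(spec$within_corr, p, p); diag(Corr) <- 1
  if (min(eigen(Corr, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop("within_corr yields a non-PD within-study correlation matrix")
  space <- outcome_space(paste0("y", seq_len(p)))
  for (attempt in seq_len(1000L)) {
    studies <- vector("list", spec$n)
    ok <- TRUE
    seen <- integer(p)
    for (i in seq_len(spec$n)) {
      sd_j <- sqrt(stats::runif(p, spec$s_range[, 1L], spec$s_range[, 2L]))
      S <- Corr * tcrossprod(sd_j)
      theta <- spec$mu + drop(Ls %*% stats::rnorm(p))
      y <- theta + drop(.sigma_sqrt(S) %*% stats::rnorm(p))
      obs <- which(stats::runif(p) >= spec$miss_prob)
      if (length(obs) == 0L) { ok <- FALSE; break }
      seen[obs] <- seen[obs] + 1L
      studies[[i]] <- study_record(paste0("study", i), obs, y[obs],
                                   S[obs, obs, drop = FALSE])
    }
    if (ok && all(seen >= 2L))
      return(mv_dataset(studies, space))
  }
  stop("could not generate a feasible dataset in 1000 attempts; ",
       "miss_prob is likely too high")
}

#' Null calibration of the Q_s statistic
#'
#' Simulates repeated meta-analyses under homogeneity (the supplied spec
#' must have a zero between-study covariance), computes `Q_s` and `v` for
#' each, and summarises the empirical distribution against its nominal
#' chi-squared reference: mean, variance, and exceedance rates at the 0.95
#' and 0.99 chi-squared quantiles.
#'
#' @param spec A [simulation_spec()] with `Sigma = 0`.
#' @param reps Number of replicates (>= 100).
#' @return List with `reps`, `v` (df of each replicate), `mean`, `var`,
#'   `exceed_95`, `exceed_99` and the vector of simulated `Q_s` values.
#' @export
null_qs_calibration <- function(spec, reps = 2000L) {
  if (reps < 100L) stop("reps must be >= 100")
  if (any(spec$Sigma != 0)) stop("null calibration requires Sigma = 0")
  Qs <- numeric(reps)
  vv <- integer(reps)
  for (r in seq_len(reps)) {
    d <- simulate_dataset(.respec(spec, seed = spec$seed + r - 1L))
    qs <- q_s(d)
    Qs[r] <- qs$Q_s
    vv[r] <- qs$v
  }
  q95 <- stats::qchisq(0.95, df = vv)
  q99 <- stats::qchisq(0.99, df = vv)
  list(reps = reps, v = vv, mean = mean(Qs), var = stats::var(Qs),
       exceed_95 = mean(Qs > q95), exceed_99 = mean(Qs > q99), Q_s = Qs)
}

.respec <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

#' Parameter-recovery and heterogeneity-statistic sampling study
#'
#' Repeatedly simulates datasets from a [simulation_spec()], fits the
#' random-effects model by REML, and computes the heterogeneity report.
#' Returns bias and RMSE for the pooled means and the between-study
#' covariance entries, and the empirical distribution of the multivariate
#' heterogeneity statistics. Replicates whose optimiser fails to converge
#' are counted and excluded from the summaries.
#'
#' @param spec A [simulation_spec()].
#' @param reps Number of replicates (>= 50).
#' @param opts [fit_options()] for the fits; the model covariance
#'   convention is the default here because only point estimates are
#'   summarised.
#' @return List with `summary` (per-parameter bias/RMSE data frame),
#'   `stats` (data frame of R, I2_R, H2, I2_H per replicate),
#'   `n_nonconverged` and `reps_used`.
#' @export
recovery_study <- function(spec, reps = 100L,
                           opts = fit_options("reml", cov_method = "model")) {
  if (reps < 50L) stop("reps must be >= 50")
  p <- length(spec$mu)
  mu_hat <- matrix(NA_real_, reps, p)
  sig_hat <- matrix(NA_real_, reps, p * (p + 1) / 2)
  het <- matrix(NA_real_, reps, 4L,
                dimnames = list(NULL, c("R", "I2_R", "H2", "I2_H")))
  bad <- 0L
  for (r in seq_len(reps)) {
    d <- simulate_dataset(.respec(spec, seed = spec$seed + r - 1L))
    fit <- suppressWarnings(reml_fit(d, opts = opts))
    if (!fit$converged) { bad <- bad + 1L; next }
    fe <- fixed_effects_fit(d)
    mu_hat[r, ] <- fit$beta
    sig_hat[r, ] <- fit$Sigma[lower.tri(fit$Sigma, diag = TRUE)]
    R <- multivariate_R(fit$C, fe$C)
    qs <- q_s(d, fe = fe)
    h2 <- h2_stats(qs$Q_s, qs$v)
    het[r, ] <- c(R, i2_from_R(R), h2$H2, h2$I2_H)
  }
  keep <- stats::complete.cases(mu_hat)
  truth <- c(spec$mu, spec$Sigma[lower.tri(spec$Sigma, diag = TRUE)])
  est <- cbind(mu_hat, sig_hat)[keep, , drop = FALSE]
  nm <- c(paste0("mu", seq_len(p)),
          paste0("sigma_", which(lower.tri(diag(p), diag = TRUE))))
  summary <- data.frame(
    parameter = nm, truth = truth,
    bias = colMeans(est) - truth,
    rmse = sqrt(colMeans(sweep(est, 2L, truth)^2)),
    mc_se = apply(est, 2L, stats::sd) / sqrt(sum(keep)))
  list(summary = summary,
       stats = as.data.frame(het[keep, , drop = FALSE]),
       n_nonconverged = bad, reps_used = sum(keep))
}
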