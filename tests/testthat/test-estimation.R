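test_that("GLS reduces to closed forms in degenerate cases", {
  # single study: pooled estimate is the study itself
  sp <- outcome_space(c("a", "b"))
  S1 <- matrix(c(2, 0.5, 0.5, 1), 2)
  d1 <- mv_dataset(list(study_record("s", 1:2, c(1, -1), S1)), sp,
                   validate = FALSE)
  f <- gls_fit(d1, matrix(0, 2, 2))
  expect_equal(unname(f$beta), c(1, -1))
  expect_equal(unname(f$C), S1)

  # identical estimates across studies are interpolated exactly
  set.seed(2)
  studies <- lapply(1:4, function(i)
    study_record(i, 1:2, c(0.3, -0.2), rand_psd(2, 0.1)))
  dd <- mv_dataset(studies, sp)
  ff <- fixed_effects_fit(dd)
  expect_equal(unname(ff$beta), c(0.3, -0.2))
  expect_equal(unname(ff$Sigma), matrix(0, 2, 2))
})

test_that("fixed-effects fit matches the brute-force stacked GLS oracle", {
  d <- periodontal_dataset()
  fe <- fixed_effects_fit(d)
  oracle <- gls_oracle(d, matrix(0, 2, 2))
  expect_equal(unname(fe$beta), oracle$beta, tolerance = 1e-10)
  expect_equal(unname(fe$C), oracle$C, tolerance = 1e-10)

  # and at a non-zero between-study covariance
  Sig <- matrix(c(0.012, 0.012, 0.012, 0.033), 2)
  g <- gls_fit(d, Sig)
  oracle2 <- gls_oracle(d, Sig)
  expect_equal(unname(g$beta), oracle2$beta, tolerance = 1e-10)
  # printed Table values for the REML-level covariance
  expect_equal(unname(g$beta), c(0.353, -0.339), tolerance = 5e-3)
})

test_that("univariate fixed-effects fit is the inverse-variance weighted mean", {
  r <- periodontal_raw()
  sp <- outcome_space("y")
  studies <- lapply(1:5, function(i)
    study_record(i, 1L, r$y1[i], matrix(r$s11[i])))
  d <- mv_dataset(studies, sp)
  fe <- fixed_effects_fit(d)
  w <- 1 / r$s11
  expect_equal(unname(fe$beta), sum(w * r$y1) / sum(w), tolerance = 1e-12)
  expect_equal(unname(fe$beta), 0.3472008702, tolerance = 1e-9)
  expect_equal(unname(fe$C[1, 1]), 1 / sum(w), tolerance = 1e-12)
})

test_that("DerSimonian-Laird univariate computations match closed forms", {
  r <- dl_univariate(c(0, 1), c(1, 1))
  expect_equal(r$mu_fixed, 0.5)
  expect_equal(r$Q, 0.5)
  expect_equal(r$tau2_dl, 0)

  raw <- periodontal_raw()
  expect_equal(dl_univariate(raw$y1, raw$s11)$Q, 12.8212963402,
               tolerance = 1e-9)

  same <- dl_univariate(rep(0.4, 4), c(1, 2, 3, 4))
  expect_equal(same$Q, 0)
  expect_equal(same$tau2_dl, 0)

  expect_error(dl_univariate(c(0, 1), c(1, -1)), "positive")
  expect_error(dl_univariate(1, 1), "at least 2")
})

test_that("REML estimates on the periodontal data agree with an independent implementation", {
  d <- periodontal_dataset()
  fit <- reml_fit(d, opts = fit_options("reml", cov_method = "model"))
  expect_true(fit$converged)

  r <- periodontal_raw()
  dat <- data.frame(trial = rep(1:5, each = 2), outcome = rep(1:2, 5),
                    yi = as.vector(rbind(r$y1, r$y2)))
  V <- matrix(0, 10, 10)
  for (i in 1:5) {
    idx <- c(2 * i - 1, 2 * i)
    V[idx, idx] <- matrix(c(r$s11[i], r$s12[i], r$s12[i], r$s22[i]), 2)
  }
  ref <- metafor::rma.mv(yi, V = V, mods = ~ factor(outcome) - 1,
                         random = ~ factor(outcome) | trial, struct = "UN",
                         data = dat, method = "REML")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(diag(fit$Sigma)), ref$tau2, tolerance = 1e-4)
  expect_equal(fit$Sigma[1, 2] / sqrt(prod(diag(fit$Sigma))), ref$rho,
               tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(fit$C))), ref$se, tolerance = 1e-5)
})

test_that("the restricted objective is minimised at the REML solution", {
  d <- periodontal_dataset()
  fit <- reml_fit(d)
  at_opt <- neg_restricted_loglik(fit$sigma_par, d)
  expect_equal(at_opt, -fit$loglik, tolerance = 1e-8)
  set.seed(3)
  for (k in 1:20) {
    perturbed <- fit$sigma_par * (1 + 0.2 * rnorm(3)) + 0.01 * rnorm(3)
    expect_gte(neg_restricted_loglik(perturbed, d), at_opt - 1e-8)
  }
  # pathological parameters yield the documented penalty, not an error
  expect_equal(neg_restricted_loglik(c(Inf, 0, 0), d), 1e10)
})

test_that("observed-information covariance equals the model covariance without nuisance parameters", {
  d <- periodontal_dataset()
  fe <- fixed_effects_fit(d)
  expect_identical(observed_information_cov(d, design_spec(d$space), fe),
                   fe$C)
  # with variance parameters the obsinfo covariance is strictly larger
  re <- reml_fit(d)  # obsinfo by default
  rem <- reml_fit(d, opts = fit_options("reml", cov_method = "model"))
  expect_true(all(diag(re$C) > diag(rem$C)))
})

test_that("estimates are equivariant under invertible linear outcome transformations", {
  set.seed(4)
  d <- rand_dataset(8, 2)
  A <- matrix(c(2, 0.5, -1, 1.5), 2)
  dA <- mv_dataset(lapply(d$studies, function(s)
    study_record(s$study_id, s$observed, drop(A %*% s$y),
                 A %*% s$S %*% t(A))), d$space)
  f <- fixed_effects_fit(d)
  fA <- fixed_effects_fit(dA)
  expect_equal(unname(fA$beta), drop(A %*% f$beta), tolerance = 1e-8)
  expect_equal(unname(fA$C), A %*% f$C %*% t(A), tolerance = 1e-8)

  r <- reml_fit(d, opts = fit_options("reml", cov_method = "model"))
  rA <- reml_fit(dA, opts = fit_options("reml", cov_method = "model"))
  expect_equal(unname(rA$Sigma), A %*% r$Sigma %*% t(A), tolerance = 1e-4)
  expect_equal(unname(rA$beta), drop(A %*% r$beta), tolerance = 1e-5)
})

test_that("ML shrinks the between-study covariance relative to REML on average", {
  set.seed(5)
  tr_ml <- tr_reml <- numeric(10)
  for (k in 1:10) {
    sp <- simulation_spec(c(0, 0), matrix(c(0.05, 0.02, 0.02, 0.05), 2),
                          n = 8, s_range = c(0.01, 0.05), seed = 100 + k)
    d <- simulate_dataset(sp)
    tr_ml[k] <- sum(diag(suppressWarnings(
      ml_fit(d, opts = fit_options("ml", cov_method = "model"))$Sigma)))
    tr_reml[k] <- sum(diag(suppressWarnings(
      reml_fit(d, opts = fit_options("reml", cov_method = "model"))$Sigma)))
  }
  expect_lt(mean(tr_ml), mean(tr_reml))
})

test_that("ML with the covariance fixed at truth reproduces the GLS coefficients", {
  set.seed(6)
  d <- rand_dataset(10, 2)
  Sig <- rand_psd(2, 0.05)
  g <- gls_fit(d, Sig)
  oracle <- gls_oracle(d, Sig)
  expect_equal(unname(g$beta), oracle$beta, tolerance = 1e-10)
})

test_that("structured between-study covariances are honoured", {
  d <- periodontal_dataset()
  fd <- reml_fit(d, opts = fit_options("reml", cov_method = "model",
                                       sigma_structure = "diagonal"))
  expect_equal(fd$Sigma[1, 2], 0)
  fs <- reml_fit(d, opts = fit_options("reml", cov_method = "model",
                                       sigma_structure = "scaled_identity"))
  expect_equal(fs$Sigma[1, 1], fs$Sigma[2, 2])
})
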