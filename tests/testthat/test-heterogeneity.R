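test_that("the R statistic follows its closed forms and error contract", {
  set.seed(10)
  M <- rand_psd(3)
  expect_equal(multivariate_R(M, M), 1)
  expect_equal(multivariate_R(M, M, subset_selection(c(1, 3))), 1)
  expect_equal(multivariate_R(diag(c(4, 9)), diag(2)), sqrt(6))
  # p = 1 reduction: ratio of standard errors
  expect_equal(multivariate_R(diag(c(4, 9)), diag(2), subset_selection(1)),
               2)
  expect_error(multivariate_R(matrix(0, 2, 2), diag(2)), "singular")
})

test_that("I2_R maps R correctly and truncates below one", {
  expect_equal(i2_from_R(1), 0)
  expect_equal(i2_from_R(2.14), (2.14^2 - 1) / 2.14^2)
  expect_equal(i2_from_R(0.5), 0)  # truncation branch
  expect_error(i2_from_R(0), "positive")
  expect_error(i2_from_R(-1), "positive")
})

test_that("Q_s vanishes for homogeneous data and reduces to Cochran's Q univariately", {
  sp <- outcome_space(c("a", "b"))
  set.seed(11)
  same <- mv_dataset(lapply(1:4, function(i)
    study_record(i, 1:2, c(1, 2), rand_psd(2, 0.1))), sp)
  qs <- q_s(same)
  expect_equal(qs$Q_s, 0, tolerance = 1e-20)
  expect_equal(qs$v, 6L)

  for (k in 1:10) {
    n <- sample(3:12, 1)
    y <- rnorm(n)
    v <- runif(n, 0.1, 2)
    d <- mv_dataset(lapply(seq_len(n), function(i)
      study_record(i, 1L, y[i], matrix(v[i]))), outcome_space("y"))
    expect_equal(q_s(d)$Q_s, dl_univariate(y, v)$Q, tolerance = 1e-12)
    expect_equal(q_s(d)$v, n - 1L)
  }
})

test_that("H2 statistics handle the null expectation and the truncation branch", {
  expect_equal(h2_stats(8, 8), list(H2 = 1, I2_H = 0))
  expect_equal(h2_stats(4, 8)$I2_H, 0)
  h <- h2_stats(16, 8)
  expect_equal(h$H2, 2)
  expect_equal(h$I2_H, 0.5)
  expect_error(h2_stats(5, 0), "v must be")
})

test_that("typical within-study variance matches its summation oracle", {
  expect_equal(typical_within_variance(rep(0.3, 6)), 0.3)
  raw <- periodontal_raw()
  expect_equal(typical_within_variance(raw$s11), 0.0046280061,
               tolerance = 1e-8)
  expect_equal(typical_within_variance(raw$s22), 0.0021205654,
               tolerance = 1e-8)
  expect_error(typical_within_variance(c(1, -1)), "positive")
})

test_that("univariate statistics reduce correctly under homogeneity", {
  us <- univariate_stats(rep(1, 5), rep(0.2, 5), tau2 = 0)
  expect_equal(us$I2_tau, 0)
  expect_equal(us$R_u, 1)
  expect_equal(us$Q, 0)
  expect_equal(us$I2_Q, 0)
})

test_that("per-outcome I2 from the marginal between-study variances behaves as specified", {
  d <- periodontal_dataset()
  expect_equal(unname(whites_i2(matrix(0, 2, 2), d)), c(0, 0))

  # equal within-study variances c and Sigma_jj = c gives exactly 1/2
  sp <- outcome_space("y")
  dd <- mv_dataset(lapply(1:4, function(i)
    study_record(i, 1L, 0, matrix(0.3))), sp)
  expect_equal(unname(whites_i2(matrix(0.3), dd)), 0.5)

  # an outcome observed once is reported as NA, not an error
  sp2 <- outcome_space(c("a", "b"))
  d2 <- mv_dataset(list(
    study_record(1, 1:2, c(0, 0), diag(2)),
    study_record(2, 1L, 0, matrix(1)),
    study_record(3, 1L, 0, matrix(1))), sp2)
  w <- whites_i2(diag(0.5, 2), d2)
  expect_false(is.na(w[1]))
  expect_true(is.na(w[2]))
})

test_that("t-scaling of R matches the quantile ratio and is monotone in df", {
  expect_equal(t_scaled_R(1, 4, 0.95), 1.4165796551, tolerance = 1e-8)
  expect_equal(t_scaled_R(2, 1e6, 0.95), 2, tolerance = 1e-5)
  vals <- sapply(c(2, 5, 10, 50), function(v) t_scaled_R(1.5, v, 0.95))
  expect_true(all(diff(vals) < 0))
})

test_that("R is at least one for every subset under the model covariance convention", {
  set.seed(12)
  for (k in 1:40) {
    d <- rand_dataset(6, 2)
    Sig <- rand_psd(2, runif(1, 0.001, 0.2))
    re <- gls_fit(d, Sig, method = "reml")      # model covariance at Sigma
    fe <- fixed_effects_fit(d)
    for (sel in list(subset_selection(1), subset_selection(2), NULL)) {
      expect_gte(multivariate_R(re$C, fe$C, sel), 1 - 1e-12)
    }
  }
})

test_that("full-dimension R is invariant under invertible outcome reparameterisation", {
  set.seed(13)
  d <- periodontal_dataset()
  re <- reml_fit(d)
  fe <- fixed_effects_fit(d)
  R0 <- multivariate_R(re$C, fe$C)
  for (k in 1:10) {
    A <- matrix(rnorm(4), 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
    RA <- multivariate_R(A %*% re$C %*% t(A), A %*% fe$C %*% t(A))
    expect_equal(RA, R0, tolerance = 1e-10)
  }
})

test_that("in one dimension with equal study sizes I2_R equals tau2/(tau2+s2) exactly", {
  # all S_i identical: the model-covariance R^2 is (tau2+s2)/s2
  set.seed(14)
  n <- 7; v0 <- 0.25
  y <- rnorm(n, sd = 0.8)
  d <- mv_dataset(lapply(seq_len(n), function(i)
    study_record(i, 1L, y[i], matrix(v0))), outcome_space("y"))
  tau2 <- 0.4
  re <- gls_fit(d, matrix(tau2), method = "reml")
  fe <- fixed_effects_fit(d)
  R <- multivariate_R(re$C, fe$C)
  expect_equal(i2_from_R(R), tau2 / (tau2 + v0), tolerance = 1e-12)
})

test_that("the heterogeneity report assembles all statistics consistently", {
  d <- periodontal_dataset()
  re <- reml_fit(d)
  fe <- fixed_effects_fit(d)
  rep_ <- heterogeneity_report(d, re, fe,
                               sels = list(contrast_selection(matrix(c(1, -1), 1),
                                                              label = "diff")))
  expect_s3_class(rep_, "het_report")
  expect_equal(rep_$v, 8L)
  expect_equal(rep_$H2, rep_$Q_s / 8)
  # every I2_R entry satisfies the defining identity and lies in [0, 1)
  expect_equal(rep_$entries$I2_R, pmax(0, 1 - rep_$entries$R^-2))
  expect_true(all(rep_$entries$I2_R >= 0 & rep_$entries$I2_R < 1))
  expect_true(all(rep_$entries$R > 0))
  expect_equal(nrow(rep_$entries), 4L)  # two singletons, full set, contrast
  expect_equal(rep_$entries$p, c(1L, 1L, 2L, 1L))
  # flat serialisation covers every statistic row
  flat <- as.data.frame(rep_)
  expect_true(all(c("Q_s", "v", "H2", "I2_H", "R", "I2_R", "I2_white") %in%
                    flat$statistic))
})

test_that("a singleton selection on univariate data recovers the univariate statistics", {
  r <- periodontal_raw()
  d <- mv_dataset(lapply(1:5, function(i)
    study_record(i, 1L, r$y1[i], matrix(r$s11[i]))), outcome_space("y"))
  re <- reml_fit(d, opts = fit_options("reml", cov_method = "model"))
  fe <- fixed_effects_fit(d)
  R <- multivariate_R(re$C, fe$C, subset_selection(1))
  expect_equal(R, sqrt(re$C[1, 1] / fe$C[1, 1]), tolerance = 1e-12)
  qs <- q_s(d)
  expect_equal(qs$Q_s, dl_univariate(r$y1, r$s11)$Q, tolerance = 1e-12)
  h <- h2_stats(qs$Q_s, qs$v)
  expect_equal(h$H2, qs$Q_s / 4)
})
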