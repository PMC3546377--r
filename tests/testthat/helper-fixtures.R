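# Shared fixtures and independent oracles for the test suite.

# Periodontal data, entered directly (independent of the CSV reader).
periodontal_raw <- function() {
  list(y1 = c(0.47, 0.20, 0.40, 0.26, 0.56),
       s11 = c(0.0075, 0.0057, 0.0021, 0.0029, 0.0148),
       y2 = c(-0.32, -0.60, -0.12, -0.31, -0.39),
       s22 = c(0.0077, 0.0008, 0.0014, 0.0015, 0.0304),
       s12 = c(0.0030, 0.0009, 0.0007, 0.0009, 0.0072))
}

periodontal_dataset <- function() {
  r <- periodontal_raw()
  sp <- outcome_space(c("probing_depth", "attachment_level"))
  studies <- lapply(1:5, function(i)
    study_record(i, 1:2, c(r$y1[i], r$y2[i]),
                 matrix(c(r$s11[i], r$s12[i], r$s12[i], r$s22[i]), 2)))
  mv_dataset(studies, sp)
}

# Random PSD matrix with eigenvalues bounded away from zero.
rand_psd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  scale * (tcrossprod(A) / p + diag(0.1, p))
}

# Random complete dataset, built directly (not via simulate_dataset) so
# that property tests of the generator have an independent construction.
rand_dataset <- function(n, p, het = 0.05) {
  sp <- outcome_space(paste0("o", seq_len(p)))
  Sig <- rand_psd(p, scale = het)
  mu <- rnorm(p)
  studies <- lapply(seq_len(n), function(i) {
    S <- rand_psd(p, scale = 0.05)
    th <- mu + drop(chol(Sig) %*% rnorm(p))
    y <- th + drop(chol(S) %*% rnorm(p))
    study_record(i, seq_len(p), y, S)
  })
  mv_dataset(studies, sp)
}

# Brute-force GLS oracle: explicitly stack the design and assemble the
# full block-diagonal covariance, then solve the normal equations.
gls_oracle <- function(d, Sigma, design = NULL) {
  if (is.null(design)) design <- design_spec(d$space)
  Xl <- build_design(d, design)
  X <- do.call(rbind, Xl)
  V <- matrix(0, d$N_obs, d$N_obs)
  at <- 0L
  for (s in d$studies) {
    k <- length(s$observed)
    P <- observed_projection(s, d$space)
    V[at + 1:k, at + 1:k] <- P %*% Sigma %*% t(P) + s$S
    at <- at + k
  }
  y <- unlist(lapply(d$studies, function(s) s$y))
  Vi <- solve(V)
  C <- solve(t(X) %*% Vi %*% X)
  list(beta = unname(drop(C %*% t(X) %*% Vi %*% y)), C = unname(C))
}
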