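#' Fitting options for the random-effects model
#'
#' @param method Estimation method: `"reml"` (restricted maximum
#'   likelihood, the default), `"ml"` (maximum likelihood) or `"fixed"`.
#' @param cov_method Covariance convention for the pooled estimates:
#'   `"obsinfo"` (inverse observed Fisher information over all parameters,
#'   the default, matching common multivariate meta-analysis software) or
#'   `"model"` (the GLS covariance treating the between-study covariance as
#'   known).
#' @param max_iter Maximum optimiser iterations per stage.
#' @param tol Relative convergence tolerance on the objective.
#' @param sigma_structure Structure of the between-study covariance:
#'   `"unstructured"`, `"diagonal"` or `"scaled_identity"`.
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(method = c("reml", "ml", "fixed"),
                        cov_method = c("obsinfo", "model"),
                        max_iter = 500L, tol = 1e-10,
                        sigma_structure = c("unstructured", "diagonal",
                                            "scaled_identity")) {
  method <- match.arg(method)
  cov_method <- match.arg(cov_method)
  sigma_structure <- match.arg(sigma_structure)
  if (tol <= 0) stop("tol must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(method = method, cov_method = cov_method,
                 max_iter = max_iter, tol = tol,
                 sigma_structure = sigma_structure),
            class = "fit_options")
}

## --- internal: assemble per-study blocks ---------------------------------

.prep <- function(d, design = NULL) {
  if (is.null(design)) design <- design_spec(d$space)
  Xlist <- build_design(d, design)
  blocks <- list(design = design,
                 X = Xlist,
                 y = lapply(d$studies, function(s) s$y),
                 S = lapply(d$studies, function(s) as.matrix(s$S)),
                 P = lapply(d$studies, observed_projection, space = d$space),
                 q = design$q)
  ## vectorised likelihood path for the commonest case: complete bivariate
  ## data under the intercept-only mean model (2x2 algebra in closed form)
  if (d$space$p_full == 2L && design$q == 2L &&
      length(design$terms) == 0L &&
      all(vapply(d$studies, function(s) length(s$observed) == 2L, logical(1)))) {
    blocks$fast <- list(
      S11 = vapply(blocks$S, function(S) S[1L, 1L], numeric(1)),
      S12 = vapply(blocks$S, function(S) S[1L, 2L], numeric(1)),
      S22 = vapply(blocks$S, function(S) S[2L, 2L], numeric(1)),
      y1 = vapply(blocks$y, `[`, numeric(1), 1L),
      y2 = vapply(blocks$y, `[`, numeric(1), 2L))
  }
  blocks
}

## profile negative log-likelihood, vectorised over studies (2x2 case)
.fast_profile_nll <- function(Sigma, fb, restricted) {
  V11 <- Sigma[1L, 1L] + fb$S11
  V12 <- Sigma[1L, 2L] + fb$S12
  V22 <- Sigma[2L, 2L] + fb$S22
  dets <- V11 * V22 - V12^2
  if (any(dets <= 0) || any(V11 <= 0)) return(Inf)
  a <- V22 / dets; b <- -V12 / dets; cc <- V11 / dets
  W11 <- sum(a); W12 <- sum(b); W22 <- sum(cc)
  rhs1 <- sum(a * fb$y1 + b * fb$y2)
  rhs2 <- sum(b * fb$y1 + cc * fb$y2)
  dW <- W11 * W22 - W12^2
  if (dW <= 0 || W11 <= 0) return(Inf)
  beta1 <- (W22 * rhs1 - W12 * rhs2) / dW
  beta2 <- (W11 * rhs2 - W12 * rhs1) / dW
  r1 <- fb$y1 - beta1; r2 <- fb$y2 - beta2
  val <- sum(log(dets)) + sum(a * r1^2 + 2 * b * r1 * r2 + cc * r2^2)
  N <- 2L * length(fb$y1)
  val <- val + if (restricted) log(dW) + (N - 2L) * log(2 * pi)
               else N * log(2 * pi)
  0.5 * val
}

## --- internal: between-study covariance parameterisation ------------------
## All structures use unconstrained parameter vectors whose map to Sigma is
## smooth and reaches the PSD boundary (singular Sigma, correlation +/-1):
##   unstructured    lower-triangular square root, p(p+1)/2 entries
##   diagonal        p entries, Sigma = diag(theta^2)
##   scaled_identity 1 entry,   Sigma = theta^2 I

.sigma_npar <- function(p, structure) {
  switch(structure,
         unstructured = p * (p + 1L) / 2L,
         diagonal = p,
         scaled_identity = 1L)
}

.theta_to_sigma <- function(theta, p, structure) {
  switch(structure,
         unstructured = {
           L <- matrix(0, p, p)
           L[lower.tri(L, diag = TRUE)] <- theta
           tcrossprod(L)
         },
         diagonal = diag(theta^2, p),
         scaled_identity = diag(theta[1L]^2, p))
}

.sigma_to_theta <- function(Sigma, structure) {
  p <- nrow(Sigma)
  switch(structure,
         unstructured = {
           L <- tryCatch(t(chol(Sigma + diag(1e-12, p))),
                         error = function(e) diag(sqrt(pmax(diag(Sigma), 0)), p))
           L[lower.tri(L, diag = TRUE)]
         },
         diagonal = sqrt(pmax(diag(Sigma), 0)),
         scaled_identity = sqrt(max(mean(diag(Sigma)), 0)))
}

## --- internal: GLS core ---------------------------------------------------

.gls_core <- function(blocks, Sigma) {
  q <- blocks$q
  W <- matrix(0, q, q)
  b <- numeric(q)
  for (i in seq_along(blocks$y)) {
    P <- blocks$P[[i]]
    V <- P %*% Sigma %*% t(P) + blocks$S[[i]]
    R <- chol(V)
    Xi <- backsolve(R, blocks$X[[i]], transpose = TRUE)
    yi <- backsolve(R, blocks$y[[i]], transpose = TRUE)
    W <- W + crossprod(Xi)
    b <- b + crossprod(Xi, yi)
  }
  Rw <- tryCatch(chol(W), error = function(e)
    stop("singular total-weight matrix: some coefficient is unestimable (",
         paste(blocks$design$coef_names, collapse = ", "), ")", call. = FALSE))
  C <- chol2inv(Rw)
  beta <- drop(C %*% b)
  names(beta) <- blocks$design$coef_names
  dimnames(C) <- list(blocks$design$coef_names, blocks$design$coef_names)
  list(beta = beta, C = C, W = W)
}

.check_rank <- function(blocks) {
  Xall <- do.call(rbind, blocks$X)
  qr_ <- qr(Xall)
  if (qr_$rank < blocks$q) {
    bad <- blocks$design$coef_names[qr_$pivot[(qr_$rank + 1L):blocks$q]]
    stop("rank-deficient design: coefficient(s) not estimable: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.new_fit <- function(beta, C, Sigma, method, cov_method, loglik, converged,
                     n_iter, blocks, sigma_par = numeric(0),
                     sigma_structure = "unstructured") {
  Sigma <- as.matrix(Sigma)
  structure(list(beta = beta, C = C, Sigma = Sigma, method = method,
                 cov_method = cov_method, loglik = loglik,
                 converged = converged, n_iter = n_iter,
                 sigma_par = sigma_par, sigma_structure = sigma_structure,
                 blocks = blocks),
            class = "mvmeta_fit")
}

#' @export
print.mvmeta_fit <- function(x, ...) {
  cat("Multivariate meta-analysis fit (", x$method, ", cov = ", x$cov_method,
      ")\n", sep = "")
  se <- sqrt(diag(x$C))
  tab <- data.frame(estimate = round(x$beta, 4), se = round(se, 4))
  print(tab)
  if (x$method != "fixed") {
    cat("Between-study covariance matrix:\n")
    print(round(x$Sigma, 4))
  }
  cat("log-likelihood:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}

#' Generalised least squares fit with a known between-study covariance
#'
#' The pooled coefficients are the GLS solution
#' `beta = (sum X_i' V_i^-1 X_i)^-1 sum X_i' V_i^-1 y_i`, where
#' `V_i = P_i Sigma P_i' + S_i` combines the supplied between-study
#' covariance (projected to each study's observed outcomes) with the known
#' within-study covariance. The returned covariance `C` is the model-based
#' `(sum X_i' V_i^-1 X_i)^-1`.
#'
#' @param d An `mv_dataset`.
#' @param Sigma Between-study covariance matrix (PSD, full outcome
#'   dimension).
#' @param design A [design_spec()]; intercept-only by default.
#' @param method Method label recorded in the result.
#' @return An object of class `"mvmeta_fit"`.
#' @export
gls_fit <- function(d, Sigma, design = NULL, method = "fixed") {
  blocks <- .prep(d, design)
  .check_rank(blocks)
  Sigma <- as.matrix(Sigma)
  p <- d$space$p_full
  if (!all(dim(Sigma) == c(p, p))) stop("Sigma must be ", p, "x", p)
  g <- .gls_core(blocks, Sigma)
  ll <- -.nll_value(c(g$beta), Sigma, blocks, restricted = FALSE)
  .new_fit(g$beta, g$C, Sigma, method, "model", ll, TRUE, 0L, blocks)
}

#' Fixed-effects multivariate fit
#'
#' GLS with the between-study covariance constrained to zero: all studies
#' share one true effect vector and only within-study sampling error
#' remains. The covariance of the estimates is deterministic given the data
#' because the within-study covariances are treated as known.
#'
#' @inheritParams gls_fit
#' @return An `"mvmeta_fit"` with `method = "fixed"` and a zero
#'   between-study covariance.
#' @export
fixed_effects_fit <- function(d, design = NULL) {
  p <- d$space$p_full
  gls_fit(d, matrix(0, p, p), design, method = "fixed")
}

## --- internal: likelihood values ------------------------------------------

.nll_value <- function(beta, Sigma, blocks, restricted = FALSE) {
  val <- 0
  N <- 0L
  q <- blocks$q
  W <- matrix(0, q, q)
  for (i in seq_along(blocks$y)) {
    P <- blocks$P[[i]]
    V <- P %*% Sigma %*% t(P) + blocks$S[[i]]
    R <- chol(V)
    r <- backsolve(R, blocks$y[[i]] - blocks$X[[i]] %*% beta, transpose = TRUE)
    val <- val + 2 * sum(log(diag(R))) + sum(r^2)
    if (restricted) {
      Xi <- backsolve(R, blocks$X[[i]], transpose = TRUE)
      W <- W + crossprod(Xi)
    }
    N <- N + length(r)
  }
  if (restricted) {
    val <- val + 2 * sum(log(diag(chol(W)))) + (N - q) * log(2 * pi)
  } else {
    val <- val + N * log(2 * pi)
  }
  0.5 * val
}

.PENALTY <- 1e10

.objective <- function(theta, blocks, p, structure, restricted) {
  tryCatch({
    Sigma <- .theta_to_sigma(theta, p, structure)
    v <- if (!is.null(blocks$fast)) {
      .fast_profile_nll(Sigma, blocks$fast, restricted)
    } else {
      g <- .gls_core(blocks, Sigma)
      .nll_value(g$beta, Sigma, blocks, restricted = restricted)
    }
    if (!is.finite(v)) .PENALTY else v
  }, error = function(e) .PENALTY)
}

#' Negative restricted log-likelihood of the between-study covariance
#'
#' Evaluates the REML objective at a between-study covariance encoded by an
#' unconstrained parameter vector (triangular square-root for the
#' unstructured case). The coefficient vector is profiled out at its GLS
#' value for that covariance. Pathological parameter values (non-finite
#' objective, numerically singular total covariance) return a large penalty
#' value rather than failing, so derivative-free optimisers can traverse
#' them.
#'
#' @param theta Parameter vector (length `p(p+1)/2` for unstructured).
#' @param d An `mv_dataset`.
#' @param design A [design_spec()]; intercept-only by default.
#' @param sigma_structure Covariance structure, as in [fit_options()].
#' @return Scalar negative restricted log-likelihood (including constants).
#' @export
neg_restricted_loglik <- function(theta, d, design = NULL,
                                  sigma_structure = "unstructured") {
  blocks <- .prep(d, design)
  .objective(theta, blocks, d$space$p_full, sigma_structure, restricted = TRUE)
}

#' Negative profile log-likelihood of the between-study covariance
#'
#' As [neg_restricted_loglik()] but for the unrestricted Gaussian
#' likelihood, used for maximum likelihood estimation. Profiling the
#' coefficients at their GLS value is exact, so minimising this function
#' over the covariance parameters yields the joint ML solution.
#'
#' @inheritParams neg_restricted_loglik
#' @return Scalar negative log-likelihood (including constants).
#' @export
neg_loglik <- function(theta, d, design = NULL,
                       sigma_structure = "unstructured") {
  blocks <- .prep(d, design)
  .objective(theta, blocks, d$space$p_full, sigma_structure, restricted = FALSE)
}

## --- internal: starting values --------------------------------------------

.start_sigma <- function(d) {
  p <- d$space$p_full
  tau2 <- numeric(p)
  scale <- numeric(p)
  for (j in seq_len(p)) {
    y <- numeric(0); v <- numeric(0)
    for (s in d$studies) {
      m <- match(j, s$observed)
      if (!is.na(m)) { y <- c(y, s$y[m]); v <- c(v, s$S[m, m]) }
    }
    scale[j] <- mean(v)
    tau2[j] <- if (length(y) >= 2L) dl_univariate(y, v)$tau2_dl else 0
  }
  diag(pmax(tau2, 1e-3 * scale), p)
}

.optimise_sigma <- function(blocks, d, opts, restricted) {
  p <- d$space$p_full
  structure_ <- opts$sigma_structure
  obj <- function(th) .objective(th, blocks, p, structure_, restricted)
  starts <- list(.sigma_to_theta(.start_sigma(d), structure_))
  starts[[2]] <- 0.1 * starts[[1]]
  best <- NULL
  n_iter <- 0L
  ## scale bound for the 1-parameter (Brent) case: the between-study sd
  ## cannot usefully exceed the total spread of the estimates
  ub <- 10 * sqrt(max(unlist(lapply(d$studies, function(s) diag(as.matrix(s$S)))),
                      stats::var(unlist(lapply(d$studies, function(s) s$y)))))
  for (st in starts) {
    o1 <- if (length(st) == 1L)
      stats::optim(abs(st), obj, method = "Brent", lower = 0, upper = ub,
                   control = list(maxit = 20L * opts$max_iter))
    else
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(maxit = 20L * opts$max_iter,
                                  reltol = opts$tol))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(maxit = opts$max_iter,
                                      reltol = opts$tol))
    n_iter <- n_iter + sum(c(o1$counts[1L], o2$counts[1L]), na.rm = TRUE)
    cand <- if (o2$value <= o1$value) o2 else o1
    # the two stages agreeing within tolerance is itself evidence of a
    # stationary point, even if the polish stops on its iteration cap
    rel_gap <- abs(o1$value - o2$value) / max(1, abs(o2$value))
    cand$ok <- cand$value < .PENALTY &&
      (cand$convergence == 0L || rel_gap < 100 * opts$tol)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  list(theta = best$par, value = best$value, converged = isTRUE(best$ok),
       n_iter = as.integer(n_iter))
}

.random_effects_fit <- function(d, design, opts, restricted) {
  blocks <- .prep(d, design)
  .check_rank(blocks)
  res <- .optimise_sigma(blocks, d, opts, restricted)
  if (!res$converged)
    warning("between-study covariance optimisation did not converge in ",
            opts$max_iter, " iterations; results returned with converged = FALSE")
  Sigma <- .theta_to_sigma(res$theta, d$space$p_full, opts$sigma_structure)
  dimnames(Sigma) <- list(d$space$names, d$space$names)
  g <- .gls_core(blocks, Sigma)
  fit <- .new_fit(g$beta, g$C, Sigma,
                  method = if (restricted) "reml" else "ml",
                  cov_method = "model", loglik = -res$value,
                  converged = res$converged, n_iter = res$n_iter,
                  blocks = blocks, sigma_par = res$theta,
                  sigma_structure = opts$sigma_structure)
  if (opts$cov_method == "obsinfo" && res$converged) {
    fit$C <- observed_information_cov(d, blocks$design, fit)
    fit$cov_method <- "obsinfo"
  }
  fit
}

#' Random-effects fit by restricted maximum likelihood
#'
#' Estimates the between-study covariance by minimising the negative
#' restricted log-likelihood over an unconstrained square-root
#' parameterisation (so boundary solutions — singular covariance,
#' between-study correlation of one — are attainable), then computes the
#' pooled coefficients by GLS at the estimate. The covariance of the pooled
#' coefficients follows `opts$cov_method`: the observed-information
#' convention (default) propagates the uncertainty of the variance
#' components; the model convention treats the estimated between-study
#' covariance as known.
#'
#' @param d An `mv_dataset`.
#' @param design A [design_spec()]; intercept-only by default.
#' @param opts A [fit_options()] with `method = "reml"`.
#' @return An `"mvmeta_fit"`.
#' @examples
#' d <- berkey_periodontal()
#' reml_fit(d)
#' @export
reml_fit <- function(d, design = NULL, opts = fit_options("reml")) {
  if (opts$method != "reml") stop("opts$method must be 'reml'")
  .random_effects_fit(d, design, opts, restricted = TRUE)
}

#' Random-effects fit by maximum likelihood
#'
#' As [reml_fit()] but maximising the unrestricted Gaussian likelihood
#' jointly over coefficients and between-study covariance (coefficients
#' profiled out exactly at their GLS value).
#'
#' @inheritParams reml_fit
#' @param opts A [fit_options()] with `method = "ml"`.
#' @export
ml_fit <- function(d, design = NULL, opts = fit_options("ml")) {
  if (opts$method != "ml") stop("opts$method must be 'ml'")
  .random_effects_fit(d, design, opts, restricted = FALSE)
}

#' Observed-information covariance of the pooled coefficients
#'
#' Numerically differentiates the unrestricted log-likelihood in all
#' parameters — coefficients and between-study covariance parameters — at
#' the fitted values (central differences, per-parameter step
#' `max(1e-5, 1e-4 |theta|)`), inverts the resulting observed Fisher
#' information and returns the coefficient block. Because the off-diagonal
#' information between coefficients and variance components is not zero in
#' finite samples, this covariance exceeds the model-based one and reflects
#' the uncertainty in the estimated between-study covariance.
#'
#' @param d An `mv_dataset`.
#' @param design The [design_spec()] used for the fit.
#' @param fit A converged `"mvmeta_fit"`.
#' @return The q x q covariance matrix of the coefficients.
#' @export
observed_information_cov <- function(d, design, fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  blocks <- .prep(d, design)
  p <- d$space$p_full
  structure_ <- fit$sigma_structure
  npar_s <- length(fit$sigma_par)
  if (npar_s == 0L || fit$method == "fixed") return(fit$C)
  q <- blocks$q
  fn <- function(par) {
    beta <- par[seq_len(q)]
    th <- par[q + seq_len(npar_s)]
    tryCatch({
      Sigma <- .theta_to_sigma(th, p, structure_)
      v <- .nll_value(beta, Sigma, blocks, restricted = FALSE)
      if (!is.finite(v)) .PENALTY else v
    }, error = function(e) .PENALTY)
  }
  x0 <- c(fit$beta, fit$sigma_par)
  k <- length(x0)
  h <- pmax(1e-5, 1e-4 * abs(x0))
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x0 + ei + ej) - fn(x0 + ei - ej) -
           fn(x0 - ei + ej) + fn(x0 - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  Cov <- tryCatch(solve(H), error = function(e)
    stop("observed information matrix is not invertible; ",
         "consider cov_method = 'model'", call. = FALSE))
  Cb <- Cov[seq_len(q), seq_len(q), drop = FALSE]
  Cb <- (Cb + t(Cb)) / 2
  dimnames(Cb) <- dimnames(fit$C)
  Cb
}

#' Univariate fixed-effects summary and DerSimonian-Laird estimate
#'
#' Inverse-variance weighted mean, Cochran's Q, and the method-of-moments
#' between-study variance `tau2 = max(0, (Q - (n-1)) / (sum w - sum w^2 /
#' sum w))`.
#'
#' @param y Numeric estimates, one per study.
#' @param var Their within-study variances (all positive).
#' @return List with `Q`, `tau2_dl`, `mu_fixed` and the fixed-effects
#'   variance `var_fixed = 1/sum(w)`.
#' @examples
#' dl_univariate(c(0, 1), c(1, 1))
#' @export
dl_univariate <- function(y, var) {
  n <- length(y)
  if (n < 2L) stop("need at least 2 studies")
  if (length(var) != n) stop("y and var must have equal length")
  if (any(var <= 0)) stop("all within-study variances must be positive")
  w <- 1 / var
  mu <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  list(Q = Q, tau2_dl = max(0, (Q - (n - 1)) / denom), mu_fixed = mu,
       var_fixed = 1 / sum(w))
}
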