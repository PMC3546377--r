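#' Define the outcome space of a multivariate meta-analysis
#'
#' The outcome space fixes the set and ordering of outcomes. All matrix
#' layouts (between-study covariance, design blocks, selection matrices)
#' follow this ordering.
#'
#' @param names Character vector of unique outcome labels.
#' @return An object of class `"outcome_space"` with fields `names` and
#'   `p_full` (the number of outcomes).
#' @examples
#' outcome_space(c("probing_depth", "attachment_level"))
#' @export
outcome_space <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("outcome space needs at least one outcome")
  if (anyDuplicated(names)) stop("outcome names must be unique")
  structure(list(names = names, p_full = length(names)),
            class = "outcome_space")
}

#' @export
print.outcome_space <- function(x, ...) {
  cat("Outcome space with", x$p_full, "outcome(s):",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Create a single study record
#'
#' A study contributes an estimate vector for the subset of outcomes it
#' observed, together with the within-study covariance matrix of those
#' estimates (treated as fixed and known).
#'
#' @param study_id Study label.
#' @param observed Integer indices (into the outcome space) of the outcomes
#'   this study observed, in outcome-space order.
#' @param y Numeric estimate vector, one entry per observed outcome.
#' @param S Within-study covariance matrix of `y` (symmetric positive
#'   definite), in squared outcome units.
#' @return An object of class `"study_record"`.
#' @export
study_record <- function(study_id, observed, y, S) {
  observed <- as.integer(observed)
  y <- as.numeric(y)
  S <- as.matrix(S)
  k <- length(observed)
  if (k < 1L) stop("a study must observe at least one outcome")
  if (anyDuplicated(observed)) stop("duplicated outcome index in 'observed'")
  if (length(y) != k) stop("length(y) must equal the number of observed outcomes")
  if (!all(dim(S) == c(k, k))) stop("S must be ", k, "x", k)
  structure(list(study_id = as.character(study_id)[1L],
                 observed = observed, y = y, S = (S + t(S)) / 2),
            class = "study_record")
}

#' Assemble a multivariate meta-analytic dataset
#'
#' @param studies List of [study_record()] objects.
#' @param space An [outcome_space()].
#' @param validate Run [validate_dataset()] on the result (default `TRUE`).
#' @return An object of class `"mv_dataset"` with fields `space`, `studies`
#'   and `N_obs` (total number of univariate estimates across studies).
#' @export
mv_dataset <- function(studies, space, validate = TRUE) {
  if (!inherits(space, "outcome_space")) stop("'space' must be an outcome_space")
  if (!all(vapply(studies, inherits, logical(1), "study_record")))
    stop("'studies' must be a list of study_record objects")
  d <- structure(list(space = space, studies = studies,
                      N_obs = sum(vapply(studies, function(s) length(s$y), integer(1)))),
                 class = "mv_dataset")
  if (validate) validate_dataset(d) else d
}

#' Validate a multivariate meta-analytic dataset
#'
#' Checks the structural invariants: at least two studies, every outcome
#' observed by at least one study, observed indices within range, and every
#' within-study covariance block symmetric positive definite.
#'
#' @param d An `mv_dataset`.
#' @param pd_tol Relative eigenvalue tolerance for the positive-definiteness
#'   check of the within-study blocks.
#' @return `d`, unchanged, if all invariants hold; otherwise an error naming
#'   the offending study or outcome.
#' @export
validate_dataset <- function(d, pd_tol = 1e-12) {
  if (!inherits(d, "mv_dataset")) stop("'d' must be an mv_dataset")
  n <- length(d$studies)
  if (n < 2L) stop("a meta-analysis needs at least 2 studies (got ", n, ")")
  p <- d$space$p_full
  seen <- rep(FALSE, p)
  for (s in d$studies) {
    if (any(s$observed < 1L | s$observed > p))
      stop("study '", s$study_id, "': observed outcome index out of range")
    seen[s$observed] <- TRUE
    ev <- eigen(s$S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= pd_tol * max(abs(ev), 1e-300))
      stop("study '", s$study_id,
           "': within-study covariance matrix is not positive definite")
  }
  if (!all(seen))
    stop("outcome(s) never observed by any study: ",
         paste(d$space$names[!seen], collapse = ", "))
  if (d$N_obs != sum(vapply(d$studies, function(s) length(s$y), integer(1))))
    stop("N_obs inconsistent with study records")
  d
}

#' Selection matrix mapping full-length parameters to a study's observations
#'
#' Returns the k_i x p 0/1 matrix P such that `P %*% mu` extracts the
#' components of a full-length outcome vector that the study observed, and
#' `P %*% Sigma %*% t(P)` the congruent covariance block. This is the
#' marginal-model device for missing outcomes: studies enter the likelihood
#' through their observed subvector only.
#'
#' @param rec A [study_record()].
#' @param space The [outcome_space()] of the dataset.
#' @return A `length(rec$observed)` x `space$p_full` selection matrix.
#' @export
observed_projection <- function(rec, space) {
  p <- space$p_full
  if (any(rec$observed < 1L | rec$observed > p))
    stop("observed outcome index out of range for study '", rec$study_id, "'")
  P <- matrix(0, length(rec$observed), p)
  P[cbind(seq_along(rec$observed), rec$observed)] <- 1
  P
}

#' @export
print.mv_dataset <- function(x, ...) {
  cat("Multivariate meta-analytic dataset:", length(x$studies), "studies,",
      x$space$p_full, "outcome(s),", x$N_obs, "univariate estimates\n")
  cat("Outcomes:", paste(x$space$names, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a dataset to long format
#'
#' One row per (study, outcome) estimate, with the within-study variance.
#' Within-study covariances are returned in the `"covariances"` attribute
#' as a data frame (study, outcome_a, outcome_b, cov).
#'
#' @param x An `mv_dataset`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data frame with columns study, outcome, estimate, variance.
#' @export
as.data.frame.mv_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$studies, function(s) {
    data.frame(study = s$study_id,
               outcome = x$space$names[s$observed],
               estimate = s$y,
               variance = diag(as.matrix(s$S)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  covs <- list()
  for (s in x$studies) {
    k <- length(s$observed)
    if (k > 1L) {
      idx <- which(upper.tri(s$S), arr.ind = TRUE)
      covs[[length(covs) + 1L]] <- data.frame(
        study = s$study_id,
        outcome_a = x$space$names[s$observed[idx[, 1L]]],
        outcome_b = x$space$names[s$observed[idx[, 2L]]],
        cov = s$S[idx],
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "covariances") <-
    if (length(covs)) do.call(rbind, covs) else
      data.frame(study = character(), outcome_a = character(),
                 outcome_b = character(), cov = numeric())
  out
}
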