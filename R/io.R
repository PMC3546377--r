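#' Within-study correlation specification for long-format input
#'
#' Long-format files carry one variance per (study, outcome) row but no
#' covariances; this object says how to fill the off-diagonal entries of
#' each study's within-study covariance matrix. Published datasets rarely
#' report within-study correlations, so a common assumed value (e.g. 0.4 or
#' 0.7) used in a sensitivity analysis is a typical choice.
#'
#' @param mode `"zero"` (diagonal within-study covariance), `"common"` (a
#'   single correlation applied to every pair) or `"file"` (explicit
#'   covariance entries).
#' @param value Correlation in (-1, 1), for `mode = "common"`.
#' @param file For `mode = "file"`: a data frame (or CSV path) with columns
#'   study, outcome_a, outcome_b, cov; unlisted pairs default to zero.
#' @return A list of class `"within_corr"`.
#' @export
within_corr <- function(mode = c("zero", "common", "file"), value = NULL,
                        file = NULL) {
  mode <- match.arg(mode)
  if (mode == "common") {
    if (is.null(value) || abs(value) >= 1)
      stop("mode = 'common' needs a correlation value in (-1, 1)")
  }
  if (mode == "file") {
    if (is.null(file)) stop("mode = 'file' needs covariance entries")
    if (is.character(file)) file <- utils::read.csv(file, stringsAsFactors = FALSE)
    need <- c("study", "outcome_a", "outcome_b", "cov")
    if (!all(need %in% names(file)))
      stop("covariance file needs columns: ", paste(need, collapse = ", "))
    file$study <- as.character(file$study)
  }
  structure(list(mode = mode, value = value, file = file),
            class = "within_corr")
}

#' Read a long-format meta-analytic dataset
#'
#' One row per (study, outcome) estimate with columns `study`, `outcome`,
#' `estimate`, `variance`; any further columns are treated as study-level
#' covariates and returned in the `"covariates"` attribute (one row per
#' study). Missing outcomes are inferred from absent rows. Within-study
#' covariances are assembled according to the [within_corr()]
#' specification.
#'
#' @param path CSV path (comma-separated, `.` decimal, header required) or
#'   a data frame in the same layout.
#' @param corr A [within_corr()]; diagonal by default.
#' @param outcomes Optional explicit outcome ordering; default is order of
#'   first appearance.
#' @return An `mv_dataset`; study-level covariate columns, if any, in
#'   `attr(, "covariates")`.
#' @export
read_long <- function(path, corr = within_corr("zero"), outcomes = NULL) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "outcome", "estimate", "variance")
  if (!all(need %in% names(df)))
    stop("long format needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("no rows in input")
  df$study <- as.character(df$study)
  df$outcome <- as.character(df$outcome)
  if (anyDuplicated(df[c("study", "outcome")]))
    stop("duplicate (study, outcome) rows in input")
  if (any(df$variance <= 0)) stop("all variances must be positive")
  if (is.null(outcomes)) outcomes <- unique(df$outcome)
  if (!all(df$outcome %in% outcomes))
    stop("outcome(s) not in the declared outcome list: ",
         paste(setdiff(df$outcome, outcomes), collapse = ", "))
  space <- outcome_space(outcomes)

  cov_lookup <- function(study, oa, ob) {
    if (corr$mode != "file") return(0)
    f <- corr$file
    hit <- (f$study == study &
              ((f$outcome_a == oa & f$outcome_b == ob) |
                 (f$outcome_a == ob & f$outcome_b == oa)))
    if (any(hit)) f$cov[which(hit)[1L]] else 0
  }

  ids <- unique(df$study)
  studies <- lapply(ids, function(id) {
    rows <- df[df$study == id, , drop = FALSE]
    obs <- sort(match(rows$outcome, outcomes))
    rows <- rows[order(match(rows$outcome, outcomes)), , drop = FALSE]
    k <- length(obs)
    S <- diag(rows$variance, k)
    if (k > 1L) {
      for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
        S[a, b] <- S[b, a] <- switch(corr$mode,
          zero = 0,
          common = corr$value * sqrt(S[a, a] * S[b, b]),
          file = cov_lookup(id, outcomes[obs[a]], outcomes[obs[b]]))
      }
    }
    study_record(id, obs, rows$estimate, S)
  })
  d <- mv_dataset(studies, space)
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    first <- df[!duplicated(df$study), c("study", extra), drop = FALSE]
    rownames(first) <- NULL
    attr(d, "covariates") <- first
  }
  d
}

#' Write a dataset in long format
#'
#' @param d An `mv_dataset`.
#' @param path CSV output path.
#' @param cov_path Optional path for the within-study covariance entries
#'   (study, outcome_a, outcome_b, cov); written only if given.
#' @return Invisibly, the long data frame.
#' @export
write_long <- function(d, path, cov_path = NULL) {
  long <- as.data.frame(d)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(cov_path))
    utils::write.csv(attr(long, "covariances"), cov_path,
                     row.names = FALSE, quote = FALSE)
  invisible(long)
}

#' Read a bivariate dataset in the wide five-column dialect
#'
#' Layout: one row per study with columns `Y1`, `S11`, `Y2`, `S22`, `S12`
#' (estimates, within-study variances and covariance), plus an optional
#' `study` column; this is the layout in which the periodontal dataset is
#' conventionally printed.
#'
#' @param path CSV path or equivalent data frame.
#' @param outcome_names Labels for the two outcomes.
#' @return A bivariate `mv_dataset`.
#' @export
read_wide_berkey <- function(path, outcome_names = c("y1", "y2")) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Y1", "S11", "Y2", "S22", "S12")
  if (!all(need %in% names(df)))
    stop("wide format needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("no rows in input")
  ids <- if ("study" %in% names(df)) as.character(df$study) else
    as.character(seq_len(nrow(df)))
  space <- outcome_space(outcome_names)
  studies <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$S12^2 >= r$S11 * r$S22)
      stop("study '", ids[i],
           "': within-study covariance matrix is not positive definite ",
           "(S12^2 >= S11*S22)")
    study_record(ids[i], 1:2, c(r$Y1, r$Y2),
                 matrix(c(r$S11, r$S12, r$S12, r$S22), 2))
  })
  mv_dataset(studies, space)
}

#' The periodontal therapy dataset
#'
#' Five randomised trials comparing surgical with non-surgical treatment of
#' moderate periodontal disease, each reporting the mean difference (mm,
#' one year post-treatment) in probing depth and attachment level, with
#' known within-study covariance matrices. A classical bivariate
#' meta-analysis example; bundled as a plain-text fixture.
#'
#' @return A bivariate `mv_dataset` with outcomes `probing_depth` and
#'   `attachment_level`.
#' @examples
#' berkey_periodontal()
#' @export
berkey_periodontal <- function() {
  path <- system.file("extdata", "berkey1998.csv", package = "mvhet",
                      mustWork = TRUE)
  read_wide_berkey(path, outcome_names = c("probing_depth", "attachment_level"))
}

#' Serialise a heterogeneity report to JSON
#'
#' Writes the flattened report (one row per statistic: statistic,
#' selection, p, value, convention) under a versioned schema.
#'
#' @param report A `"het_report"`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report_json <- function(report, path) {
  rows <- as.data.frame(report)
  jsonlite::write_json(
    list(schema = "mvhet-report/1",
         convention = report$convention,
         rows = rows),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Serialise a heterogeneity report to flat CSV
#'
#' @inheritParams write_report_json
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
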