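#' Omnibus F test of the oscillatory regressors per region
#'
#' Regressor-quality check at ROI level: for each region, the BOLD trace is
#' regressed on an intercept plus the oscillatory boxcar regressors
#' (unconvolved by default, matching the drivers the DCM receives), and the
#' omnibus F statistic for the joint null of all oscillatory coefficients
#' is computed together with its log transform — a measure of the variance
#' explained by the regressors relative to the residual variance. Optional
#' polynomial drift columns can be added as nuisance covariates.
#'
#' @param recording A `subject_recording`.
#' @param design Matrix of oscillatory regressors at scan resolution
#'   (rows = scans), e.g. from [regressors_at_scans()].
#' @param drift_order Degree of polynomial drift columns added as nuisance
#'   regressors (default 0 = none).
#' @return An object of class `regressor_fit`: data frame with per-region
#'   `F`, `log_f`, and the degrees of freedom `df1` (number of oscillatory
#'   regressors) and `df2` (scans - regressors - nuisance - 1).
#' @export
omnibus_f <- function(recording, design, drift_order = 0) {
  stopifnot(inherits(recording, "subject_recording"))
  design <- as.matrix(design)
  Y <- recording$bold
  if (nrow(design) != nrow(Y)) {
    stop("design has ", nrow(design), " rows but the recording has ",
         nrow(Y), " scans", call. = FALSE)
  }
  if (any(apply(design, 2, function(x) all(x == 0)))) {
    stop("design contains an all-zero regressor column", call. = FALSE)
  }
  n <- nrow(Y)
  nuisance <- matrix(1, n, 1)
  if (drift_order > 0) {
    t_sc <- scale(seq_len(n))
    nuisance <- cbind(nuisance, stats::poly(drop(t_sc), drift_order))
  }
  X <- cbind(nuisance, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design (rank ", qrX$rank, " < ", ncol(X),
         " columns)", call. = FALSE)
  }
  qr0 <- qr(nuisance)
  df1 <- ncol(design)
  df2 <- n - ncol(X)
  stats <- vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    rss1 <- sum(qr.resid(qrX, y)^2)
    rss0 <- sum(qr.resid(qr0, y)^2)
    Fj <- ((rss0 - rss1) / df1) / (rss1 / df2)
    c(Fj, log(Fj))
  }, numeric(2))
  structure(
    list(table = data.frame(region = colnames(Y), F = stats[1, ],
                            log_f = stats[2, ], df1 = df1, df2 = df2),
         drift_order = drift_order),
    class = "regressor_fit"
  )
}

#' @export
print.regressor_fit <- function(x, ...) {
  cat("Omnibus F over oscillatory regressors (df1 =", x$table$df1[1],
      ", df2 =", x$table$df2[1], ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Expected log F statistic under the null hypothesis
#'
#' Exact null expectation of `log F(df1, df2)`:
#' `digamma(df1/2) - log(df1/2) - digamma(df2/2) + log(df2/2)`. Used to
#' center the group-level test of log-transformed F values, which would
#' otherwise be biased (the null mean of log F is negative for small df1).
#'
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return The null expectation of log F.
#' @export
expected_null_log_f <- function(df1, df2) {
  digamma(df1 / 2) - log(df1 / 2) - digamma(df2 / 2) + log(df2 / 2)
}

#' Group-level t-test on log-transformed F statistics
#'
#' One-sample t-test, per region, of subjects' log F values against the
#' null expectation of log F — a test of whether the variance captured by
#' the oscillatory regressors exceeds the residual variance across the
#' group. Degrees of freedom are n - 1 (110 for the full 111-subject
#' cohort).
#'
#' @param log_f Matrix of log F values, subjects x regions (or a list of
#'   [omnibus_f()] results).
#' @param df1,df2 Degrees of freedom of the per-subject F tests; taken
#'   from the first `regressor_fit` when a list is supplied.
#' @return An object of class `group_log_f_test`: per-region `t`, `df`,
#'   `p` (one-sided, greater), the reference value, and a `degenerate`
#'   flag where the across-subject variance is zero (the t statistic is
#'   then unbounded and reported as +-Inf rather than hidden).
#' @export
group_log_f_test <- function(log_f, df1 = NULL, df2 = NULL) {
  if (is.list(log_f) && inherits(log_f[[1]], "regressor_fit")) {
    df1 <- log_f[[1]]$table$df1[1]
    df2 <- log_f[[1]]$table$df2[1]
    regions <- log_f[[1]]$table$region
    log_f <- do.call(rbind, lapply(log_f, function(r) r$table$log_f))
    colnames(log_f) <- regions
  }
  log_f <- as.matrix(log_f)
  if (nrow(log_f) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(df1) || is.null(df2)) {
    stop("df1 and df2 required when log_f is a plain matrix", call. = FALSE)
  }
  ref <- expected_null_log_f(df1, df2)
  n <- nrow(log_f)
  m <- colMeans(log_f)
  s <- apply(log_f, 2, sd)
  degenerate <- s == 0
  tval <- ifelse(degenerate, ifelse(m > ref, Inf, -Inf),
                 (m - ref) / (s / sqrt(n)))
  tab <- data.frame(
    region = colnames(log_f), mean_log_f = m, t = tval, df = n - 1,
    p = pt(tval, df = n - 1, lower.tail = FALSE),
    degenerate = degenerate
  )
  rownames(tab) <- NULL
  structure(list(table = tab, reference = ref, n = n),
            class = "group_log_f_test")
}

#' @export
print.group_log_f_test <- function(x, ...) {
  cat("Group t-test of log F against the null expectation (",
      format(x$reference, digits = 4), "), n = ", x$n, "\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
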