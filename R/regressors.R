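#' Low-frequency boxcar driver regressors
#'
#' Resting-state BOLD shows spontaneous low-frequency fluctuations; a
#' deterministic resting-state DCM models them with periodic on/off drivers
#' in place of task inputs. For each frequency, two boxcars are built with a
#' 90 degree phase lag: the bin covering `[t, t + dt)` is 1 wherever
#' `sin(2 pi f t + phase) > 0` over the bin's interior (evaluated at the
#' bin midpoint), i.e. thresholded sine and cosine waves. The midpoint
#' convention pins each on/off transition to the true zero crossing
#' regardless of the sampling resolution, so refining `dt` never shifts a
#' transition; thresholding at the bin's left edge instead would leave the
#' crossing bins at the mercy of floating-point sign noise whenever the
#' grid hits a crossing exactly (as the default TR/16 grid does). The
#' defaults 0.01, 0.02, 0.04 and 0.08 Hz give eight columns with cycles of
#' 100, 50, 25 and 12.5 s and duty cycle exactly one half.
#'
#' @param frequencies Oscillation frequencies in Hz.
#' @param duration Total duration in seconds; must cover at least one full
#'   period of the slowest oscillation.
#' @param dt Sampling step in seconds (micro-time resolution); must divide
#'   `duration` and resolve the fastest half-period.
#' @param phases Phase offsets in degrees applied per frequency
#'   (default 0 and 90).
#' @return An object of class `boxcar_set`: `values` (T x K binary matrix,
#'   columns named `f<Hz>_p<deg>`), `dt`, `times`, and per-column
#'   `frequencies` and `phases`.
#' @examples
#' bx <- boxcar_regressors(duration = 600, dt = 2.5 / 16)
#' ncol(bx$values)  # 8
#' @export
boxcar_regressors <- function(frequencies = c(0.01, 0.02, 0.04, 0.08),
                              duration, dt, phases = c(0, 90)) {
  stopifnot(is.numeric(frequencies), length(frequencies) >= 1,
            all(frequencies > 0), is.numeric(duration), duration > 0,
            is.numeric(dt), dt > 0)
  if (duration < 1 / min(frequencies)) {
    stop("duration (", duration, " s) shorter than the longest period (",
         1 / min(frequencies), " s)", call. = FALSE)
  }
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("dt must divide duration", call. = FALSE)
  }
  if (dt >= 0.5 / max(frequencies)) {
    stop("dt (", dt, " s) does not resolve the shortest half-period (",
         0.5 / max(frequencies), " s)", call. = FALSE)
  }
  t <- seq(0, duration - dt, by = dt)
  grid <- expand.grid(phase = phases, frequency = frequencies)
  grid <- grid[order(grid$frequency, grid$phase), , drop = FALSE]
  values <- vapply(seq_len(nrow(grid)), function(k) {
    as.numeric(sin(2 * pi * grid$frequency[k] * (t + dt / 2) +
                     grid$phase[k] * pi / 180) > 0)
  }, numeric(length(t)))
  colnames(values) <- paste0("f", grid$frequency, "_p", grid$phase)
  structure(
    list(values = values, dt = dt, times = t,
         frequencies = grid$frequency, phases = grid$phase),
    class = "boxcar_set"
  )
}

#' @export
print.boxcar_set <- function(x, ...) {
  cat("Boxcar driver set:", ncol(x$values), "columns,",
      nrow(x$values), "time bins at dt =", x$dt, "s\n")
  cat("  cycles:", paste(unique(1 / x$frequencies), collapse = ", "), "s\n")
  invisible(x)
}

#' Down-sample a boxcar set to scan times
#'
#' Takes the micro-time bin nearest each scan time `k * tr`,
#' `k = 0 ... n_scans - 1`, mirroring how simulated BOLD is sampled.
#'
#' @param regressors A [boxcar_regressors()] object.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans.
#' @return An `n_scans` x K numeric matrix with the boxcar column names.
#' @export
regressors_at_scans <- function(regressors, tr, n_scans) {
  stopifnot(inherits(regressors, "boxcar_set"))
  idx <- scan_row_index(regressors$dt, tr, n_scans,
                        n_micro = nrow(regressors$values))
  regressors$values[idx, , drop = FALSE]
}

#' Write a boxcar design matrix as TSV
#'
#' @param regressors A [boxcar_regressors()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design_tsv <- function(regressors, path) {
  stopifnot(inherits(regressors, "boxcar_set"))
  utils::write.table(regressors$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# nearest micro-time row for each scan time k*tr (k = 0..n_scans-1),
# 1-based; errors if the simulated duration is insufficient
scan_row_index <- function(dt, tr, n_scans, n_micro) {
  stopifnot(tr > 0, n_scans >= 1)
  idx <- round((seq_len(n_scans) - 1) * tr / dt) + 1
  if (max(idx) > n_micro) {
    stop("simulated duration (", n_micro * dt, " s) too short for ",
         n_scans, " scans at TR = ", tr, " s", call. = FALSE)
  }
  idx
}
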