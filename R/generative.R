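#' Right-hand side of the bilinear neural state equation
#'
#' Evaluates dy/dt = A y + C x + sum_i y_i D(i) y, where D(i) is the matrix
#' of modulatory gains attributed to modulator region i: each modulatory
#' triple (modulator m, source s, target t) with gain g contributes
#' `y[m] * g * y[s]` to the target's derivative, i.e. region m
#' multiplicatively scales the s -> t coupling.
#'
#' @param y Neural state vector (length 5).
#' @param x Driver input vector (length K).
#' @param params A [dcm_parameters()] object.
#' @param spec The matching [cmc_spec()].
#' @return The derivative vector (length 5, Hz).
#' @export
neural_derivative <- function(y, x, params, spec) {
  stopifnot(inherits(params, "dcm_parameters"), inherits(spec, "cmc_spec"))
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    stop("non-finite state or input", call. = FALSE)
  }
  stopifnot(length(y) == nrow(params$a), length(x) == ncol(params$c))
  dy <- unname(drop(params$a %*% y + params$c %*% x))
  tr <- spec$d_triples
  for (j in seq_len(nrow(tr))) {
    dy[tr[j, 3]] <- dy[tr[j, 3]] + y[tr[j, 1]] * params$d[j] * y[tr[j, 2]]
  }
  dy
}

# classed error used for all trajectory blow-ups
divergence_error <- function(kind, step, dt, params) {
  info <- paste0("self-decay = [",
                 paste(signif(diag(params$a), 3), collapse = ", "), "]",
                 if (length(params$d) > 0)
                   paste0(", d = [", paste(signif(params$d, 3),
                                           collapse = ", "), "]")
                 else "")
  msg <- sprintf("%s divergence at t = %.2f s (%s)",
                 if (kind == 1) "neural" else "hemodynamic",
                 step * dt, info)
  structure(
    class = c("dcm_divergence_error", "error", "condition"),
    list(message = msg, call = NULL, step = step, kind = kind)
  )
}

# shared driver for the compiled forward sweep
forward_sweep <- function(params, regressors, duration, want_bold,
                          y_bound = 1e3) {
  stopifnot(inherits(params, "dcm_parameters"),
            inherits(regressors, "boxcar_set"))
  n_steps <- round(duration / regressors$dt)
  if (n_steps > nrow(regressors$values)) {
    stop("duration exceeds the regressor set's coverage", call. = FALSE)
  }
  U <- regressors$values[seq_len(n_steps), , drop = FALSE]
  d_idx <- params_d_index(params)
  res <- dcm_forward_cpp(params$a, params$c, d_idx, params$d, U,
                         regressors$dt, params$hemo$kappa,
                         params$hemo$gamma, params$hemo$tau,
                         params$hemo$alpha, params$hemo$rho,
                         params$hemo$v0, y_bound, want_bold)
  if (res$status != 0) {
    stop(divergence_error(res$status, res$step, regressors$dt, params))
  }
  res
}

# spec triples as a 0-based integer matrix for the compiled code; the
# variant stored with the parameters carries its own triples
params_d_index <- function(params) {
  spec <- cmc_spec(params$variant, n_regressors = ncol(params$c))
  matrix(as.integer(spec$d_triples - 1L), ncol = 3)
}

#' Integrate the neural state equation under boxcar drivers
#'
#' Fixed-step classical RK4 integration at the regressor set's micro-time
#' step, starting from rest (y = 0); inputs are held constant over each
#' micro-time bin. Bit-reproducible for identical inputs. Trajectories
#' leaving `|y| > y_bound` raise a divergence error naming the offending
#' parameters.
#'
#' @param params A [dcm_parameters()] object.
#' @param regressors A [boxcar_regressors()] set; its `dt` becomes the
#'   integration step.
#' @param duration Seconds to integrate (at most the regressor duration).
#' @param y_bound Magnitude bound treated as divergence (default 1e3).
#' @return An object of class `neural_trajectory`: `y` (T x 5 matrix, row t
#'   is the state at time (t-1) dt) and `dt`.
#' @export
simulate_neural <- function(params, regressors, duration, y_bound = 1e3) {
  res <- forward_sweep(params, regressors, duration, want_bold = FALSE,
                       y_bound = y_bound)
  structure(list(y = res$neural, dt = regressors$dt),
            class = "neural_trajectory")
}

#' Balloon-model BOLD from a neural trajectory
#'
#' Integrates, per region, the hemodynamic cascade
#' ds/dt = y - kappa s - gamma (f - 1); df/dt = s;
#' tau dv/dt = f - v^(1/alpha);
#' tau dq/dt = f (1 - (1 - rho)^(1/f)) / rho - v^(1/alpha) q / v,
#' from the resting point (s = 0, f = v = q = 1), and maps (v, q) to BOLD
#' through V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)). Regions are
#' independent given their neural traces. The positive states f, v, q are
#' integrated on the log scale, so they stay positive under arbitrarily
#' strong deactivation; a divergence error is raised only on non-finite
#' states.
#'
#' @param neural A [simulate_neural()] trajectory.
#' @param params A [dcm_parameters()] object (hemodynamic constants used).
#' @return T x 5 matrix of continuous BOLD at micro-time resolution.
#' @export
simulate_bold <- function(neural, params) {
  stopifnot(inherits(neural, "neural_trajectory"),
            inherits(params, "dcm_parameters"))
  if (!all(is.finite(neural$y))) {
    stop("non-finite neural trajectory", call. = FALSE)
  }
  res <- bold_from_neural_cpp(neural$y, neural$dt, params$hemo$kappa,
                              params$hemo$gamma, params$hemo$tau,
                              params$hemo$alpha, params$hemo$rho,
                              params$hemo$v0)
  if (res$status != 0) {
    stop(divergence_error(res$status, res$step, neural$dt, params))
  }
  res$bold
}

#' Sample continuous BOLD at scan times
#'
#' Takes the micro-time sample nearest each scan time k TR
#' (k = 0 ... n_scans - 1) and packages the result as a subject recording.
#'
#' @param bold T x 5 continuous BOLD matrix at micro-time resolution.
#' @param dt Micro-time step of `bold`, seconds.
#' @param tr Repetition time, seconds.
#' @param n_scans Number of scans to extract.
#' @param regions Region labels (default [cmc_regions()]).
#' @param group Optional group label ("PD" or "HC").
#' @param seed Optional seed recorded for provenance.
#' @param truth Optional ground-truth [dcm_parameters()].
#' @return An object of class `subject_recording`: `bold`
#'   (n_scans x 5, columns named by region), `tr`, `regions`, `group`,
#'   `seed`, `truth`, `noise_sd`.
#' @export
sample_to_scans <- function(bold, dt, tr, n_scans, regions = cmc_regions(),
                            group = NA_character_, seed = NA_integer_,
                            truth = NULL) {
  bold <- as.matrix(bold)
  idx <- scan_row_index(dt, tr, n_scans, n_micro = nrow(bold))
  y <- bold[idx, , drop = FALSE]
  colnames(y) <- regions
  rownames(y) <- NULL
  structure(
    list(bold = y, tr = tr, regions = regions, group = group, seed = seed,
         truth = truth, noise_sd = 0),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  cat("Subject recording:", nrow(x$bold), "scans x", ncol(x$bold),
      "regions, TR =", x$tr, "s",
      if (!is.na(x$group)) paste0(", group ", x$group) else "", "\n")
  if (!is.null(x$truth)) cat("  ground-truth parameters attached\n")
  invisible(x)
}
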