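#' Control settings for DCM inversion
#'
#' @param max_iter Maximum outer iterations (default 64).
#' @param tol Free-energy convergence tolerance in nats (default 0.01).
#' @param fd_step Finite-difference step on the latent scale (default 1e-4).
#' @param y_bound Neural divergence bound passed to the integrator.
#' @param max_halvings Step halvings tried per iteration before giving up.
#' @param fit_hemo Also estimate shared hemodynamic scaling latents.
#' @param multi_start Optional `list(n = , seed = )` requesting `n` extra
#'   jittered initializations; the fit with the highest free energy wins.
#' @param verbose Print per-iteration free energies.
#' @return A list of class `dcm_control`.
#' @export
dcm_control <- function(max_iter = 64, tol = 0.01, fd_step = 1e-4,
                        y_bound = 1e3, max_halvings = 6, fit_hemo = FALSE,
                        multi_start = NULL, verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, fd_step > 0)
  structure(list(max_iter = max_iter, tol = tol, fd_step = fd_step,
                 y_bound = y_bound, max_halvings = max_halvings,
                 fit_hemo = fit_hemo, multi_start = multi_start,
                 verbose = verbose),
            class = "dcm_control")
}

# closed-form-style update of the noise log-precision h:
# maximizes N/2 h - exp(h) E/2 - (h - mu)^2 / (2 v) by Newton, clamped
solve_noise_logprec <- function(E, N, mu = 4, v = 1) {
  E <- max(E, 1e-10)
  h <- log(N / E)
  for (i in 1:50) {
    phi <- N / 2 - exp(h) * E / 2 - (h - mu) / v
    dphi <- -exp(h) * E / 2 - 1 / v
    step <- phi / dphi
    h <- h - step
    if (abs(step) < 1e-10) break
  }
  min(max(h, -10), 30)
}

# Laplace free energy given residual sum of squares E, log-precision h,
# latent theta, diagonal prior, and the log-determinant of the posterior
# precision P
free_energy_value <- function(E, h, N, theta, mu0, v0, logdetP,
                              noise_mu = 4, noise_v = 1) {
  p <- length(theta)
  ll <- -N / 2 * log(2 * pi) + N / 2 * h - exp(h) * E / 2
  lp <- -0.5 * sum((theta - mu0)^2 / v0) - 0.5 * sum(log(2 * pi * v0))
  lh <- -0.5 * (h - noise_mu)^2 / noise_v - 0.5 * log(2 * pi * noise_v)
  Ph <- exp(h) * E / 2 + 1 / noise_v
  ll + lp + lh - 0.5 * logdetP - 0.5 * log(Ph) +
    (p + 1) / 2 * log(2 * pi)
}

#' Invert a CMC-DCM variant on one subject recording
#'
#' Fits the generative model to an observed scans x regions BOLD matrix by
#' variational-Laplace style optimization of the free energy
#' F = accuracy - complexity: Gauss-Newton ascent on the latent parameter
#' vector under the Gaussian shrinkage prior, a closed-form update of the
#' shared noise log-precision each outer iteration, and the Laplace
#' approximation for the posterior covariance. The free energy approximates
#' the log model evidence log L(m | y) and is the plug-in used by Bayesian
#' model selection. The fit is deterministic given identical inputs and
#' settings.
#'
#' The forward sweep regenerates the eight boxcar drivers to match the
#' recording duration at micro-time dt = TR/16 and integrates the neural
#' and hemodynamic states jointly; predictions are sampled at scan times.
#' Forward sensitivities use finite differences on the latent scale.
#' Convergence is declared when the free-energy improvement falls below
#' `control$tol` (default 0.01 nats) or after `control$max_iter`
#' iterations, in which case the returned convergence record is flagged.
#'
#' @param recording A `subject_recording` (at least 60 scans).
#' @param spec The [cmc_spec()] variant to fit.
#' @param priors A [dcm_priors()] object (defaults to shrinkage priors for
#'   `spec`).
#' @param control A [dcm_control()] list.
#' @return An object of class `dcm_fit` with posterior mean and covariance
#'   on the generative scale (`mean`, `cov`), the latent-scale Gaussian
#'   (`latent`), `free_energy` (nats), the noise log-precision `h` and
#'   noise SD `sigma`, `fitted`, `residuals`, a `convergence` record
#'   (iterations, dF trace, converged flag) and the index map.
#' @seealso [fit_cohort()], [log_group_bayes_factor()],
#'   [bayesian_parameter_average()]
#' @export
dcm_fit <- function(recording, spec, priors = NULL, control = dcm_control()) {
  stopifnot(inherits(recording, "subject_recording"),
            inherits(spec, "cmc_spec"))
  if (is.null(priors)) priors <- dcm_priors(spec, fit_hemo = control$fit_hemo)
  stopifnot(inherits(priors, "dcm_priors"),
            priors$variant == spec$variant)
  Y <- recording$bold
  if (!all(is.finite(Y))) stop("recording contains non-finite values",
                               call. = FALSE)
  n_scans <- nrow(Y)
  if (n_scans < 60) stop("need at least 60 scans, got ", n_scans,
                         call. = FALSE)
  tr <- recording$tr
  dt <- tr / 16
  duration <- n_scans * tr
  regressors <- boxcar_regressors(duration = duration, dt = dt)
  if (ncol(regressors$values) != ncol(spec$c_mask)) {
    stop("spec expects ", ncol(spec$c_mask), " driver inputs but ",
         ncol(regressors$values), " were generated", call. = FALSE)
  }
  U <- regressors$values
  idx_scan <- scan_row_index(dt, tr, n_scans, n_micro = nrow(U))
  d_idx <- matrix(as.integer(spec$d_triples - 1L), ncol = 3)
  hemo0 <- default_hemodynamics(length(spec$regions))

  yvec <- as.numeric(Y)
  N <- length(yvec)
  idx <- priors$index
  mu0 <- idx$mean
  v0 <- idx$var
  p <- nrow(idx)

  predict_theta <- function(theta) {
    pr <- theta_to_params(theta, spec, priors, hemo = hemo0)
    res <- dcm_forward_cpp(pr$A, pr$C, d_idx, pr$d, U, dt,
                           pr$hemo$kappa, pr$hemo$gamma, pr$hemo$tau,
                           pr$hemo$alpha, pr$hemo$rho, pr$hemo$v0,
                           control$y_bound, TRUE)
    if (res$status != 0) return(NULL)
    as.numeric(res$bold[idx_scan, , drop = FALSE])
  }

  run_from <- function(theta) {
    g <- predict_theta(theta)
    if (is.null(g)) {
      stop("forward model diverged at the initial parameters", call. = FALSE)
    }
    r <- yvec - g
    E <- sum(r^2)
    h <- solve_noise_logprec(E, N, priors$noise$mean, priors$noise$var)
    J <- matrix(0, N, p)
    Fcur <- -Inf
    dF_trace <- numeric(0)
    converged <- FALSE
    iter <- 0

    while (iter < control$max_iter) {
      iter <- iter + 1
      # finite-difference Jacobian of the prediction at theta
      for (j in seq_len(p)) {
        tj <- theta
        tj[j] <- tj[j] + control$fd_step
        gj <- predict_theta(tj)
        if (is.null(gj)) {
          tj[j] <- theta[j] - control$fd_step
          gj <- predict_theta(tj)
          J[, j] <- if (is.null(gj)) 0 else (g - gj) / control$fd_step
        } else {
          J[, j] <- (gj - g) / control$fd_step
        }
      }
      eh <- exp(h)
      P <- eh * crossprod(J) + diag(1 / v0, p)
      cholP <- chol((P + t(P)) / 2)
      logdetP <- 2 * sum(log(diag(cholP)))
      # re-evaluate F under the current Jacobian so candidate comparisons
      # use one consistent Laplace approximation
      Fcur <- free_energy_value(E, h, N, theta, mu0, v0, logdetP,
                                priors$noise$mean, priors$noise$var)
      grad <- eh * crossprod(J, r) - (theta - mu0) / v0
      delta <- backsolve(cholP, forwardsolve(t(cholP), grad))

      accepted <- FALSE
      stp <- 1
      for (half in 0:control$max_halvings) {
        theta_c <- theta + stp * as.numeric(delta)
        g_c <- predict_theta(theta_c)
        if (!is.null(g_c)) {
          r_c <- yvec - g_c
          E_c <- sum(r_c^2)
          h_c <- solve_noise_logprec(E_c, N, priors$noise$mean,
                                     priors$noise$var)
          P_c <- exp(h_c) * crossprod(J) + diag(1 / v0, p)
          ld_c <- 2 * sum(log(diag(chol((P_c + t(P_c)) / 2))))
          F_c <- free_energy_value(E_c, h_c, N, theta_c, mu0, v0, ld_c,
                                   priors$noise$mean, priors$noise$var)
          if (is.finite(F_c) && F_c > Fcur) {
            dF <- F_c - Fcur
            theta <- theta_c; g <- g_c; r <- r_c; E <- E_c; h <- h_c
            Fcur <- F_c
            dF_trace <- c(dF_trace, dF)
            accepted <- TRUE
            if (control$verbose) {
              message(sprintf("iter %d: F = %.3f (dF = %.4f)", iter, Fcur,
                              dF))
            }
            if (dF < control$tol) converged <- TRUE
            break
          }
        }
        stp <- stp / 2
      }
      if (!accepted) {
        # no ascent direction left at this resolution: local optimum
        converged <- TRUE
        break
      }
      if (converged) break
    }

    # Laplace covariance at the accepted optimum, with the Jacobian there
    for (j in seq_len(p)) {
      tj <- theta
      tj[j] <- tj[j] + control$fd_step
      gj <- predict_theta(tj)
      if (is.null(gj)) {
        tj[j] <- theta[j] - control$fd_step
        gj <- predict_theta(tj)
        J[, j] <- if (is.null(gj)) 0 else (g - gj) / control$fd_step
      } else {
        J[, j] <- (gj - g) / control$fd_step
      }
    }
    P <- exp(h) * crossprod(J) + diag(1 / v0, p)
    cholP <- chol((P + t(P)) / 2)
    Fcur <- free_energy_value(E, h, N, theta, mu0, v0,
                              2 * sum(log(diag(cholP))),
                              priors$noise$mean, priors$noise$var)
    Sigma <- chol2inv(cholP)
    list(theta = theta, Sigma = Sigma, F = Fcur, h = h, g = g,
         iterations = iter, dF_trace = dF_trace, converged = converged)
  }

  best <- run_from(mu0)
  if (!is.null(control$multi_start)) {
    ms <- control$multi_start
    starts <- with_seed(ms$seed, {
      lapply(seq_len(ms$n), function(i) mu0 + rnorm(p, sd = sqrt(v0) / 2))
    })
    for (s in starts) {
      cand <- tryCatch(run_from(s), error = function(e) NULL)
      if (!is.null(cand) && cand$F > best$F) best <- cand
    }
  }

  gen <- latent_to_generative(best$theta, best$Sigma, priors)
  fitted <- matrix(best$g, n_scans, ncol(Y), dimnames = dimnames(Y))
  structure(
    list(mean = gen$mean, cov = gen$cov,
         latent = list(mean = setNames(best$theta, idx$name),
                       cov = best$Sigma),
         free_energy = best$F, h = best$h, sigma = exp(-best$h / 2),
         fitted = fitted, residuals = Y - fitted,
         convergence = list(iterations = best$iterations,
                            dF_trace = best$dF_trace,
                            converged = best$converged),
         index = idx, spec = spec, priors = priors, control = control,
         tr = tr, n_scans = n_scans, group = recording$group,
         seed = recording$seed, N = N),
    class = "dcm_fit"
  )
}
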