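#' @export
print.dcm_fit <- function(x, ...) {
  cat("DCM fit (", x$spec$variant, " variant): ", x$n_scans, " scans x ",
      length(x$spec$regions), " regions, TR = ", x$tr, " s\n", sep = "")
  cat("  free energy: ", format(x$free_energy, digits = 6), " nats (",
      x$convergence$iterations, " iterations, ",
      if (x$convergence$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  cat("  noise sd:", signif(x$sigma, 4), "\n")
  d <- x$index$type == "d"
  if (any(d)) {
    cat("  modulatory gains:\n")
    for (k in which(d)) {
      cat(sprintf("    %s = %.3f (sd %.3f)\n", x$index$name[k],
                  x$mean[k], sqrt(x$cov[k, k])))
    }
  }
  invisible(x)
}

#' @export
summary.dcm_fit <- function(object, ...) {
  tab <- data.frame(
    parameter = object$index$name,
    type = object$index$type,
    estimate = as.numeric(object$mean),
    sd = sqrt(diag(object$cov))
  )
  out <- list(table = tab, free_energy = object$free_energy,
              sigma = object$sigma, convergence = object$convergence,
              variant = object$spec$variant)
  class(out) <- "summary.dcm_fit"
  out
}

#' @export
print.summary.dcm_fit <- function(x, ...) {
  cat("Posterior summary,", x$variant, "variant\n")
  cat("free energy:", format(x$free_energy, digits = 6), "nats;",
      "noise sd:", signif(x$sigma, 4), "\n\n")
  show <- x$table[x$table$type %in% c("self", "a", "d", "hemo"), ]
  print(show, row.names = FALSE, digits = 3)
  cat("(", sum(x$table$type == "c"), "driver-weight parameters omitted )\n")
  invisible(x)
}

#' @export
coef.dcm_fit <- function(object, type = NULL, ...) {
  if (is.null(type)) return(object$mean)
  object$mean[object$index$type %in% type]
}

#' @export
vcov.dcm_fit <- function(object, ...) object$cov

#' @export
logLik.dcm_fit <- function(object, ...) {
  structure(object$free_energy, df = nrow(object$index) + 1,
            nobs = object$N, class = "logLik")
}

#' @export
fitted.dcm_fit <- function(object, ...) object$fitted

#' @export
residuals.dcm_fit <- function(object, ...) object$residuals

#' Simulate recordings from a fitted DCM
#'
#' Generates new synthetic recordings from the posterior-mean parameters
#' with Gaussian observation noise at the fitted noise SD.
#'
#' @param object A [dcm_fit()] object.
#' @param nsim Number of recordings.
#' @param seed Seed for the noise draws.
#' @param ... Unused.
#' @return A list of `subject_recording` objects.
#' @export
simulate.dcm_fit <- function(object, nsim = 1, seed = 1, ...) {
  params <- posterior_parameters(object)
  lapply(seq_len(nsim), function(i) {
    generate_subject(params, object$spec, tr = object$tr,
                     n_scans = object$n_scans,
                     seed = as.integer(seed) + i - 1L)
  })
}

#' Posterior-mean parameters as a generative parameter object
#'
#' @param fit A [dcm_fit()] object.
#' @return A [dcm_parameters()] object usable with the generative module.
#' @export
posterior_parameters <- function(fit) {
  stopifnot(inherits(fit, "dcm_fit"))
  pr <- theta_to_params(fit$latent$mean, fit$spec, fit$priors)
  dcm_parameters(pr$A, pr$C, pr$d, fit$spec, hemo = pr$hemo,
                 noise_sd = fit$sigma)
}

#' @export
plot.dcm_fit <- function(x, regions = NULL, ...) {
  rg <- x$spec$regions
  if (is.null(regions)) regions <- rg
  obs <- x$fitted + x$residuals
  t <- (seq_len(x$n_scans) - 1) * x$tr
  old <- graphics::par(mfrow = c(length(regions), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (r in regions) {
    graphics::plot(t, obs[, r], type = "l", col = "grey50",
                   xlab = "time (s)", ylab = r, ...)
    graphics::lines(t, x$fitted[, r], col = "firebrick")
  }
  invisible(x)
}

#' Fit every subject of a cohort under one CMC variant
#'
#' Runs [dcm_fit()] independently on each recording. Per-subject failures
#' are isolated and reported rather than aborting the batch; an all-subject
#' failure aborts with a summary. With `cache_dir` set, each posterior is
#' serialized as JSON after fitting and existing files are loaded instead
#' of refitted, making long batches resumable.
#'
#' @param cohort A [generate_cohort()] object or a list of
#'   `subject_recording`s.
#' @param spec The [cmc_spec()] variant to fit.
#' @param priors,control Passed to [dcm_fit()].
#' @param cache_dir Optional directory for per-subject posterior JSON.
#' @param progress Print one line per subject (default `FALSE`).
#' @return An object of class `dcm_cohort_fit`: `fits` (list, `NULL` where
#'   failed), `errors` (character messages), `groups`, `free_energies`.
#' @export
fit_cohort <- function(cohort, spec, priors = NULL, control = dcm_control(),
                       cache_dir = NULL, progress = FALSE) {
  recordings <- if (inherits(cohort, "dcm_cohort")) cohort$recordings
                else cohort
  if (length(recordings) == 0) stop("empty cohort", call. = FALSE)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  fits <- vector("list", length(recordings))
  errors <- rep(NA_character_, length(recordings))
  for (i in seq_along(recordings)) {
    cache <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("posterior-%03d.json", i))
    }
    if (!is.null(cache) && file.exists(cache)) {
      fits[[i]] <- read_posterior(cache)
    } else {
      # assign via [i] <- list(...) so a NULL result keeps the slot
      fits[i] <- list(tryCatch(
        dcm_fit(recordings[[i]], spec, priors = priors, control = control),
        error = function(e) {
          errors[i] <<- conditionMessage(e)
          NULL
        }
      ))
      if (!is.null(fits[[i]]) && !is.null(cache)) {
        write_posterior(fits[[i]], cache)
      }
    }
    if (progress) {
      message(sprintf("subject %d/%d: %s", i, length(recordings),
                      if (is.null(fits[[i]])) paste("FAILED:", errors[i])
                      else sprintf("F = %.1f", fits[[i]]$free_energy)))
    }
  }
  if (all(vapply(fits, is.null, logical(1)))) {
    stop("all subjects failed to fit; first error: ",
         errors[which(!is.na(errors))[1]], call. = FALSE)
  }
  groups <- vapply(recordings, function(r) {
    if (is.null(r$group)) NA_character_ else r$group
  }, character(1))
  structure(
    list(fits = fits, errors = errors, groups = groups,
         free_energies = vapply(fits, function(f) {
           if (is.null(f)) NA_real_ else f$free_energy
         }, numeric(1)),
         variant = spec$variant),
    class = "dcm_cohort_fit"
  )
}

#' @export
print.dcm_cohort_fit <- function(x, ...) {
  ok <- !vapply(x$fits, is.null, logical(1))
  cat("Cohort fit (", x$variant, " variant): ", sum(ok), "/", length(ok),
      " subjects fitted\n", sep = "")
  if (any(ok)) {
    cat("  free energy range:",
        paste(signif(range(x$free_energies[ok]), 6), collapse = " .. "),
        "nats\n")
  }
  if (any(!ok)) {
    cat("  failures:\n")
    for (i in which(!ok)) cat("   ", i, ":", x$errors[i], "\n")
  }
  invisible(x)
}

#' Serialize a fitted posterior as structured JSON
#'
#' Stores the index map, posterior mean and covariance (generative and
#' latent scale), free energy, noise log-precision and convergence trace.
#' `read_posterior` restores a `dcm_fit` object; the fitted time series are
#' not stored and come back `NULL`.
#'
#' @param fit A [dcm_fit()] object.
#' @param path JSON file path.
#' @return `write_posterior` the path invisibly; `read_posterior` a
#'   `dcm_fit`.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "dcm_fit"))
  obj <- list(
    variant = fit$spec$variant,
    n_regressors = ncol(fit$spec$c_mask),
    fit_hemo = fit$priors$fit_hemo,
    index = fit$index,
    mean = as.numeric(fit$mean),
    cov = fit$cov,
    latent_mean = as.numeric(fit$latent$mean),
    latent_cov = fit$latent$cov,
    free_energy = fit$free_energy,
    h = fit$h,
    convergence = fit$convergence,
    tr = fit$tr, n_scans = fit$n_scans,
    group = fit$group, seed = fit$seed, N = fit$N
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- cmc_spec(obj$variant, n_regressors = obj$n_regressors)
  priors <- dcm_priors(spec, fit_hemo = isTRUE(obj$fit_hemo))
  p <- length(obj$mean)
  structure(
    list(mean = setNames(obj$mean, obj$index$name),
         cov = matrix(obj$cov, p, p,
                      dimnames = list(obj$index$name, obj$index$name)),
         latent = list(mean = setNames(obj$latent_mean, obj$index$name),
                       cov = matrix(obj$latent_cov, p, p)),
         free_energy = obj$free_energy, h = obj$h,
         sigma = exp(-obj$h / 2), fitted = NULL, residuals = NULL,
         convergence = as.list(obj$convergence),
         index = obj$index, spec = spec, priors = priors,
         control = NULL, tr = obj$tr, n_scans = obj$n_scans,
         group = obj$group, seed = obj$seed, N = obj$N),
    class = "dcm_fit"
  )
}
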