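#' Shrinkage priors for a CMC variant
#'
#' Builds the Gaussian prior over the latent parameter vector used by
#' [dcm_fit()]. Off-diagonal fixed connections get zero-mean priors with
#' variance 1/16 and modulatory gains zero-mean priors with variance 1
#' (the convention of the reference DCM software, and wide enough that
#' published gating gains of magnitude 2-4 remain plausible a priori);
#' driver weights get zero-mean priors with variance 1;
#' self-connections are parameterized as
#' a_ii = -exp(latent) to preserve negativity, with latent prior
#' Normal(0, 1/64), i.e. centered on a decay of -1 Hz. The observation
#' noise log-precision carries a Normal(4, 1) hyperprior. When `fit_hemo`
#' is `TRUE`, two additional shared latents scale the hemodynamic transit
#' time and signal decay (tau = 2 exp(latent), kappa = 0.64 exp(latent)),
#' each Normal(0, 1/64).
#'
#' The parameter order is the documented index map: self-connections in
#' region order, then off-diagonal fixed connections (column-major over the
#' mask), then driver weights (column-major), then modulatory gains, then
#' hemodynamic latents. Entries are named `a:<source>-><target>`,
#' `c:<region>|x<k>`, `d:<modulator>|<source>-><target>`.
#'
#' @param spec A [cmc_spec()] object.
#' @param fit_hemo Include hemodynamic scaling latents (default `FALSE`).
#' @return An object of class `dcm_priors`: a data frame `index`
#'   (name, type, row, col, mean, var) plus the noise hyperprior.
#' @export
dcm_priors <- function(spec, fit_hemo = FALSE) {
  stopifnot(inherits(spec, "cmc_spec"))
  rg <- spec$regions
  rows <- list()
  for (i in seq_along(rg)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("a:", rg[i], "->", rg[i]), type = "self",
      row = i, col = i, mean = 0, var = 1 / 64
    )
  }
  off <- which(spec$a_mask == 1 & row(spec$a_mask) != col(spec$a_mask))
  for (k in off) {
    i <- row(spec$a_mask)[k]; j <- col(spec$a_mask)[k]
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("a:", rg[j], "->", rg[i]), type = "a",
      row = i, col = j, mean = 0, var = 1 / 16
    )
  }
  for (k in seq_len(ncol(spec$c_mask))) {
    for (i in seq_len(nrow(spec$c_mask))) {
      if (spec$c_mask[i, k] == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0("c:", rg[i], "|x", k), type = "c",
          row = i, col = k, mean = 0, var = 1
        )
      }
    }
  }
  for (j in seq_len(nrow(spec$d_triples))) {
    tr <- spec$d_triples[j, ]
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("d:", rg[tr[1]], "|", rg[tr[2]], "->", rg[tr[3]]),
      type = "d", row = j, col = NA_integer_, mean = 0, var = 1
    )
  }
  if (fit_hemo) {
    rows[[length(rows) + 1]] <- data.frame(
      name = "hemo:log_tau", type = "hemo", row = NA_integer_,
      col = NA_integer_, mean = 0, var = 1 / 64
    )
    rows[[length(rows) + 1]] <- data.frame(
      name = "hemo:log_kappa", type = "hemo", row = NA_integer_,
      col = NA_integer_, mean = 0, var = 1 / 64
    )
  }
  index <- do.call(rbind, rows)
  rownames(index) <- NULL
  structure(
    list(index = index, noise = list(mean = 4, var = 1),
         variant = spec$variant, fit_hemo = fit_hemo),
    class = "dcm_priors"
  )
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat("DCM priors (", x$variant, " variant): ", nrow(x$index),
      " parameters\n", sep = "")
  print(table(x$index$type))
  cat("noise log-precision ~ Normal(", x$noise$mean, ",", x$noise$var, ")\n")
  invisible(x)
}

# latent theta -> generative-scale quantities (A, C, d gains, hemo table)
theta_to_params <- function(theta, spec, priors,
                            hemo = default_hemodynamics()) {
  idx <- priors$index
  n <- length(spec$regions)
  A <- matrix(0, n, n)
  C <- matrix(0, n, ncol(spec$c_mask))
  d <- numeric(nrow(spec$d_triples))
  for (k in seq_len(nrow(idx))) {
    ty <- idx$type[k]
    if (ty == "self") {
      A[idx$row[k], idx$col[k]] <- -exp(theta[k])
    } else if (ty == "a") {
      A[idx$row[k], idx$col[k]] <- theta[k]
    } else if (ty == "c") {
      C[idx$row[k], idx$col[k]] <- theta[k]
    } else if (ty == "d") {
      d[idx$row[k]] <- theta[k]
    } else if (ty == "hemo") {
      if (idx$name[k] == "hemo:log_tau") hemo$tau <- 2 * exp(theta[k])
      if (idx$name[k] == "hemo:log_kappa") hemo$kappa <- 0.64 * exp(theta[k])
    }
  }
  list(A = A, C = C, d = d, hemo = hemo)
}

# generative-scale posterior mean and delta-method covariance from the
# latent-scale Gaussian
latent_to_generative <- function(theta, Sigma, priors) {
  idx <- priors$index
  mean_gen <- theta
  grad <- rep(1, length(theta))
  self <- idx$type == "self"
  mean_gen[self] <- -exp(theta[self])
  grad[self] <- -exp(theta[self])
  hm <- idx$type == "hemo"
  if (any(hm)) {
    base <- ifelse(idx$name[hm] == "hemo:log_tau", 2, 0.64)
    mean_gen[hm] <- base * exp(theta[hm])
    grad[hm] <- base * exp(theta[hm])
  }
  cov_gen <- Sigma * tcrossprod(grad)
  names(mean_gen) <- idx$name
  dimnames(cov_gen) <- list(idx$name, idx$name)
  list(mean = mean_gen, cov = cov_gen)
}

# the prior itself on the generative scale (delta method at the prior
# mean), used by fixed-effects group averaging
prior_generative <- function(priors) {
  idx <- priors$index
  lt <- latent_to_generative(idx$mean, diag(idx$var, nrow(idx)), priors)
  lt
}
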