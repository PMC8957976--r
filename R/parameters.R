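#' Default balloon-Windkessel hemodynamic constants
#'
#' Per-region constants of the hemodynamic observation model: signal decay
#' `kappa` (1/s), flow autoregulation `gamma` (1/s), mean transit time `tau`
#' (s), vessel stiffness exponent `alpha`, resting oxygen extraction
#' fraction `rho`, and resting venous volume fraction `v0`. The BOLD output
#' nonlinearity uses k1 = 7 rho, k2 = 2, k3 = 2 rho - 0.2.
#'
#' @param n_regions Number of regions (default 5).
#' @return A data frame with one row per region.
#' @export
default_hemodynamics <- function(n_regions = 5) {
  data.frame(
    kappa = rep(0.64, n_regions),
    gamma = rep(0.32, n_regions),
    tau   = rep(2.0, n_regions),
    alpha = rep(0.32, n_regions),
    rho   = rep(0.4, n_regions),
    v0    = rep(0.04, n_regions)
  )
}

#' Assemble one subject's generative DCM parameters
#'
#' Bundles the full generative parameter set: fixed connectivity `a` (5 x 5,
#' Hz; diagonal = self-decay, strictly negative), driver weights `c`
#' (5 x K, Hz per unit input), modulatory gains `d` (one value per
#' modulatory triple of the spec), per-region hemodynamic constants, and the
#' observation noise level. Nonzero entries must respect the spec's masks.
#'
#' @param a 5 x 5 numeric matrix (row = target, column = source).
#' @param c_mat 5 x K numeric matrix of driver weights.
#' @param d Numeric vector of modulatory gains, one per row of
#'   `spec$d_triples` (length 0 for the direct variant).
#' @param spec The [cmc_spec()] the parameters instantiate.
#' @param hemo Hemodynamic constants, as from [default_hemodynamics()].
#' @param noise_sd Observation noise standard deviation in BOLD units, or
#'   `NA` to resolve it from `snr` at generation time.
#' @param snr Target signal-to-noise ratio (temporal signal sd / noise sd)
#'   used when `noise_sd` is `NA`.
#' @return An object of class `dcm_parameters`.
#' @export
dcm_parameters <- function(a, c_mat, d = numeric(0), spec,
                           hemo = default_hemodynamics(),
                           noise_sd = NA_real_, snr = 3) {
  stopifnot(inherits(spec, "cmc_spec"))
  n <- length(spec$regions)
  a <- as.matrix(a); c_mat <- as.matrix(c_mat)
  stopifnot(identical(dim(a), dim(spec$a_mask)),
            nrow(c_mat) == n, ncol(c_mat) == ncol(spec$c_mask),
            length(d) == nrow(spec$d_triples))
  if (any(a[spec$a_mask == 0] != 0)) {
    stop("nonzero entries of a outside the spec's fixed-connection mask",
         call. = FALSE)
  }
  if (any(c_mat[spec$c_mask == 0] != 0)) {
    stop("nonzero entries of c outside the spec's input mask", call. = FALSE)
  }
  if (any(diag(a) >= 0)) {
    stop("self-connections (diagonal of a) must be strictly negative",
         call. = FALSE)
  }
  stopifnot(is.data.frame(hemo), nrow(hemo) == n,
            all(c("kappa", "gamma", "tau", "alpha", "rho", "v0") %in%
                  names(hemo)))
  if (any(hemo$kappa <= 0) || any(hemo$gamma <= 0) || any(hemo$tau <= 0) ||
      any(hemo$v0 <= 0) || any(hemo$alpha <= 0) || any(hemo$alpha >= 1) ||
      any(hemo$rho <= 0) || any(hemo$rho >= 1)) {
    stop("hemodynamic constants out of range: need kappa, gamma, tau, v0 > 0",
         " and alpha, rho in (0, 1)", call. = FALSE)
  }
  dimnames(a) <- dimnames(spec$a_mask)
  structure(
    list(a = a, c = c_mat, d = as.numeric(d), hemo = hemo,
         noise_sd = noise_sd, snr = snr, variant = spec$variant),
    class = "dcm_parameters"
  )
}

#' @export
print.dcm_parameters <- function(x, ...) {
  cat("DCM generative parameters (", x$variant, " variant)\n", sep = "")
  cat("  self-decay (Hz):", paste(signif(diag(x$a), 3), collapse = ", "), "\n")
  if (length(x$d) > 0) {
    cat("  modulatory gains:", paste(signif(x$d, 3), collapse = ", "), "\n")
  }
  cat("  noise sd:",
      if (is.na(x$noise_sd)) paste0("resolved at SNR ", x$snr)
      else signif(x$noise_sd, 3), "\n")
  invisible(x)
}
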