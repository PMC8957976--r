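#' Bayesian parameter averaging over a group of subjects
#'
#' Fixed-effects combination of per-subject Gaussian posteriors into one
#' group posterior: the group precision is the sum of the individual
#' posterior precisions minus (n - 1) times the prior precision (so the
#' shared prior is counted exactly once), and the group mean is the
#' precision-weighted combination
#' `Sigma_g (sum_i P_i mu_i - (n - 1) P_0 mu_0)`.
#' With a single posterior the input is returned unchanged; with n
#' identical posteriors and a vague prior the mean is unchanged and the
#' variance shrinks by 1/n.
#'
#' Posteriors are combined on the generative scale; the prior enters on
#' that scale through the same transformation as the posteriors.
#'
#' @param posteriors List of [dcm_fit()] objects (or lists with `mean` and
#'   `cov`), all with the same index map.
#' @param priors The shared [dcm_priors()] (or a list with `mean`, `cov`
#'   on the generative scale). `NULL` uses the priors stored in the first
#'   fit.
#' @param group Optional group label carried into the result.
#' @return An object of class `bpa_result`: `mean`, `cov`, `sd`
#'   (posterior dispersion per parameter), `n`, `group`, `names`.
#' @export
bayesian_parameter_average <- function(posteriors, priors = NULL,
                                       group = NA_character_) {
  stopifnot(is.list(posteriors), length(posteriors) >= 1)
  posteriors <- Filter(Negate(is.null), posteriors)
  if (length(posteriors) == 0) stop("no posteriors to average",
                                    call. = FALSE)
  nm <- names(posteriors[[1]]$mean)
  for (ps in posteriors) {
    if (!identical(names(ps$mean), nm)) {
      bad <- union(setdiff(names(ps$mean), nm), setdiff(nm, names(ps$mean)))
      stop("posterior index maps differ (mismatched: ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  if (is.null(priors)) priors <- posteriors[[1]]$priors
  pg <- if (inherits(priors, "dcm_priors")) prior_generative(priors)
        else priors
  n <- length(posteriors)
  p <- length(nm)
  P0 <- solve(pg$cov)
  mu0 <- pg$mean
  Psum <- matrix(0, p, p)
  Pmu <- numeric(p)
  for (ps in posteriors) {
    Pi <- solve((ps$cov + t(ps$cov)) / 2)
    Psum <- Psum + Pi
    Pmu <- Pmu + Pi %*% ps$mean
  }
  Pg <- Psum - (n - 1) * P0
  Pg <- (Pg + t(Pg)) / 2
  ev <- eigen(Pg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("combined group precision not positive definite (min eigenvalue ",
         format(min(ev), digits = 3), "); posteriors may be wider than ",
         "the prior", call. = FALSE)
  }
  covg <- solve(Pg)
  covg <- (covg + t(covg)) / 2
  mug <- drop(covg %*% (Pmu - (n - 1) * P0 %*% mu0))
  structure(
    list(mean = setNames(mug, nm), cov = covg,
         sd = setNames(sqrt(diag(covg)), nm), n = n, group = group,
         names = nm),
    class = "bpa_result"
  )
}

#' @export
print.bpa_result <- function(x, ...) {
  cat("Bayesian parameter average",
      if (!is.na(x$group)) paste0("(", x$group, " group)") else "",
      "over", x$n, "subjects\n")
  keep <- grepl("^(a|d):", x$names)
  print(data.frame(parameter = x$names[keep],
                   mu = signif(x$mean[keep], 3),
                   sigma = signif(x$sd[keep], 3)),
        row.names = FALSE)
  invisible(x)
}

#' Directional group-difference tests on averaged parameters
#'
#' For each parameter, the group posteriors are treated as independent
#' Gaussians and the standardized difference
#' `z = (mu_PD - mu_HC) / sqrt(sd_PD^2 + sd_HC^2)` is computed. The
#' one-sided p-value for the alternative M_PD - M_HC < 0 is `Phi(z)` and
#' for M_PD - M_HC > 0 it is `1 - Phi(z)`; the two always sum to one.
#' Equivalently, each p-value is the posterior probability that the sign
#' of the group difference is opposite to the tested direction.
#'
#' @param bpa_pd,bpa_hc [bayesian_parameter_average()] results for the two
#'   groups, with matching parameter sets.
#' @param parameters Optional subset of parameter names to test.
#' @return An object of class `directional_test`: a data frame with
#'   per-parameter group means and dispersions, `z`, `p_less`, `p_greater`.
#' @export
directional_test <- function(bpa_pd, bpa_hc, parameters = NULL) {
  stopifnot(inherits(bpa_pd, "bpa_result"), inherits(bpa_hc, "bpa_result"))
  if (!identical(bpa_pd$names, bpa_hc$names)) {
    stop("parameter sets differ between groups", call. = FALSE)
  }
  nm <- bpa_pd$names
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, nm)
    if (length(missing) > 0) {
      stop("unknown parameters: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    nm <- parameters
  }
  se <- sqrt(bpa_pd$sd[nm]^2 + bpa_hc$sd[nm]^2)
  if (any(se == 0)) {
    stop("zero combined dispersion for ",
         paste(nm[se == 0], collapse = ", "), call. = FALSE)
  }
  z <- (bpa_pd$mean[nm] - bpa_hc$mean[nm]) / se
  tab <- data.frame(
    parameter = nm,
    mu_pd = as.numeric(bpa_pd$mean[nm]), sd_pd = as.numeric(bpa_pd$sd[nm]),
    mu_hc = as.numeric(bpa_hc$mean[nm]), sd_hc = as.numeric(bpa_hc$sd[nm]),
    z = as.numeric(z),
    p_less = as.numeric(pnorm(z)),
    p_greater = as.numeric(1 - pnorm(z))
  )
  rownames(tab) <- NULL
  structure(list(table = tab, n_pd = bpa_pd$n, n_hc = bpa_hc$n),
            class = "directional_test")
}

# report-dialect p-value: two decimals with a "<0.001" floor
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(round(p, 2), format = "f", digits = 2))
}

#' Format a directional test the way group-comparison tables are printed
#'
#' Two-decimal rounding with a `<0.001` floor. Following the sequential
#' testing convention (test the "less" direction first, test "greater"
#' only where "less" is not significant), the untested direction is shown
#' as an em dash when the first test already rejects.
#'
#' @param test A [directional_test()] result.
#' @return A data frame of formatted strings.
#' @export
format_directional_table <- function(test) {
  stopifnot(inherits(test, "directional_test"))
  tab <- test$table
  p_less <- format_p(tab$p_less)
  p_greater <- ifelse(tab$p_less < 0.001, "—",
                      format_p(tab$p_greater))
  data.frame(
    parameter = tab$parameter,
    mu_pd = formatC(tab$mu_pd, format = "fg", digits = 2),
    sd_pd = formatC(tab$sd_pd, format = "fg", digits = 2),
    mu_hc = formatC(tab$mu_hc, format = "fg", digits = 2),
    sd_hc = formatC(tab$sd_hc, format = "fg", digits = 2),
    p_less = p_less, p_greater = p_greater
  )
}

#' @export
print.directional_test <- function(x, ...) {
  cat("Directional group comparison (PD - HC), n =", x$n_pd, "vs",
      x$n_hc, "\n")
  print(format_directional_table(x), row.names = FALSE)
  invisible(x)
}

#' Cross-variant contrast of direct-connection group differences
#'
#' Compares the group difference (PD - HC) of every shared direct
#' connection as estimated under the modulatory variant against the same
#' difference under the direct variant, flagging connections whose sign
#' disagrees between variants — the situation in which accounting for
#' gating changes the interpretation of a group effect.
#'
#' @param bpa_mod_pd,bpa_mod_hc Group averages fitted with the modulatory
#'   variant.
#' @param bpa_dir_pd,bpa_dir_hc Group averages fitted with the direct
#'   variant.
#' @return A data frame with one row per shared off-diagonal fixed
#'   connection: the two group differences and a `sign_disagrees` flag.
#' @export
cross_model_contrast <- function(bpa_mod_pd, bpa_mod_hc, bpa_dir_pd,
                                 bpa_dir_hc) {
  for (b in list(bpa_mod_pd, bpa_mod_hc, bpa_dir_pd, bpa_dir_hc)) {
    stopifnot(inherits(b, "bpa_result"))
  }
  shared <- intersect(
    grep("^a:", bpa_mod_pd$names, value = TRUE),
    grep("^a:", bpa_dir_pd$names, value = TRUE)
  )
  # off-diagonal connections only: drop self-connections a:R->R
  self <- vapply(strsplit(sub("^a:", "", shared), "->", fixed = TRUE),
                 function(x) x[1] == x[2], logical(1))
  shared <- shared[!self]
  diff_mod <- bpa_mod_pd$mean[shared] - bpa_mod_hc$mean[shared]
  diff_dir <- bpa_dir_pd$mean[shared] - bpa_dir_hc$mean[shared]
  out <- data.frame(
    connection = shared,
    diff_modulatory = as.numeric(diff_mod),
    diff_direct = as.numeric(diff_dir),
    sign_disagrees = sign(diff_mod) != sign(diff_dir)
  )
  rownames(out) <- NULL
  out
}
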