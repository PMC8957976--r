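test_that("priors enumerate the masked parameters with shrinkage means", {
  mod <- dcm_priors(cmc_spec("modulatory"))
  dir <- dcm_priors(cmc_spec("direct"))
  expect_equal(sum(mod$index$type == "d"), 2)
  expect_equal(sum(dir$index$type == "d"), 0)
  expect_true("a:BG->PFC" %in% dir$index$name)
  expect_false("a:BG->PFC" %in% mod$index$name)
  offdiag <- mod$index$type %in% c("a", "c", "d")
  expect_true(all(mod$index$mean[offdiag] == 0))
  expect_true(all(mod$index$var > 0))
  # one-parameter difference between the variants, matching the masks
  expect_equal(nrow(mod$index) - nrow(dir$index), 1)
  with_hemo <- dcm_priors(cmc_spec("modulatory"), fit_hemo = TRUE)
  expect_equal(sum(with_hemo$index$type == "hemo"), 2)
})

test_that("a noiseless recording at prior-mean parameters is recovered", {
  spec <- cmc_spec("modulatory")
  priors <- dcm_priors(spec)
  # prior means: zero couplings and drive, self-decay -1 Hz
  a <- diag(-1, 5)
  params <- dcm_parameters(a, matrix(0, 5, 8), c(0, 0), spec, noise_sd = 0)
  rec <- generate_subject(params, spec, n_scans = 80, seed = 1)
  fit <- dcm_fit(rec, spec)
  expect_true(fit$convergence$converged)
  sds <- sqrt(pmax(diag(fit$cov), 1e-12))
  truth <- c(rep(-1, 5), rep(0, nrow(priors$index) - 5))
  expect_true(all(abs(fit$mean - truth) <= 2 * sds + 1e-6))
})

test_that("pure noise shrinks every coupling toward zero", {
  spec <- cmc_spec("modulatory")
  rec <- noise_recording(n_scans = 80, sd = 0.01, seed = 4)
  fit <- dcm_fit(rec, spec)
  priors <- dcm_priors(spec)
  offdiag <- priors$index$type %in% c("a", "d")
  expect_true(all(abs(fit$mean[offdiag]) <
                    sqrt(priors$index$var[offdiag])))
})

test_that("inversion is deterministic and reports a PSD covariance", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  rec <- generate_subject(params, spec, n_scans = 80, seed = 9,
                          group = "PD")
  f1 <- dcm_fit(rec, spec)
  f2 <- dcm_fit(rec, spec)
  expect_identical(f1$mean, f2$mean)
  expect_identical(f1$free_energy, f2$free_energy)
  ev <- eigen((f1$cov + t(f1$cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_true(is.finite(f1$free_energy))
  # latent covariance PSD as well
  evl <- eigen((f1$latent$cov + t(f1$latent$cov)) / 2, symmetric = TRUE,
               only.values = TRUE)$values
  expect_gt(min(evl), -1e-8)
})

test_that("fitted model methods are mutually consistent", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  rec <- generate_subject(params, spec, n_scans = 80, seed = 10)
  fit <- dcm_fit(rec, spec)
  expect_equal(fitted(fit) + residuals(fit), rec$bold,
               ignore_attr = TRUE)
  expect_equal(as.numeric(logLik(fit)), fit$free_energy)
  expect_equal(unname(coef(fit)), unname(fit$mean))
  expect_equal(length(coef(fit, type = "d")), 2)
  expect_equal(dim(vcov(fit)), rep(nrow(fit$index), 2))
  # posterior-mean parameters regenerate a valid recording
  sim <- simulate(fit, nsim = 1, seed = 2)
  expect_s3_class(sim[[1]], "subject_recording")
  expect_equal(dim(sim[[1]]$bold), dim(rec$bold))
  # summary carries the parameter table
  s <- summary(fit)
  expect_equal(nrow(s$table), nrow(fit$index))
})

test_that("recordings that are too short or non-finite are rejected", {
  spec <- cmc_spec("modulatory")
  rec <- noise_recording(n_scans = 40)
  expect_error(dcm_fit(rec, spec), "at least 60 scans")
  rec2 <- noise_recording(n_scans = 80)
  rec2$bold[5, 2] <- NA
  expect_error(dcm_fit(rec2, spec), "non-finite")
})

test_that("posterior JSON serialization round-trips", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  rec <- generate_subject(params, spec, n_scans = 80, seed = 12,
                          group = "PD")
  fit <- dcm_fit(rec, spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior(fit, path)
  back <- read_posterior(path)
  expect_equal(back$mean, fit$mean, tolerance = 1e-12)
  expect_equal(back$cov, fit$cov, tolerance = 1e-12)
  expect_equal(back$free_energy, fit$free_energy, tolerance = 1e-12)
  expect_equal(back$spec$variant, "modulatory")
  expect_equal(back$group, "PD")
})

test_that("cohort fitting isolates failures and is resumable", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  good1 <- generate_subject(params, spec, n_scans = 80, seed = 21)
  good2 <- generate_subject(params, spec, n_scans = 80, seed = 22)
  bad <- noise_recording(n_scans = 40)  # too short: fails validation
  expect_error(fit_cohort(list(), spec), "empty")
  res <- fit_cohort(list(good1, bad, good2), spec)
  expect_null(res$fits[[2]])
  expect_match(res$errors[2], "60 scans")
  expect_true(all(is.finite(res$free_energies[c(1, 3)])))
  # identical recordings give identical posteriors
  res2 <- fit_cohort(list(good1, good1), spec)
  expect_identical(res2$fits[[1]]$mean, res2$fits[[2]]$mean)
  # cache makes refits load from disk
  cache <- withr::local_tempdir()
  r1 <- fit_cohort(list(good1), spec, cache_dir = cache)
  expect_true(file.exists(file.path(cache, "posterior-001.json")))
  r2 <- fit_cohort(list(good1), spec, cache_dir = cache)
  expect_equal(r2$fits[[1]]$free_energy, r1$fits[[1]]$free_energy)
  # an all-failure cohort aborts with a summary
  expect_error(fit_cohort(list(bad, bad), spec), "all subjects failed")
})

test_that("optional hemodynamic latents are estimated when requested", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  rec <- generate_subject(params, spec, n_scans = 80, seed = 31)
  fit <- dcm_fit(rec, spec, control = dcm_control(fit_hemo = TRUE,
                                                  max_iter = 16))
  hm <- fit$index$type == "hemo"
  expect_equal(sum(hm), 2)
  # reported on the generative scale: transit time near 2 s, decay near
  # 0.64 1/s (the generating values)
  expect_equal(unname(fit$mean["hemo:log_tau"]), 2, tolerance = 0.5)
  expect_equal(unname(fit$mean["hemo:log_kappa"]), 0.64, tolerance = 0.5)
  expect_true(is.finite(fit$free_energy))
})

test_that("the generating variant wins the evidence comparison", {
  # planted gating gains of 1.0 at SNR 3: the modulatory fit should beat
  # the direct fit on the same recording for most seeds
  spec <- cmc_spec("modulatory")
  specd <- cmc_spec("direct")
  prof <- group_profile("PD", spec)
  wins <- 0
  for (s in 1:10) {
    params <- draw_subject_parameters(prof, spec, seed = s,
                                      jitter_scale = 0)
    params$d <- c(1.0, 1.0)
    rec <- generate_subject(params, spec, n_scans = 120, seed = s)
    fm <- dcm_fit(rec, spec)
    fd <- dcm_fit(rec, specd)
    wins <- wins + (fm$free_energy > fd$free_energy)
  }
  expect_gte(wins, 8)
})
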