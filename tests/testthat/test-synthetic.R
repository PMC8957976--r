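test_that("group profiles carry the published group means", {
  spec <- cmc_spec("modulatory")
  pd <- group_profile("PD", spec)
  hc <- group_profile("HC", spec)
  expect_equal(pd$d_mean, c(0.24, -1.59))
  expect_equal(hc$d_mean, c(-3.84, -2.39))
  expect_equal(pd$d_sd, c(0.11, 0.31))
  expect_equal(hc$d_sd, c(0.02, 0.56))
  expect_equal(pd$a_mean["MC", "SENS"], -0.16)   # SENS to MC
  expect_equal(hc$a_mean["MC", "SENS"], 0.11)
  expect_equal(pd$a_mean["MTL", "PFC"], 0.28)    # PFC to MTL
  expect_equal(hc$a_mean["MTL", "PFC"], 0.46)
  expect_equal(pd$a_mean["PFC", "BG"], 0)        # no BG->PFC when gating
  dirspec <- cmc_spec("direct")
  pdd <- group_profile("PD", dirspec)
  expect_equal(length(pdd$d_mean), 0)
  expect_gt(pdd$a_mean["PFC", "BG"], 0)
})

test_that("subject draws are deterministic and respect jitter scaling", {
  spec <- cmc_spec("modulatory")
  prof <- group_profile("PD", spec)
  p0 <- draw_subject_parameters(prof, spec, seed = 11, jitter_scale = 0)
  expect_equal(p0$a, prof$a_mean, ignore_attr = TRUE)
  expect_equal(p0$c, prof$c_mean, ignore_attr = TRUE)
  expect_equal(p0$d, prof$d_mean)
  p1 <- draw_subject_parameters(prof, spec, seed = 12)
  p2 <- draw_subject_parameters(prof, spec, seed = 12)
  expect_identical(p1, p2)
  p3 <- draw_subject_parameters(prof, spec, seed = 13)
  expect_false(identical(p1$d, p3$d))
  expect_true(all(diag(p1$a) < 0))
  # draws leave the caller's RNG stream alone
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(draw_subject_parameters(prof, spec, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("subject generation adds calibrated observation noise", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  noiseless <- params
  noiseless$noise_sd <- 0
  rec0 <- generate_subject(noiseless, spec, n_scans = 240, seed = 3)
  expect_equal(rec0$noise_sd, 0)
  # the noiseless recording equals the forward simulation sampled at scans
  bx <- boxcar_regressors(duration = 600, dt = 2.5 / 16)
  traj <- simulate_neural(params, bx, 600)
  bold <- simulate_bold(traj, params)
  direct <- sample_to_scans(bold, 2.5 / 16, 2.5, 240)
  # joint and two-stage integration agree to well below the noise floor
  expect_lt(max(abs(rec0$bold - direct$bold)), 1e-4)
  # NA noise resolves to signal sd / snr and matches empirically
  rec <- generate_subject(params, spec, n_scans = 240, seed = 3)
  expect_equal(dim(rec$bold), c(240, 5))
  expect_equal(rec$noise_sd, mean(apply(rec0$bold, 2, sd)) / 3)
  resid <- rec$bold - rec0$bold
  expect_equal(sd(as.numeric(resid)), rec$noise_sd, tolerance = 0.05)
})

test_that("cohorts reproduce the study's group sizes and determinism", {
  spec <- cmc_spec("modulatory")
  co <- generate_cohort(n_pd = 3, n_hc = 2, master_seed = 5, spec = spec,
                        n_scans = 80)
  expect_equal(nrow(co$manifest), 5)
  expect_equal(co$manifest$group, c("PD", "PD", "PD", "HC", "HC"))
  co2 <- generate_cohort(n_pd = 3, n_hc = 2, master_seed = 5, spec = spec,
                         n_scans = 80)
  expect_identical(lapply(co$recordings, `[[`, "bold"),
                   lapply(co2$recordings, `[[`, "bold"))
  co3 <- generate_cohort(n_pd = 0, n_hc = 2, master_seed = 5, spec = spec,
                         n_scans = 80)
  expect_true(all(co3$manifest$group == "HC"))
  expect_error(generate_cohort(n_pd = 0, n_hc = 0, master_seed = 1,
                               spec = spec))
})

test_that("truth parameters concentrate on the profile means as n grows", {
  spec <- cmc_spec("modulatory")
  prof <- group_profile("PD", spec)
  n <- 200
  d1 <- vapply(seq_len(n), function(s) {
    draw_subject_parameters(prof, spec, seed = 1000 + s)$d[1]
  }, numeric(1))
  expect_lt(abs(mean(d1) - prof$d_mean[1]), 3 * prof$d_sd[1] / sqrt(n))
})

test_that("PD and HC gating distributions are disjoint at default jitter", {
  spec <- cmc_spec("modulatory")
  prof_pd <- group_profile("PD", spec)
  prof_hc <- group_profile("HC", spec)
  d_pd <- vapply(1:50, function(s) {
    draw_subject_parameters(prof_pd, spec, seed = s)$d[1]
  }, numeric(1))
  d_hc <- vapply(1:50, function(s) {
    draw_subject_parameters(prof_hc, spec, seed = s)$d[1]
  }, numeric(1))
  expect_gt(min(d_pd), max(d_hc))
})

test_that("recordings and cohorts round-trip through TSV + sidecar", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  rec <- generate_subject(params, spec, n_scans = 80, seed = 2,
                          group = "PD")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$bold, rec$bold, tolerance = 1e-12)
  expect_equal(back$tr, rec$tr)
  expect_equal(back$group, "PD")
  expect_equal(back$truth$a, rec$truth$a, tolerance = 1e-12)
  expect_equal(back$truth$d, rec$truth$d, tolerance = 1e-12)

  co <- generate_cohort(n_pd = 1, n_hc = 1, master_seed = 2, spec = spec,
                        n_scans = 80)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  sub1 <- read_recording(file.path(dir, "sub-001.tsv"))
  expect_equal(sub1$bold, co$recordings[[1]]$bold, tolerance = 1e-12)
})
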