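test_that("the state equation reduces correctly in its linear limits", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  y <- c(0.3, -0.2, 0.1, 0.4, -0.1)
  x <- rep(0, 8)
  # with x = 0 and d zeroed the derivative is A y exactly
  p0 <- params
  p0$d <- c(0, 0)
  expect_equal(neural_derivative(y, x, p0, spec),
               unname(drop(params$a %*% y)))
  # with y = 0 the derivative is C x exactly
  x1 <- runif(8)
  expect_equal(neural_derivative(rep(0, 5), x1, params, spec),
               unname(drop(params$c %*% x1)))
  expect_error(neural_derivative(c(y[-5], NaN), x, params, spec),
               "non-finite")
})

test_that("the bilinear term matches a hand evaluation and a loop oracle", {
  spec <- cmc_spec("modulatory")
  g <- 0.7
  a <- matrix(0, 5, 5); diag(a) <- -1e-9  # validator needs negative diag
  cmat <- matrix(0, 5, 8)
  params <- dcm_parameters(a, cmat, d = c(g, 0), spec)
  y <- c(0, 0, 2, 3, 0)  # y_BG = 2, y_MTL = 3
  got <- neural_derivative(y, rep(0, 8), params, spec)
  # BG modulates MTL->PFC: PFC receives y_BG * g * y_MTL = 2 g 3
  expect_equal(got[2], 2 * g * 3, tolerance = 1e-8)
  expect_equal(got[-2], rep(0, 4), tolerance = 1e-8)
  # general case against the elementwise loop oracle
  params2 <- pd_params(spec)
  y2 <- c(0.3, -0.2, 0.15, 0.25, -0.35)
  x2 <- runif(8, -1, 1)
  expect_equal(
    neural_derivative(y2, x2, params2, spec),
    neural_deriv_oracle(y2, x2, params2$a, params2$c, spec$d_triples,
                        params2$d),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("neural integration holds fixed points and steady states", {
  spec <- cmc_spec("modulatory", n_regressors = 1)
  # all-zero input from zero state stays at the fixed point
  a <- diag(-0.5, 5)
  params <- dcm_parameters(a, matrix(0, 5, 1), c(0, 0), spec,
                           noise_sd = 0)
  reg0 <- const_input_set(0, duration = 100, dt = 0.05)
  traj <- simulate_neural(params, reg0, 100)
  expect_true(all(traj$y == 0))
  # constant unit input, c = 1 on one region: steady state -a^-1 c = 2
  cmat <- matrix(0, 5, 1); cmat[1, 1] <- 1
  params2 <- dcm_parameters(a, cmat, c(0, 0), spec, noise_sd = 0)
  reg1 <- const_input_set(1, duration = 60, dt = 0.05)
  traj2 <- simulate_neural(params2, reg1, 60)
  expect_equal(traj2$y[nrow(traj2$y), 1], 2.0, tolerance = 1e-3)
  expect_equal(max(abs(traj2$y[, 3])), 0, tolerance = 1e-9)
})

test_that("step-size refinement leaves the endpoint unchanged", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  dt <- 2.5 / 16
  bx1 <- boxcar_regressors(duration = 150, dt = dt)
  bx2 <- boxcar_regressors(duration = 150, dt = dt / 2)
  t1 <- simulate_neural(params, bx1, 150)
  t2 <- simulate_neural(params, bx2, 150)
  # compare the final shared time stamp (rows are offset by dt/2)
  expect_lt(max(abs(t1$y[nrow(t1$y), ] - t2$y[2 * nrow(t1$y) - 1, ])),
            1e-3)
  # and the whole trajectory on the shared grid
  expect_lt(max(abs(t1$y - t2$y[seq(1, nrow(t2$y), 2), ])), 1e-3)
})

test_that("doubling the drive doubles the trajectory when d = 0", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  params$d <- c(0, 0)
  params2 <- params
  params2$c <- 2 * params$c
  bx <- boxcar_regressors(duration = 150, dt = 2.5 / 16)
  t1 <- simulate_neural(params, bx, 150)
  t2 <- simulate_neural(params2, bx, 150)
  expect_equal(t2$y, 2 * t1$y, tolerance = 1e-9)
})

test_that("resting neural input produces identically zero BOLD", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  neural <- structure(list(y = matrix(0, 400, 5), dt = 0.1),
                      class = "neural_trajectory")
  bold <- simulate_bold(neural, params)
  expect_true(all(bold == 0))
})

test_that("the balloon response lags the neural impulse", {
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  dt <- 0.1
  y <- matrix(0, 300, 5)
  y[11:20, 1] <- 1  # 1 s neural burst at t = 1 s
  y[11:20, 2] <- 1  # identical trace in a second region
  neural <- structure(list(y = y, dt = dt), class = "neural_trajectory")
  bold <- simulate_bold(neural, params)
  neural_peak <- which.max(y[, 1]) * dt
  bold_peak <- which.max(bold[, 1]) * dt
  expect_gt(bold_peak, neural_peak + 2)
  # identical neural traces and constants give identical BOLD columns
  expect_equal(bold[, 1], bold[, 2])
})

test_that("scan sampling has the documented shape and identities", {
  dt <- 2.5 / 16
  bold <- matrix(rnorm(3840 * 5), 3840, 5)
  rec <- sample_to_scans(bold, dt, tr = 2.5, n_scans = 240)
  expect_s3_class(rec, "subject_recording")
  expect_equal(dim(rec$bold), c(240, 5))
  expect_equal(colnames(rec$bold), cmc_regions())
  expect_equal(rec$bold[5, ], bold[4 * 16 + 1, ], ignore_attr = TRUE)
  # tr equal to dt: identity on rows
  rec2 <- sample_to_scans(bold[1:100, ], dt, tr = dt, n_scans = 100)
  expect_equal(rec2$bold, bold[1:100, ], ignore_attr = TRUE)
  # constant signal stays constant
  rec3 <- sample_to_scans(matrix(2.5, 1000, 5), dt, tr = 2.5, n_scans = 60)
  expect_true(all(rec3$bold == 2.5))
  expect_error(sample_to_scans(bold, dt, tr = 2.5, n_scans = 500),
               "too short")
})

test_that("divergence raises a structured error naming the parameters", {
  spec <- cmc_spec("modulatory", n_regressors = 1)
  a <- diag(-0.5, 5)
  a[2, 4] <- 3; a[4, 2] <- 3  # strongly unstable pair
  cmat <- matrix(0.5, 5, 1)
  params <- dcm_parameters(a, cmat, c(0, 0), spec)
  reg <- const_input_set(1, duration = 200, dt = 0.05)
  err <- tryCatch(simulate_neural(params, reg, 200),
                  dcm_divergence_error = function(e) e)
  expect_s3_class(err, "dcm_divergence_error")
  expect_match(conditionMessage(err), "self-decay")
})

test_that("fixed-step integration agrees with an adaptive reference", {
  skip_if_not_installed("deSolve")
  spec <- cmc_spec("modulatory")
  params <- pd_params(spec)
  dt <- 2.5 / 16
  bx <- boxcar_regressors(duration = 150, dt = dt)
  traj <- simulate_neural(params, bx, 150)
  bold <- simulate_bold(traj, params)
  ref <- desolve_forward(params, spec, bx$values, dt)
  expect_lt(max(abs(traj$y - ref$neural)), 1e-3)
  expect_lt(max(abs(bold - ref$bold)), 1e-3)
})
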