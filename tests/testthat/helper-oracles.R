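# Independent oracles and small fixture builders shared across tests.

# PD-profile generative parameters (jitter 0 reproduces the profile means)
pd_params <- function(spec = cmc_spec("modulatory"), jitter_scale = 0,
                      seed = 1) {
  draw_subject_parameters(group_profile("PD", spec), spec, seed = seed,
                          jitter_scale = jitter_scale)
}

hc_params <- function(spec = cmc_spec("modulatory"), jitter_scale = 0,
                      seed = 1) {
  draw_subject_parameters(group_profile("HC", spec), spec, seed = seed,
                          jitter_scale = jitter_scale)
}

# a constant-input "regressor set" for closed-form steady-state checks
const_input_set <- function(value = 1, duration, dt, K = 1) {
  T_ <- round(duration / dt)
  structure(
    list(values = matrix(value, T_, K), dt = dt,
         times = seq(0, duration - dt, by = dt),
         frequencies = rep(NA_real_, K), phases = rep(NA_real_, K)),
    class = "boxcar_set"
  )
}

# elementwise-loop evaluation of A y + C x + sum_i y_i D(i) y, written
# independently of the package's matrix formulation
neural_deriv_oracle <- function(y, x, a, cmat, d_triples, d_gains) {
  dy <- numeric(length(y))
  for (i in seq_along(y)) {
    for (j in seq_along(y)) dy[i] <- dy[i] + a[i, j] * y[j]
    for (k in seq_along(x)) dy[i] <- dy[i] + cmat[i, k] * x[k]
  }
  for (r in seq_len(nrow(d_triples))) {
    tr <- d_triples[r, ]
    dy[tr[3]] <- dy[tr[3]] + y[tr[1]] * d_gains[r] * y[tr[2]]
  }
  dy
}

# adaptive high-accuracy reference integrator (deSolve::lsoda) for the
# joint neural + hemodynamic system on the natural scale, with the
# piecewise-constant inputs applied bin by bin
desolve_forward <- function(params, spec, U, dt) {
  n <- nrow(params$a)
  hemo <- params$hemo
  d_tr <- spec$d_triples
  deriv <- function(t, state, u) {
    y <- state[1:n]; s <- state[n + 1:n]; f <- state[2 * n + 1:n]
    v <- state[3 * n + 1:n]; q <- state[4 * n + 1:n]
    dy <- drop(params$a %*% y + params$c %*% u)
    for (r in seq_len(nrow(d_tr))) {
      dy[d_tr[r, 3]] <- dy[d_tr[r, 3]] +
        y[d_tr[r, 1]] * params$d[r] * y[d_tr[r, 2]]
    }
    fv <- v^(1 / hemo$alpha)
    ef <- 1 - (1 - hemo$rho)^(1 / f)
    list(c(dy,
           y - hemo$kappa * s - hemo$gamma * (f - 1),
           s,
           (f - fv) / hemo$tau,
           (f * ef / hemo$rho - fv * q / v) / hemo$tau))
  }
  state <- c(rep(0, 2 * n), rep(1, 3 * n))
  T_ <- nrow(U)
  out_y <- matrix(0, T_, n)
  out_bold <- matrix(0, T_, n)
  k1 <- 7 * hemo$rho; k3 <- 2 * hemo$rho - 0.2
  for (t in seq_len(T_)) {
    out_y[t, ] <- state[1:n]
    v <- state[3 * n + 1:n]; q <- state[4 * n + 1:n]
    out_bold[t, ] <- hemo$v0 * (k1 * (1 - q) + 2 * (1 - q / v) +
                                  k3 * (1 - v))
    if (t == T_) break
    sol <- deSolve::lsoda(state, c(0, dt), deriv, parms = U[t, ],
                          rtol = 1e-10, atol = 1e-12)
    state <- as.numeric(sol[2, -1])
  }
  list(neural = out_y, bold = out_bold)
}

# quick white-noise recording
noise_recording <- function(n_scans = 120, sd = 1, seed = 1, tr = 2.5) {
  set.seed(seed)
  bold <- matrix(rnorm(n_scans * 5, sd = sd), n_scans, 5)
  colnames(bold) <- cmc_regions()
  structure(
    list(bold = bold, tr = tr, regions = cmc_regions(),
         group = NA_character_, seed = seed, truth = NULL, noise_sd = sd),
    class = "subject_recording"
  )
}

# synthetic single-parameter "posterior" in the shape BPA consumes
toy_posterior <- function(mean, var, name = "theta") {
  list(mean = setNames(mean, name),
       cov = matrix(var, 1, 1, dimnames = list(name, name)))
}

toy_prior <- function(var = 1e8, name = "theta") {
  list(mean = setNames(0, name),
       cov = matrix(var, 1, 1, dimnames = list(name, name)))
}
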