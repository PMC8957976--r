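test_that("parameter averaging follows the precision-weighting closed forms", {
  # a single posterior is returned unchanged
  p1 <- toy_posterior(1.5, 0.2)
  one <- bayesian_parameter_average(list(p1), priors = toy_prior())
  expect_equal(unname(one$mean), 1.5, tolerance = 1e-6)
  expect_equal(unname(one$sd^2), 0.2, tolerance = 1e-4)
  # Normal(1, 1) and Normal(3, 1) under a vague prior: mean 2, var 0.5
  two <- bayesian_parameter_average(
    list(toy_posterior(1, 1), toy_posterior(3, 1)), priors = toy_prior())
  expect_equal(unname(two$mean), 2, tolerance = 1e-6)
  expect_equal(unname(two$sd^2), 0.5, tolerance = 1e-4)
  # n identical posteriors: same mean, variance divided by n
  n <- 5
  many <- bayesian_parameter_average(
    replicate(n, toy_posterior(0.7, 0.3), simplify = FALSE),
    priors = toy_prior())
  expect_equal(unname(many$mean), 0.7, tolerance = 1e-6)
  expect_equal(unname(many$sd^2), 0.3 / n, tolerance = 1e-4)
})

test_that("averaging removes the multiply-counted prior exactly", {
  # two posteriors that each combine a known prior with one observation:
  # BPA must reproduce the posterior from the prior and both observations
  prior <- toy_prior(var = 2)
  obs_prec <- c(1.5, 0.5)
  obs_mean <- c(1, -2)
  posts <- lapply(1:2, function(i) {
    prec <- 1 / 2 + obs_prec[i]
    toy_posterior(obs_prec[i] * obs_mean[i] / prec, 1 / prec)
  })
  got <- bayesian_parameter_average(posts, priors = prior)
  prec_all <- 1 / 2 + sum(obs_prec)
  expect_equal(unname(got$mean), sum(obs_prec * obs_mean) / prec_all,
               tolerance = 1e-8)
  expect_equal(unname(got$sd^2), 1 / prec_all, tolerance = 1e-8)
})

test_that("averaging rejects mismatched maps and non-PD precisions", {
  pa <- toy_posterior(1, 1, name = "alpha")
  pb <- toy_posterior(1, 1, name = "beta")
  expect_error(bayesian_parameter_average(list(pa, pb),
                                          priors = toy_prior()),
               "index maps differ")
  # posteriors wider than the prior make the combined precision indefinite
  wide <- toy_posterior(0, 10)
  expect_error(
    bayesian_parameter_average(list(wide, wide),
                               priors = toy_prior(var = 1)),
    "not positive definite")
})

test_that("directional tests convert standardized differences to tails", {
  mk_bpa <- function(mu, sd, n = 10, group = "PD") {
    structure(list(mean = setNames(mu, "par"),
                   cov = matrix(sd^2, 1, 1), sd = setNames(sd, "par"),
                   n = n, group = group, names = "par"),
              class = "bpa_result")
  }
  # identical groups: both tails are one half
  t0 <- directional_test(mk_bpa(0.4, 0.1), mk_bpa(0.4, 0.1, group = "HC"))
  expect_equal(t0$table$p_less, 0.5)
  expect_equal(t0$table$p_greater, 0.5)
  # tails always sum to one and swap under group exchange
  t1 <- directional_test(mk_bpa(0.24, 0.11), mk_bpa(-0.5, 0.2,
                                                    group = "HC"))
  expect_equal(t1$table$p_less + t1$table$p_greater, 1)
  t2 <- directional_test(mk_bpa(-0.5, 0.2), mk_bpa(0.24, 0.11,
                                                   group = "HC"))
  expect_equal(t1$table$p_less, t2$table$p_greater)
  expect_equal(t1$table$p_greater, t2$table$p_less)
  expect_equal(t1$table$z, -t2$table$z)
  # degenerate dispersion is an error
  expect_error(directional_test(mk_bpa(1, 0), mk_bpa(1, 0, group = "HC")),
               "zero combined dispersion")
})

test_that("report formatting uses the two-decimal dialect with a floor", {
  expect_equal(cmcdcm:::format_p(c(0.0004, 0.106, 0.5, 0.999)),
               c("<0.001", "0.11", "0.50", "1.00"))
})

test_that("cross-variant contrast flags sign disagreements", {
  nm <- c("a:SENS->MC", "a:MC->MC")
  mk <- function(vals) {
    structure(list(mean = setNames(vals, nm),
                   cov = diag(0.01, 2), sd = setNames(rep(0.1, 2), nm),
                   n = 5, group = "PD", names = nm),
              class = "bpa_result")
  }
  # identical inputs for both variants: no disagreements
  same <- cross_model_contrast(mk(c(0.3, -1)), mk(c(0.1, -1)),
                               mk(c(0.3, -1)), mk(c(0.1, -1)))
  expect_false(any(same$sign_disagrees))
  # self-connections are excluded from the contrast
  expect_equal(same$connection, "a:SENS->MC")
  # +0.1 under one variant, -0.1 under the other: flagged
  flip <- cross_model_contrast(mk(c(0.2, 0)), mk(c(0.1, 0)),
                               mk(c(0.1, 0)), mk(c(0.2, 0)))
  expect_true(flip$sign_disagrees[1])
  expect_equal(flip$diff_modulatory[1], 0.1)
  expect_equal(flip$diff_direct[1], -0.1)
})
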