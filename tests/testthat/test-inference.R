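single_instrument_dataset <- function(k = 8, seed = 99) {
  set.seed(seed)
  delta <- rnorm(k, -10, 2)
  se <- runif(k, 1.5, 3)
  data.frame(trial_id = sprintf("s%02d", seq_len(k)), arm_index = 1,
             n_control = 80, n_arm = 80, instrument = "A",
             mean_diff = rnorm(k, delta, se), se = se,
             pooled_sd = 20, basis = "unknown",
             stringsAsFactors = FALSE)
}

test_that("sampling is deterministic given the seed", {
  ds <- toy_dataset()
  spec <- model_spec("fixed_mapping", reference = "A")
  cfg <- mcmc_config(2, 200, 200, seed = 5)
  f1 <- run_mcmc(spec, ds, cfg)
  f2 <- run_mcmc(spec, ds, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(spec, ds, mcmc_config(2, 200, 200, seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("single-instrument model matches an independent Gibbs sampler", {
  # with one instrument the model is ordinary normal-normal
  # random-effects meta-analysis; cross-check against a conjugate
  # Gibbs implementation that shares no code with the package sampler
  dat <- single_instrument_dataset()
  ds <- load_trials(dat)
  fit <- run_mcmc(model_spec("fixed_mapping", reference = "A"), ds,
                  mcmc_config(4, 4000, 4000, seed = 21))
  rep <- fit_report(fit)

  set.seed(22)
  ref <- ref_meta_gibbs(dat$mean_diff, dat$se, n_iter = 12000)

  expect_equal(rep$mean[rep$parameter == "mu"], mean(ref[, "mu"]),
               tolerance = 0.05)
  expect_equal(rep$sd[rep$parameter == "mu"], sd(ref[, "mu"]),
               tolerance = 0.08)
  expect_equal(rep$median[rep$parameter == "sigma"],
               median(ref[, "sigma"]), tolerance = 0.12)
})

test_that("convergence diagnostic matches the split-chain formula", {
  ds <- toy_dataset()
  fit <- run_mcmc(model_spec("fixed_mapping", reference = "A"), ds,
                  mcmc_config(3, 500, 400, seed = 9))
  rhat <- gelman_rubin(fit)
  for (p in c("mu", "sigma")) {
    expect_equal(unname(rhat[p]),
                 rhat_ref(lapply(fit$draws, function(d) d[, p])),
                 tolerance = 1e-8)
  }

  # identical well-mixed chains sit at 1; separated chains blow up
  set.seed(1)
  m <- matrix(rnorm(2000 * ncol(fit$draws[[1]])), 2000,
              dimnames = list(NULL, colnames(fit$draws[[1]])))
  same <- structure(list(draws = list(m, m), par_names = colnames(m)),
                    class = "posterior_samples")
  expect_true(all(abs(gelman_rubin(same) - 1) < 0.05))
  shifted <- structure(list(draws = list(m, m + 50),
                            par_names = colnames(m)),
                       class = "posterior_samples")
  expect_gt(gelman_rubin(shifted)[["mu"]], 2)
  one <- structure(list(draws = list(m), par_names = colnames(m)),
                   class = "posterior_samples")
  expect_error(gelman_rubin(one), "2 chains")
})

test_that("residual deviance is the posterior mean discrepancy", {
  # exact-fit draws give deviance zero
  dat <- single_instrument_dataset(k = 3)
  ds <- load_trials(dat)
  spec <- suppressWarnings(model_spec("ratios_one", reference = "A"))
  md <- mapmeta:::build_model_data(spec, ds)
  draws <- matrix(rep(c(-10, 1, dat$mean_diff), each = 5), nrow = 5)
  colnames(draws) <- md$par_names
  fake <- structure(list(draws = list(draws), par_names = md$par_names,
                         model = md),
                    class = "posterior_samples")
  expect_equal(residual_deviance(fake), 0, tolerance = 1e-12)

  # hand-computed quadratic form for off-target draws
  draws2 <- draws
  draws2[, 3:5] <- draws2[, 3:5] + 1  # shift every trial effect by 1
  fake$draws <- list(draws2)
  expect_equal(residual_deviance(fake), sum(1 / dat$se^2), tolerance = 1e-10)

  # agreement with the sampler's own accumulation on a real fit
  fit <- run_mcmc(model_spec("fixed_mapping", reference = "A"),
                  toy_dataset(), mcmc_config(2, 500, 500, seed = 13))
  expect_equal(residual_deviance(fit), mean(unlist(fit$resdev)),
               tolerance = 1e-8)
})

test_that("fit report summarises the pooled draws", {
  fit <- run_mcmc(model_spec("fixed_mapping", reference = "A"),
                  toy_dataset(), mcmc_config(2, 800, 500, seed = 17))
  rep <- suppressWarnings(fit_report(fit))
  pooled <- do.call(rbind, fit$draws)
  for (p in c("mu", "sigma", "beta[B]")) {
    x <- pooled[, p]
    row <- rep[rep$parameter == p, ]
    expect_equal(row$mean, mean(x), tolerance = 1e-12)
    expect_equal(row$median, median(x), tolerance = 1e-12)
    # brute-force quantiles from the sorted array
    xs <- sort(x)
    expect_equal(row$lower, unname(quantile(xs, 0.025)), tolerance = 1e-12)
    expect_equal(row$upper, unname(quantile(xs, 0.975)), tolerance = 1e-12)
    expect_lte(row$lower, row$median)
    expect_lte(row$median, row$upper)
  }

  # degenerate all-equal draws: point summaries, zero-width interval
  md <- fit$model
  const <- matrix(rep(c(-2, 1, 0.5, -2, -2), each = 4), nrow = 4)
  colnames(const) <- fit$par_names
  fake <- structure(list(draws = list(const, const),
                         par_names = fit$par_names, model = md,
                         spec = fit$spec),
                    class = "posterior_samples")
  rep0 <- fit_report(fake)
  mu0 <- rep0[rep0$parameter == "mu", ]
  expect_equal(mu0$mean, -2)
  expect_equal(mu0$median, -2)
  expect_equal(mu0$sd, 0)
  expect_equal(mu0$upper - mu0$lower, 0)
})

test_that("scalar blocks adapt toward the target acceptance rate", {
  fit <- run_mcmc(model_spec("fixed_mapping"), social_anxiety_data(),
                  mcmc_config(2, 3000, 1000, seed = 31))
  rates <- fit$accept_rate
  expect_true(all(rates > 0.15 & rates < 0.75, na.rm = TRUE))
})

test_that("the between-trials SD prior knob shifts sigma as expected", {
  ds <- social_anxiety_data()
  fits <- lapply(c("uniform_var", "uniform_sd"), function(pr) {
    fit_report(run_mcmc(
      model_spec("fixed_mapping", priors = prior_spec(sigma_prior = pr)),
      ds, mcmc_config(4, 3000, 3000, seed = 41)))
  })
  s <- vapply(fits, function(r) r$median[r$parameter == "sigma"], numeric(1))
  # the variance-scale prior weights larger sigma; the shift is a few
  # percent, well above Monte Carlo error at this run length
  expect_gt(s[1], s[2])
  expect_lt(abs(s[1] - s[2]) / s[2], 0.25)
})
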