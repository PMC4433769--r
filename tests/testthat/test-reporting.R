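test_that("mapped effects are the per-draw transformed summaries", {
  fit <- run_mcmc(model_spec("fixed_mapping", reference = "A"),
                  toy_dataset(), mcmc_config(2, 800, 800, seed = 19))
  me <- map_pooled_effects(fit)
  rep <- suppressWarnings(fit_report(fit))

  # reference row equals the raw mu / sigma summaries exactly
  ref_row <- me[me$instrument == "A", ]
  expect_equal(ref_row$effect_mean, rep$mean[rep$parameter == "mu"],
               tolerance = 1e-12)
  expect_equal(ref_row$sd_median, rep$median[rep$parameter == "sigma"],
               tolerance = 1e-12)

  # degenerate ratio draws: linearity of the transformation
  md <- fit$model
  n <- 6
  draws <- cbind(mu = rnorm(n, -10), sigma = rexp(n) + 0.5,
                 `beta[B]` = 2, d1 = rnorm(n), d2 = rnorm(n))
  colnames(draws) <- fit$par_names
  fake <- structure(list(draws = list(draws), par_names = fit$par_names,
                         model = md, spec = fit$spec),
                    class = "posterior_samples")
  me2 <- map_pooled_effects(fake)
  expect_equal(me2$effect_mean[me2$instrument == "B"],
               2 * mean(draws[, "mu"]), tolerance = 1e-12)
  expect_equal(me2$sd_median[me2$instrument == "B"],
               2 * median(draws[, "sigma"]), tolerance = 1e-12)
})

test_that("relative precision is simple arithmetic on the summaries", {
  fake_report <- function(mu_mean, mu_sd, sigma_median) {
    structure(data.frame(parameter = c("mu", "sigma"),
                         mean = c(mu_mean, NA), sd = c(mu_sd, NA),
                         median = c(NA, sigma_median),
                         lower = NA, upper = NA, rhat = NA),
              class = c("fit_report", "data.frame"))
  }
  pt <- relative_precision(list(m = fake_report(-10, 1, 2)))
  expect_equal(pt$effect_to_sd, 10)
  expect_equal(pt$effect_to_between_sd, 5)

  # invariance under rescaling of measurement units
  pt10 <- relative_precision(list(m = fake_report(-100, 10, 20)))
  expect_equal(pt$effect_to_sd, pt10$effect_to_sd)
  expect_equal(pt$effect_to_between_sd, pt10$effect_to_between_sd)

  expect_error(relative_precision(list(bad = fake_report(-10, 0, 2))),
               "zero posterior SD")
})

test_that("rescaling the data leaves the precision ratios invariant", {
  # unit-change invariance needs the prior bounds expressed in the new
  # units too (a tenth of the default upper bound for data scaled down
  # tenfold), and a dataset rich enough to identify sigma
  ds <- social_anxiety_data()
  scaled <- ds$observations
  for (cl in c("mean_diff", "se", "pooled_sd")) {
    scaled[[cl]] <- scaled[[cl]] / 10
  }
  ds10 <- load_trials(scaled, instruments = ds$instruments)
  cfg <- mcmc_config(2, 2000, 2000, seed = 23)
  p1 <- relative_precision(list(a = suppressWarnings(
    run_mcmc(model_spec("fixed_mapping"), ds, cfg))))
  p2 <- relative_precision(list(a = suppressWarnings(
    run_mcmc(model_spec("fixed_mapping",
                        priors = prior_spec(sigma_upper = 5)), ds10, cfg))))
  expect_equal(p1$effect_to_sd, p2$effect_to_sd, tolerance = 0.05)
  expect_equal(p1$effect_to_between_sd, p2$effect_to_between_sd,
               tolerance = 0.05)
})

test_that("range-ratio conversion uses the instrument scale ranges", {
  expect_equal(range_ratio_conversion("LSAS", "CGI-S"), 7 / 144,
               tolerance = 1e-12)
  expect_equal(range_ratio_conversion("LSAS", "LSAS"), 1)
  # composition across an intermediate instrument
  expect_equal(range_ratio_conversion("LSAS", "BSPS") *
                 range_ratio_conversion("BSPS", "SPIN"),
               range_ratio_conversion("LSAS", "SPIN"), tolerance = 1e-12)
  expect_error(range_ratio_conversion("LSAS", "XX"), "XX")
  custom <- data.frame(instrument = c("a", "b"), scale_range = c(NA, 10))
  expect_error(range_ratio_conversion("a", "b", custom), "scale range")
})

test_that("network adjacency dump mirrors the instrument network", {
  ds <- social_anxiety_data()
  adj <- network_adjacency(ds)
  expect_identical(adj, instrument_network(ds)$edges)
  expect_true(all(adj$n_trials >= 1))
})
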