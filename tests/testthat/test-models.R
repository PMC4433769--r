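test_that("derived mappings are transitive", {
  beta <- c("CGI-S" = 0.0445, a = 2, b = 4)
  expect_equal(derived_mapping(beta, "a", "a"), 1)
  expect_equal(derived_mapping(beta, "LSAS", "CGI-S"), 0.0445)
  expect_equal(derived_mapping(beta, "a", "b"), 2)
  expect_equal(derived_mapping(beta, "a", "b") * derived_mapping(beta, "b", "a"),
               1)
  # transitivity through a third instrument
  expect_equal(derived_mapping(beta, "a", "b"),
               derived_mapping(beta, "a", "CGI-S") *
                 derived_mapping(beta, "CGI-S", "b"))
  expect_error(derived_mapping(c(a = 0, b = 1), "a", "b"), "degenerate")
  expect_error(derived_mapping(beta, "a", "zz"), "zz")
})

test_that("expected effects follow the variant-specific mean structure", {
  ds <- toy_dataset()
  t1 <- ds$observations[ds$observations$trial_id == "t1", ]

  # constrained model: every instrument shows the raw trial effect
  sp1 <- suppressWarnings(model_spec("ratios_one", reference = "A"))
  st <- list(mu = -1, sigma = 1, delta = list("t1:1" = -0.45))
  expect_equal(expected_effects(st, sp1, t1), c(-0.45, -0.45))

  # fixed mapping: product of trial effect and basic ratio
  spf <- model_spec("fixed_mapping", reference = "A")
  st <- list(mu = -10, sigma = 2, beta = list(B = 0.0443),
             delta = list("t1:1" = -11.85))
  expect_equal(expected_effects(st, spf, t1),
               c(-11.85, -11.85 * 0.0443), tolerance = 1e-12)

  # random mapping with trial ratios equal to their means collapses to
  # the fixed-mapping mean structure
  spr <- model_spec("random_mapping", reference = "A")
  str <- c(st, list(phi = 0, beta_trial = list("t1:B" = 0.0443)))
  expect_equal(expected_effects(str, spr, t1),
               expected_effects(st, spf, t1), tolerance = 1e-12)
  expect_error(expected_effects(st, spr, t1), "trial-specific")
})

test_that("log prior matches an independent density evaluation", {
  ds <- toy_dataset()
  spec <- model_spec("fixed_mapping", reference = "A",
                     priors = prior_spec(sigma_prior = "uniform_sd"))
  set.seed(1)
  st <- make_state(ds, spec, mu = -8, sigma = 1.5, beta = c(B = 0.1))

  # out-of-support states return -Inf, not an error
  bad <- st; bad$sigma <- -1
  expect_identical(log_prior(bad, spec), -Inf)
  bad <- st; bad$sigma <- 0
  expect_identical(log_prior(bad, spec), -Inf)

  # hand-computed normal log densities (uniform terms are constants)
  manual <- dnorm(-8, 0, 100, log = TRUE) - log(50) +
    dnorm(0.1, 0, 100, log = TRUE) +
    sum(dnorm(unlist(st$delta), -8, 1.5, log = TRUE))
  expect_equal(log_prior(st, spec), manual, tolerance = 1e-10)

  # random-mapping hierarchy term, CV parameterisation
  spec_r <- model_spec("random_mapping", reference = "A",
                       priors = prior_spec(sigma_prior = "uniform_sd"))
  st_r <- make_state(ds, spec_r, mu = -8, sigma = 1.5,
                     beta = c(B = -0.1), phi = 0.25)
  manual_r <- dnorm(-8, 0, 100, log = TRUE) - log(50) +
    dnorm(-0.1, 0, 100, log = TRUE) - log(2) +
    sum(dnorm(unlist(st_r$delta), -8, 1.5, log = TRUE)) +
    sum(dnorm(unlist(st_r$beta_trial), -0.1, 0.25 * 0.1, log = TRUE))
  expect_equal(log_prior(st_r, spec_r), manual_r, tolerance = 1e-10)

  bad <- st_r; bad$phi <- -0.01
  expect_identical(log_prior(bad, spec_r), -Inf)
  bad <- st_r; bad$phi <- 2.5
  expect_identical(log_prior(bad, spec_r), -Inf)
})

test_that("log likelihood agrees with a generic MVN oracle", {
  ds <- social_anxiety_data()
  spec <- model_spec("fixed_mapping")
  covs <- build_covariances(ds, spec$rho)
  set.seed(7)
  for (rep in 1:5) {
    st <- make_state(ds, spec, mu = rnorm(1, -12, 2), sigma = runif(1, 1, 4),
                     beta = setNames(runif(8, 0.02, 1.6),
                                     setdiff(unique(ds$observations$instrument),
                                             "LSAS")))
    ll <- log_likelihood(st, spec, ds, covs)
    manual <- 0
    for (tid in unique(ds$observations$trial_id)) {
      tr <- ds$observations[ds$observations$trial_id == tid, ]
      manual <- manual + mvn_logpdf_ref(tr$mean_diff,
                                        expected_effects(st, spec, tr),
                                        covs[[tid]]$matrix)
    }
    expect_equal(ll, manual, tolerance = 1e-8)
  }

  # a single-observation trial reduces to a scalar normal density
  one <- toy_trials()[1, ]
  ds1 <- load_trials(one)
  sp1 <- model_spec("fixed_mapping", reference = "A")
  st1 <- list(mu = -9, sigma = 1, beta = list(), delta = list("t1:1" = -9.5))
  expect_equal(log_likelihood(st1, sp1, ds1),
               dnorm(-10, -9.5, 2.5, log = TRUE), tolerance = 1e-12)

  # exact fit leaves only the normalising constant
  st1$delta[["t1:1"]] <- -10
  expect_equal(log_likelihood(st1, sp1, ds1),
               -0.5 * log(2 * pi) - log(2.5), tolerance = 1e-12)
})

test_that("likelihood is invariant to the choice of reference instrument", {
  ds <- social_anxiety_data()
  insts <- unique(ds$observations$instrument)
  spec_l <- model_spec("fixed_mapping", reference = "LSAS")
  spec_c <- model_spec("fixed_mapping", reference = "CGI-S")
  set.seed(11)
  beta_l <- setNames(runif(8, 0.05, 1.5), setdiff(insts, "LSAS"))
  st_l <- make_state(ds, spec_l, mu = -11, sigma = 3, beta = beta_l)

  # reparameterise: effects on the CGI-S scale, ratios from CGI-S
  b_cgi <- beta_l[["CGI-S"]]
  beta_c <- setNames(vapply(setdiff(insts, "CGI-S"), function(k) {
    derived_mapping(beta_l, "CGI-S", k)
  }, numeric(1)), setdiff(insts, "CGI-S"))
  st_c <- st_l
  st_c$mu <- b_cgi * st_l$mu
  st_c$sigma <- b_cgi * st_l$sigma
  st_c$beta <- as.list(beta_c)
  st_c$delta <- lapply(st_l$delta, function(d) b_cgi * d)

  expect_equal(log_likelihood(st_c, spec_c, ds),
               log_likelihood(st_l, spec_l, ds), tolerance = 1e-9)
})

test_that("ratios_one is the fixed-mapping model clamped at one", {
  ds <- standardise_dataset(social_anxiety_data())
  spec_f <- model_spec("fixed_mapping", standardised = TRUE)
  spec_1 <- model_spec("ratios_one", standardised = TRUE)
  set.seed(3)
  insts <- setdiff(unique(ds$observations$instrument), "LSAS")
  st <- make_state(ds, spec_f, mu = -0.45, sigma = 0.15,
                   beta = setNames(rep(1, 8), insts))
  covs <- build_covariances(ds, 0.65)
  expect_equal(log_likelihood(st, spec_f, ds, covs),
               log_likelihood(st, spec_1, ds, covs), tolerance = 1e-12)
})

test_that("likelihood is invariant under trial reordering", {
  ds <- social_anxiety_data()
  spec <- model_spec("fixed_mapping")
  set.seed(5)
  st <- make_state(ds, spec, mu = -11, sigma = 3)
  obs <- ds$observations
  perm_ids <- sample(unique(obs$trial_id))
  ds_p <- load_trials(obs[order(match(obs$trial_id, perm_ids)), ],
                      instruments = ds$instruments)
  expect_equal(log_likelihood(st, spec, ds_p),
               log_likelihood(st, spec, ds), tolerance = 1e-10)
})

test_that("model_spec validates its inputs", {
  expect_warning(model_spec("ratios_one", standardised = FALSE),
                 "standardised")
  expect_error(model_spec("fixed_mapping", rho = 1.2), "rho")
  expect_error(run_mcmc(model_spec(reference = "nope"),
                        toy_dataset(), mcmc_config(1, 10, 10)),
               "reference")
  # disconnected network is refused at model build
  tt <- toy_trials()
  tt$instrument[tt$trial_id == "t2"] <- c("C", "D")
  expect_error(run_mcmc(model_spec(reference = "A"), load_trials(tt),
                        mcmc_config(1, 10, 10)),
               "disconnected")
})
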