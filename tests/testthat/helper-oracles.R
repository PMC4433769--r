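# Independent reference implementations used as oracles.  These
# deliberately avoid the code paths of the package itself.

# MVN log density via solve()/determinant() (package uses Cholesky)
mvn_logpdf_ref <- function(y, mean, V) {
  d <- length(y)
  r <- y - mean
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * d * log(2 * pi) - 0.5 * ld - 0.5 * drop(t(r) %*% solve(V) %*% r)
}

# Conjugate Gibbs (with grid draw for sigma) for the single-instrument
# normal-normal random-effects model:
#   y_i ~ N(delta_i, se_i^2), delta_i ~ N(mu, sigma^2),
#   mu ~ N(0, mu_sd^2), sigma uniform on (0, upper) on the SD or
#   variance scale.  Completely independent of the package sampler.
ref_meta_gibbs <- function(y, se, n_iter = 8000, n_burn = 2000,
                           mu_sd = 100, sigma_upper = 50,
                           sigma_prior_var = TRUE) {
  k <- length(y)
  mu <- mean(y); sigma <- stats::sd(y); if (!is.finite(sigma)) sigma <- 1
  delta <- y
  grid <- seq(1e-4, sigma_upper, length.out = 4000)
  out <- matrix(NA_real_, n_iter, 2, dimnames = list(NULL, c("mu", "sigma")))
  for (it in seq_len(n_iter + n_burn)) {
    prec <- 1 / se^2 + 1 / sigma^2
    m <- (y / se^2 + mu / sigma^2) / prec
    delta <- rnorm(k, m, 1 / sqrt(prec))
    pm <- (sum(delta) / sigma^2) / (k / sigma^2 + 1 / mu_sd^2)
    pv <- 1 / (k / sigma^2 + 1 / mu_sd^2)
    mu <- rnorm(1, pm, sqrt(pv))
    ss <- sum((delta - mu)^2)
    logd <- -k * log(grid) - ss / (2 * grid^2) +
      if (sigma_prior_var) log(grid) else 0
    w <- exp(logd - max(logd))
    sigma <- sample(grid, 1, prob = w)
    if (it > n_burn) out[it - n_burn, ] <- c(mu, sigma)
  }
  out
}

# Split-chain potential scale reduction, written straight from the
# formula on a plain list of numeric vectors.
rhat_ref <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- n %/% 2
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  n <- length(halves[[1]])
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  W <- mean(vrs)
  B <- n * stats::var(mns)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# small two-trial, two-instrument dataset used across tests
toy_trials <- function() {
  data.frame(
    trial_id = c("t1", "t1", "t2", "t2"),
    arm_index = 1,
    n_control = c(50, 50, 60, 60),
    n_arm = c(55, 55, 58, 58),
    instrument = c("A", "B", "A", "B"),
    mean_diff = c(-10, -1.1, -12, -0.9),
    se = c(2.5, 0.3, 3.0, 0.25),
    pooled_sd = c(20, 2.2, 22, 2.0),
    basis = "unknown",
    stringsAsFactors = FALSE)
}

toy_dataset <- function() load_trials(toy_trials())

# a full parameter state for a dataset, for the R-path density functions
make_state <- function(ds, spec, mu = -10, sigma = 2, beta = NULL,
                       phi = NULL, delta_shift = 0) {
  obs <- ds$observations
  insts <- setdiff(unique(obs$instrument), spec$reference)
  if (is.null(beta)) beta <- setNames(rep(0.5, length(insts)), insts)
  keys <- unique(paste(obs$trial_id, obs$arm_index, sep = ":"))
  delta <- setNames(as.list(rnorm(length(keys), mu, sigma) + delta_shift), keys)
  st <- list(mu = mu, sigma = sigma, beta = as.list(beta), delta = delta)
  if (spec$variant == "random_mapping") {
    st$phi <- if (is.null(phi)) 0.2 else phi
    bt_keys <- unique(paste(obs$trial_id, obs$instrument,
                            sep = ":")[obs$instrument != spec$reference])
    st$beta_trial <- setNames(as.list(
      vapply(bt_keys, function(kk) {
        beta[[sub("^.*:", "", kk)]] * exp(rnorm(1, 0, 0.05))
      }, numeric(1))), bt_keys)
  }
  st
}

# shared MCMC fits for the acceptance checks: computed once per test
# run at fixed seed and reused across test blocks
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(variant, standardised = FALSE,
                       n_burn = 5000, n_keep = 5000, seed = 101,
                       rho = 0.65) {
  key <- paste(variant, standardised, n_burn, n_keep, seed, rho, sep = "|")
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  ds <- social_anxiety_data()
  fit <- suppressWarnings(run_mcmc(
    model_spec(variant, standardised = standardised, rho = rho),
    ds, mcmc_config(4, n_burn, n_keep, seed = seed)))
  .fit_cache[[key]] <- fit
  fit
}
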