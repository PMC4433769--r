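#' Prior specification
#'
#' Vague priors on the data scale: normal for the pooled effect and the
#' basic mapping ratios, uniform for the between-trials SD and for the
#' between-trials CV of mapping ratios.
#'
#' @param mu_sd Prior SD of the pooled treatment effect (normal, mean 0).
#' @param beta_sd Prior SD of each basic mapping ratio (normal, mean 0).
#' @param sigma_upper Upper bound of the uniform prior on the
#'   between-trials SD.  `NULL` picks 50 for unstandardised and 5 for
#'   standardised analyses at model build.
#' @param sigma_prior `"uniform_var"` (default) places the uniform
#'   prior on the between-trials variance (density proportional to
#'   sigma on the SD scale); `"uniform_sd"` places it on the SD
#'   itself.  A sensitivity knob: the posterior median of sigma moves
#'   by a few percent between the two.
#' @param phi_upper Upper bound of the uniform prior on the
#'   between-trials CV of mapping ratios.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(mu_sd = 100, beta_sd = 100, sigma_upper = NULL,
                       sigma_prior = c("uniform_var", "uniform_sd"),
                       phi_upper = 2) {
  stopifnot(mu_sd > 0, beta_sd > 0, phi_upper > 0,
            is.null(sigma_upper) || sigma_upper > 0)
  structure(list(mu_sd = mu_sd, beta_sd = beta_sd,
                 sigma_upper = sigma_upper,
                 sigma_prior = match.arg(sigma_prior),
                 phi_upper = phi_upper),
            class = "prior_spec")
}

#' Model specification
#'
#' Selects one of the mapping-model variants:
#'
#' * `"fixed_mapping"`: treatment effects on instruments h and k are in
#'   the same fixed ratio in every trial;
#' * `"random_mapping"`: per-trial ratios vary around their mean with a
#'   constant between-trials coefficient of variation `phi`;
#' * `"ratios_one"`: all mapping ratios forced to 1 (the assumption
#'   implicit in pooling standardised effects), normally combined with
#'   `standardised = TRUE`.
#'
#' @param variant One of `"fixed_mapping"`, `"random_mapping"`,
#'   `"ratios_one"`.
#' @param standardised Fit to effects standardised by the pooled SD?
#' @param reference Reference instrument name (pooled effect `mu` and
#'   between-trials SD `sigma` live on this scale; mapping ratios run
#'   from it to each other instrument).
#' @param rho Assumed between-instrument score correlation.
#' @param priors A [prior_spec()].
#' @param ratio_scale Scale of the random-mapping hierarchy:
#'   `"natural"` (default) draws per-trial ratios normal around the
#'   mean ratio with SD `phi * |beta|` (constant between-trials CV);
#'   `"log"` draws them lognormal with log-SD `phi` (equivalent CV for
#'   small `phi`, ratios constrained positive).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(variant = c("fixed_mapping", "random_mapping",
                                   "ratios_one"),
                       standardised = FALSE,
                       reference = "LSAS",
                       rho = 0.65,
                       priors = prior_spec(),
                       ratio_scale = c("natural", "log")) {
  variant <- match.arg(variant)
  ratio_scale <- match.arg(ratio_scale)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  if (variant == "ratios_one" && !standardised) {
    warning("ratios_one constrains all mapping ratios to 1, which is ",
            "normally only meaningful for standardised effects")
  }
  structure(list(variant = variant,
                 standardised = isTRUE(standardised),
                 reference = reference,
                 rho = rho,
                 priors = priors,
                 ratio_scale = ratio_scale),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$variant,
      if (x$standardised) ", standardised" else ", unstandardised",
      ", reference ", x$reference, ", rho ", x$rho, "\n", sep = "")
  invisible(x)
}

#' Mapping ratio between two instruments
#'
#' The basic mapping parameters are the ratios from the reference
#' instrument (ratio 1 by definition) to each other instrument; all
#' remaining pairwise ratios follow by transitivity:
#' `beta[h -> k] = beta[ref -> k] / beta[ref -> h]`.
#'
#' @param beta_basic Named vector of basic mapping ratios (reference ->
#'   instrument); the reference itself may be included with value 1 or
#'   omitted.
#' @param h,k Instrument names (`h` maps to `k`).
#' @param reference Reference instrument name.
#' @return The ratio relating a treatment effect on `h` to the
#'   equivalent effect on `k`.
#' @export
derived_mapping <- function(beta_basic, h, k, reference = "LSAS") {
  get_beta <- function(inst) {
    if (inst == reference) return(1)
    if (!inst %in% names(beta_basic)) {
      stop("no basic mapping ratio for instrument '", inst, "'")
    }
    unname(beta_basic[inst])
  }
  bh <- get_beta(h)
  bk <- get_beta(k)
  if (bh == 0) stop("degenerate mapping: ratio to '", h, "' is zero")
  bk / bh
}

# sigma_upper resolved against the spec's standardisation flag
.sigma_upper <- function(spec) {
  if (!is.null(spec$priors$sigma_upper)) return(spec$priors$sigma_upper)
  if (spec$standardised) 5 else 50
}

#' Expected observation vector for one trial
#'
#' The model mean of the observed difference vector, in the trial's
#' canonical (arm, instrument) order: `beta[ref -> k] * delta[i, a]`
#' under fixed mapping, `beta_trial[i, ref -> k] * delta[i, a]` under
#' random mapping, and `delta[i, a]` for every instrument under
#' `ratios_one`.  The reference instrument always uses ratio 1.
#'
#' @param state Parameter state: list with `mu`, `sigma`, named `beta`
#'   (one entry per non-reference instrument), optional `phi`, `delta`
#'   named `"trial:arm"`, and (random mapping) `beta_trial` named
#'   `"trial:instrument"`.
#' @param spec A [model_spec()].
#' @param trial Data frame of one trial's observations.
#' @return Numeric vector, one entry per observation.
#' @export
expected_effects <- function(state, spec, trial) {
  tid <- trial$trial_id[1]
  vapply(seq_len(nrow(trial)), function(j) {
    dl <- state$delta[[paste(tid, trial$arm_index[j], sep = ":")]]
    if (is.null(dl)) stop("missing random effect for trial '", tid,
                          "', arm ", trial$arm_index[j])
    inst <- trial$instrument[j]
    ratio <- if (inst == spec$reference || spec$variant == "ratios_one") {
      1
    } else if (spec$variant == "fixed_mapping") {
      state$beta[[inst]]
    } else {
      bt <- state$beta_trial[[paste(tid, inst, sep = ":")]]
      if (is.null(bt)) stop("missing trial-specific ratio for trial '", tid,
                            "', instrument '", inst, "'")
      bt
    }
    ratio * dl
  }, numeric(1))
}

#' Joint log-prior density of a parameter state
#'
#' Sum of the log prior densities of `mu`, `sigma`, the basic mapping
#' ratios and (random mapping) `phi`, plus the hierarchical terms:
#' `delta[i, a] ~ N(mu, sigma^2)` independently per active arm, and,
#' under random mapping, `beta_trial[i, k] ~ N(beta[k],
#' (phi * |beta[k]|)^2)`.  States outside the prior support return
#' `-Inf` rather than raising an error.
#'
#' @inheritParams expected_effects
#' @return Scalar log density (`-Inf` outside the support).
#' @export
log_prior <- function(state, spec) {
  pr <- spec$priors
  s_up <- .sigma_upper(spec)
  if (!is.finite(state$mu)) return(-Inf)
  if (is.na(state$sigma) || state$sigma <= 0 || state$sigma >= s_up) return(-Inf)
  lp <- dnorm(state$mu, 0, pr$mu_sd, log = TRUE) - log(s_up)
  if (identical(pr$sigma_prior, "uniform_var")) {
    # uniform on sigma^2 up to s_up^2: density 2*sigma/s_up^2 on sigma
    lp <- lp + log(2 * state$sigma / s_up)
  }
  if (spec$variant != "ratios_one") {
    lp <- lp + sum(dnorm(unlist(state$beta), 0, pr$beta_sd, log = TRUE))
  }
  lp <- lp + sum(dnorm(unlist(state$delta), state$mu, state$sigma, log = TRUE))
  if (spec$variant == "random_mapping") {
    phi <- state$phi
    if (is.null(phi) || is.na(phi) || phi < 0 || phi >= pr$phi_upper) {
      return(-Inf)
    }
    lp <- lp - log(pr$phi_upper)
    log_scale <- identical(spec$ratio_scale, "log")
    for (nm in names(state$beta_trial)) {
      inst <- sub("^.*:", "", nm)
      bk <- state$beta[[inst]]
      bt <- state$beta_trial[[nm]]
      if (log_scale) {
        if (bk <= 0 || bt <= 0) return(-Inf)
        lp <- lp + stats::dlnorm(bt, log(bk),
                                 max(phi, .Machine$double.eps), log = TRUE)
      } else {
        sdk <- max(phi * abs(bk), .Machine$double.eps)
        lp <- lp + dnorm(bt, bk, sdk, log = TRUE)
      }
    }
  }
  lp
}

# multivariate normal log density via Cholesky factor of the covariance
.mvn_logpdf <- function(y, mean, chol_v) {
  d <- length(y)
  z <- backsolve(chol_v, y - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_v))) - 0.5 * sum(z^2)
}

#' Multivariate-normal log-likelihood of a dataset
#'
#' Sum over trials of the multivariate normal log density of the
#' observed difference vector around [expected_effects()], with the
#' within-trial covariance from [trial_covariance()].
#'
#' @inheritParams expected_effects
#' @param ds A [trial_dataset].
#' @param covs Covariances from [build_covariances()]; built from
#'   `spec$rho` when omitted.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(state, spec, ds, covs = NULL) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (is.null(covs)) covs <- build_covariances(ds, rho = spec$rho)
  obs <- ds$observations
  total <- 0
  for (tid in unique(obs$trial_id)) {
    trial <- obs[obs$trial_id == tid, ]
    cv <- covs[[tid]]
    if (is.null(cv) || nrow(cv$matrix) != nrow(trial)) {
      stop("covariance dimension mismatch for trial '", tid, "'")
    }
    theta <- expected_effects(state, spec, trial)
    total <- total + .mvn_logpdf(trial$mean_diff, theta, cv$chol)
  }
  total
}
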