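#' MCMC configuration
#'
#' Defaults reproduce the full-length reference run: four chains of
#' 20,000 kept samples each after 30,000 burn-in iterations.  Shorter
#' runs (e.g. `n_burn = 5000, n_keep = 5000`) are adequate for the
#' packaged dataset.
#'
#' @param n_chains Number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param n_burn Burn-in iterations discarded per chain; proposal step
#'   sizes adapt during burn-in only.
#' @param n_keep Kept samples per chain.
#' @param seed Integer seed; all chain randomness (overdispersed starts
#'   and proposals) derives from it.
#' @param adapt_interval Iterations per adaptation batch during burn-in.
#' @param target_accept Target acceptance rate of the scalar
#'   random-walk blocks.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_burn = 30000, n_keep = 20000,
                        seed = 1, adapt_interval = 50, target_accept = 0.44,
                        thin = 1) {
  stopifnot(n_chains >= 1, n_burn >= 0, n_keep >= 1, adapt_interval >= 1,
            target_accept > 0, target_accept < 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept,
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

# Internal: index structures shared by the sampler and the summaries.
# Instruments are reordered with the reference first; observations keep
# the dataset's canonical order.
build_model_data <- function(spec, ds) {
  stopifnot(inherits(spec, "model_spec"), inherits(ds, "trial_dataset"))
  if (spec$standardised && !isTRUE(ds$standardised)) {
    ds <- standardise_dataset(ds)
  }
  obs <- ds$observations
  used <- unique(obs$instrument)
  if (!spec$reference %in% used) {
    stop("reference instrument '", spec$reference, "' is not reported ",
         "by any trial")
  }
  net <- instrument_network(ds)
  memb <- net$membership[used]
  if (length(unique(memb)) > 1) {
    ref_comp <- net$membership[[spec$reference]]
    stop("instrument network is disconnected; unreachable from '",
         spec$reference, "': ",
         paste(used[memb != ref_comp], collapse = ", "))
  }

  inst_order <- c(spec$reference, setdiff(
    ds$instruments$instrument[ds$instruments$instrument %in% used],
    spec$reference))
  M <- length(inst_order)
  trial_ids <- unique(obs$trial_id)
  obs_trial <- match(obs$trial_id, trial_ids) - 1L
  obs_inst <- match(obs$instrument, inst_order) - 1L

  delta_key <- paste(obs$trial_id, obs$arm_index, sep = ":")
  delta_ids <- unique(delta_key)
  obs_delta <- match(delta_key, delta_ids) - 1L
  D <- length(delta_ids)

  if (spec$variant == "random_mapping") {
    bt_key <- ifelse(obs_inst == 0L, NA,
                     paste(obs$trial_id, obs$instrument, sep = ":"))
    bt_ids <- unique(bt_key[!is.na(bt_key)])
    obs_bt <- ifelse(is.na(bt_key), -1L, match(bt_key, bt_ids) - 1L)
    bt_trial <- match(sub(":[^:]*$", "", bt_ids), trial_ids) - 1L
    bt_inst <- match(sub("^.*:", "", bt_ids), inst_order) - 2L
  } else {
    bt_ids <- character(0)
    obs_bt <- rep(-1L, nrow(obs))
    bt_trial <- integer(0)
    bt_inst <- integer(0)
  }
  B <- length(bt_ids)

  covs <- build_covariances(ds, rho = spec$rho)
  Vinv <- lapply(covs, function(cv) chol2inv(cv$chol))
  trial_obs <- lapply(seq_along(trial_ids) - 1L,
                      function(t) which(obs_trial == t) - 1L)

  beta_trials <- lapply(seq_len(M - 1), function(k) {
    sort(unique(obs_trial[obs_inst == k]))
  })
  beta_bts <- lapply(seq_len(M - 1), function(k) {
    which(bt_inst == k - 1L) - 1L
  })

  variant_code <- match(spec$variant,
                        c("fixed_mapping", "random_mapping", "ratios_one")) - 1L
  nb <- if (spec$variant == "ratios_one") 0L else M - 1L
  has_phi <- spec$variant == "random_mapping"

  # data-informed initial proposal scales, refined by adaptation: the
  # conditional scale of each effect block is roughly the inverse
  # root of its summed likelihood precision
  ref_y <- obs$mean_diff[obs_inst == 0L]
  ctr <- mean(if (length(ref_y) > 1) ref_y else obs$mean_diff)
  if (!is.finite(ctr) || ctr == 0) ctr <- 1
  b_hat <- vapply(seq_len(max(M - 1, 1)), function(k) {
    b <- mean(obs$mean_diff[obs_inst == k]) / ctr
    if (!is.finite(b) || b == 0) 1 else abs(b)
  }, numeric(1))
  map_hat <- ifelse(obs_inst == 0L, 1, b_hat[pmax(obs_inst, 1L)])
  delta_step <- vapply(seq_len(D), function(d) {
    j <- which(obs_delta == d - 1L)
    2.4 / sqrt(sum((map_hat[j] / obs$se[j])^2))
  }, numeric(1))
  bt_step <- if (B > 0) vapply(seq_len(B), function(b) {
    j <- which(obs_bt == b - 1L)
    2.4 / sqrt(sum((ctr / obs$se[j])^2))
  }, numeric(1)) else numeric(0)
  spread <- if (length(ref_y) > 1) sd(ref_y) else abs(ctr) / 2
  step_init <- c(max(spread / 2, abs(ctr) / 10, 1e-3), 0.4,
                 if (nb > 0) pmax(0.3 * b_hat[seq_len(nb)], 1e-4),
                 if (has_phi) 0.4,
                 delta_step, bt_step,
                 # joint (beta, trial-ratio) translation blocks
                 if (has_phi) pmax(0.3 * b_hat[seq_len(nb)], 1e-4))
  par_names <- c("mu", "sigma",
                 if (nb > 0) paste0("beta[", inst_order[-1], "]"),
                 if (has_phi) "phi",
                 paste0("delta[", delta_ids, "]"),
                 if (B > 0) paste0("bt[", bt_ids, "]"))

  list(ds = ds, spec = spec, trial_ids = trial_ids,
       inst_order = inst_order, M = M, D = D, B = B,
       delta_ids = delta_ids, bt_ids = bt_ids,
       y = obs$mean_diff, Vinv = unname(Vinv), trial_obs = trial_obs,
       obs_trial = obs_trial, obs_delta = obs_delta, obs_inst = obs_inst,
       obs_bt = obs_bt,
       delta_trial = match(sub(":[^:]*$", "", delta_ids), trial_ids) - 1L,
       bt_inst = bt_inst, bt_trial = bt_trial,
       beta_trials = beta_trials, beta_bts = beta_bts,
       variant = variant_code, step_init = step_init,
       mu_sd = spec$priors$mu_sd, beta_sd = spec$priors$beta_sd,
       sigma_upper = .sigma_upper(spec), phi_upper = spec$priors$phi_upper,
       sigma_prior_var = identical(spec$priors$sigma_prior, "uniform_var"),
       ratio_log = identical(spec$ratio_scale, "log"),
       par_names = par_names,
       nb = nb, has_phi = has_phi)
}

# Internal: overdispersed but data-informed start for one chain, on the
# sampler's internal scale (log sigma, log phi).  Starting values are
# spread widely in magnitude but respect the sign structure the
# reference-scale observations identify, so no chain starts in the
# unidentified sign-reflected basin that coordinatewise random-walk
# moves cannot leave.
draw_init <- function(md) {
  obs <- md$ds$observations
  ref_name <- md$inst_order[1]
  ref <- obs$mean_diff[obs$instrument == ref_name]
  if (length(ref) < 2) ref <- obs$mean_diff
  ctr <- mean(ref); spread <- max(sd(ref), abs(ctr) / 4, 1e-3)
  mu0 <- ctr * exp(runif(1, -1, 1)) + runif(1, -spread, spread)
  sigma0 <- exp(runif(1, log(spread / 5), log(min(3 * spread,
                                                  md$sigma_upper * 0.9))))
  beta0 <- vapply(seq_len(md$M - 1), function(k) {
    yk <- obs$mean_diff[obs$instrument == md$inst_order[k + 1]]
    b <- mean(yk) / ctr
    if (!is.finite(b) || b == 0) b <- 1
    if (md$ratio_log) b <- abs(b)  # log-scale hierarchy needs positives
    b * exp(runif(1, -0.7, 0.7))
  }, numeric(1))
  phi0 <- runif(1, 0.05 * md$phi_upper, 0.9 * md$phi_upper)
  # per-arm effects seeded from the arm's own observations
  delta0 <- vapply(seq_len(md$D), function(d) {
    rows <- which(md$obs_delta == d - 1L)
    ref_rows <- rows[md$obs_inst[rows] == 0L]
    base <- if (length(ref_rows) > 0) {
      mean(obs$mean_diff[ref_rows])
    } else {
      ks <- md$obs_inst[rows]
      mean(obs$mean_diff[rows] / beta0[ks])
    }
    base + rnorm(1, 0, spread / 2)
  }, numeric(1))
  bt0 <- if (md$B > 0) {
    beta0[md$bt_inst + 1L] * exp(runif(md$B, -0.3, 0.3))
  } else numeric(0)
  c(mu0, log(sigma0),
    if (md$nb > 0) beta0,
    if (md$has_phi) log(phi0),
    delta0, bt0)
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs
#'
#' Runs `cfg$n_chains` independent chains from overdispersed,
#' data-informed starting values.  Every parameter is updated by a
#' scalar random-walk Metropolis step (on the log scale for `sigma` and
#' `phi`); step sizes adapt toward [mcmc_config()]'s target acceptance
#' during burn-in and are frozen afterwards.  All randomness flows from
#' `cfg$seed`, so runs are bit-reproducible.
#'
#' @param spec A [model_spec()].
#' @param ds A [trial_dataset]; standardised internally when
#'   `spec$standardised` is set.
#' @param cfg An [mcmc_config()].
#' @return Object of class `posterior_samples`: list with `draws` (one
#'   `n_keep x n_par` matrix per chain, natural scale), `resdev`
#'   (per-iteration residual deviance per chain), `par_names`,
#'   `accept_rate`, the `spec`, `cfg` and internal model layout.
#' @examples
#' \donttest{
#' ds <- social_anxiety_data()
#' fit <- run_mcmc(model_spec("fixed_mapping"), ds,
#'                 mcmc_config(n_burn = 2000, n_keep = 2000, seed = 42))
#' summary(fit)
#' }
#' @export
run_mcmc <- function(spec, ds, cfg = mcmc_config()) {
  stopifnot(inherits(cfg, "mcmc_config"))
  md <- build_model_data(spec, ds)
  set.seed(cfg$seed)
  chains <- vector("list", cfg$n_chains)
  resdev <- vector("list", cfg$n_chains)
  rates <- NULL
  for (ch in seq_len(cfg$n_chains)) {
    init <- draw_init(md)
    out <- .mwg_chain(md, init, cfg)
    dr <- out$draws
    colnames(dr) <- md$par_names
    chains[[ch]] <- dr
    resdev[[ch]] <- as.numeric(out$resdev)
    rates <- cbind(rates, as.numeric(out$accept_rate))
    block_names <- c(md$par_names,
                     if (md$has_phi) paste0("joint:", md$inst_order[-1]))
    bad <- which(!is.na(rates[, ch]) & rates[, ch] == 0)
    if (length(bad) > 0) {
      warning("chain ", ch, ": no accepted proposals after adaptation for ",
              "block(s) ", paste(block_names[bad], collapse = ", "))
    }
  }
  structure(list(draws = chains, resdev = resdev,
                 par_names = md$par_names,
                 accept_rate = rates,
                 spec = spec, cfg = cfg, model = md),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", x$spec$variant,
      if (x$spec$standardised) " (standardised)", ": ",
      length(x$draws), " chains x ", nrow(x$draws[[1]]), " kept draws, ",
      length(x$par_names), " parameters\n", sep = "")
  invisible(x)
}

#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor per stored parameter:
#' each chain is split in half, and R-hat is
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `W`, `B` the within- and
#' between-half variances.  Parameters with zero total variance
#' (degenerate draws) report 1.
#'
#' @param samples A [run_mcmc()] result.
#' @return Named vector of R-hat values.
#' @export
gelman_rubin <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (length(samples$draws) < 2) {
    stop("at least 2 chains are required for the convergence diagnostic")
  }
  n <- nrow(samples$draws[[1]])
  half <- n %/% 2
  splits <- list()
  for (dr in samples$draws) {
    splits <- c(splits, list(dr[seq_len(half), , drop = FALSE],
                             dr[(n - half + 1):n, , drop = FALSE]))
  }
  m <- length(splits)
  means <- vapply(splits, colMeans, numeric(length(samples$par_names)))
  vars <- vapply(splits, function(s) apply(s, 2, stats::var),
                 numeric(length(samples$par_names)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- half * apply(means, 1, stats::var)
  rhat <- sqrt(((half - 1) / half * W + B / half) / W)
  rhat[W == 0 & B == 0] <- 1
  setNames(rhat, samples$par_names)
}

#' Posterior mean residual deviance
#'
#' Posterior mean over all kept draws of the model-data discrepancy
#' `sum_i (y_i - theta_i)' V_i^{-1} (y_i - theta_i)`.  For a
#' well-fitting model this is approximately the number of observations.
#' Recomputed from the stored draws (not read from sampler bookkeeping).
#'
#' @param samples A [run_mcmc()] result.
#' @return Scalar posterior mean residual deviance.
#' @export
residual_deviance <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  md <- samples$model
  # 1-based column of the first per-arm random effect in the draw matrix
  i_delta0 <- 3L + md$nb + as.integer(md$has_phi)
  i_bt0 <- i_delta0 + md$D
  dev <- 0
  n_total <- 0
  for (dr in samples$draws) {
    n <- nrow(dr)
    theta <- matrix(0, n, length(md$y))
    for (j in seq_along(md$y)) {
      dcol <- dr[, i_delta0 + md$obs_delta[j]]
      k <- md$obs_inst[j]
      fac <- if (k == 0L || md$variant == 2L) {
        1
      } else if (md$variant == 0L) {
        dr[, 2L + k]
      } else {
        dr[, i_bt0 + md$obs_bt[j]]  # obs_bt is 0-based
      }
      theta[, j] <- fac * dcol
    }
    for (t in seq_along(md$Vinv)) {
      idx <- md$trial_obs[[t]] + 1L
      R <- theta[, idx, drop = FALSE] -
        matrix(md$y[idx], n, length(idx), byrow = TRUE)
      dev <- dev + sum((R %*% md$Vinv[[t]]) * R)
    }
    n_total <- n_total + n
  }
  dev / n_total
}

#' Posterior summaries of a fitted mapping model
#'
#' Reports the pooled treatment effect `mu` as posterior mean with SD,
#' and the between-trials SD `sigma`, basic mapping ratios and (random
#' mapping) the between-trials CV `phi` as posterior medians with
#' equal-tailed 95% credible intervals, together with split-chain R-hat
#' and the posterior mean residual deviance.
#'
#' @param samples A [run_mcmc()] result.
#' @param rhat_limit Warn when any reported parameter exceeds this
#'   R-hat (convergence gate).
#' @return Object of class `fit_report`: data frame with columns
#'   `parameter`, `mean`, `sd`, `median`, `lower`, `upper`, `rhat`;
#'   attributes `resdev`, `spec` and `n_obs`.
#' @export
fit_report <- function(samples, rhat_limit = 1.05) {
  stopifnot(inherits(samples, "posterior_samples"))
  md <- samples$model
  keep <- c("mu", "sigma",
            if (md$nb > 0) paste0("beta[", md$inst_order[-1], "]"),
            if (md$has_phi) "phi")
  all_draws <- do.call(rbind, samples$draws)
  rhat <- if (length(samples$draws) >= 2) gelman_rubin(samples) else
    setNames(rep(NA_real_, length(samples$par_names)), samples$par_names)
  rows <- lapply(keep, function(p) {
    x <- all_draws[, p]
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               median = median(x),
               lower = unname(quantile(x, 0.025)),
               upper = unname(quantile(x, 0.975)),
               rhat = unname(rhat[p]),
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  if (any(is.finite(rep_df$rhat) & rep_df$rhat > rhat_limit)) {
    warning("convergence gate: R-hat above ", rhat_limit, " for ",
            paste(rep_df$parameter[is.finite(rep_df$rhat) &
                                     rep_df$rhat > rhat_limit],
                  collapse = ", "))
  }
  structure(rep_df,
            resdev = residual_deviance(samples),
            spec = samples$spec,
            n_obs = length(md$y),
            class = c("fit_report", "data.frame"))
}

#' @export
summary.posterior_samples <- function(object, ...) fit_report(object, ...)

#' @export
print.fit_report <- function(x, digits = 4, ...) {
  spec <- attr(x, "spec")
  cat("Mapping-model fit: ", spec$variant,
      if (spec$standardised) " (standardised)" else " (unstandardised)",
      ", reference ", spec$reference, ", rho ", spec$rho, "\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  cat("Mean residual deviance: ", round(attr(x, "resdev"), 1),
      " (", attr(x, "n_obs"), " observations)\n", sep = "")
  invisible(x)
}

# Internal: matrix of all kept draws for selected parameters
pooled_draws <- function(samples, pars = NULL) {
  all_draws <- do.call(rbind, samples$draws)
  if (is.null(pars)) all_draws else all_draws[, pars, drop = FALSE]
}
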