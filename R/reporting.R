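#' Pooled treatment effect mapped to every instrument
#'
#' Transforms the posterior draws so the pooled effect and the
#' between-trials SD can be read on any instrument in the network: per
#' draw, the mapped effect on instrument k is `beta[ref -> k] * mu` and
#' the mapped between-trials SD is `|beta[ref -> k]| * sigma`.  The
#' reference row reproduces the raw `mu`, `sigma` summaries exactly.
#'
#' @param samples A [run_mcmc()] result from a model with mapping
#'   ratios (fixed or random variant).
#' @return Object of class `mapped_effects`: data frame with one row
#'   per instrument; effect summarised as posterior mean with 95% CrI,
#'   between-trials SD as posterior median with 95% CrI.
#' @export
map_pooled_effects <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  md <- samples$model
  if (md$nb == 0) {
    stop("mapped effects need a model with mapping ratios ",
         "(fixed_mapping or random_mapping)")
  }
  dr <- pooled_draws(samples)
  mu <- dr[, "mu"]; sigma <- dr[, "sigma"]
  rows <- lapply(seq_len(md$M), function(k) {
    inst <- md$inst_order[k]
    b <- if (k == 1) 1 else dr[, paste0("beta[", inst, "]")]
    eff <- b * mu
    bsd <- abs(b) * sigma
    data.frame(instrument = inst,
               effect_mean = mean(eff),
               effect_lower = unname(quantile(eff, 0.025)),
               effect_upper = unname(quantile(eff, 0.975)),
               sd_median = median(bsd),
               sd_lower = unname(quantile(bsd, 0.025)),
               sd_upper = unname(quantile(bsd, 0.975)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("mapped_effects", "data.frame"))
}

#' Relative precision of pooled estimates across models
#'
#' Two unit-free ratios per fitted model: the absolute posterior mean
#' of the pooled effect divided by its posterior SD, and divided by the
#' posterior median between-trials SD.  Both are invariant to rescaling
#' of the measurement units, so they compare standardised and
#' unstandardised analyses on an equal footing.
#'
#' @param reports Named list of [fit_report()] objects (or
#'   `posterior_samples`, which are summarised on the fly).
#' @return Data frame with columns `model`, `effect_to_sd`,
#'   `effect_to_between_sd`.
#' @export
relative_precision <- function(reports) {
  if (inherits(reports, "fit_report") ||
      inherits(reports, "posterior_samples")) {
    reports <- list(reports)
  }
  nms <- names(reports)
  if (is.null(nms)) nms <- paste0("model", seq_along(reports))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    if (inherits(r, "posterior_samples")) r <- fit_report(r)
    mu <- r[r$parameter == "mu", ]
    sig <- r[r$parameter == "sigma", ]
    if (nrow(mu) != 1 || nrow(sig) != 1) {
      stop("report ", nms[i], " lacks mu/sigma summaries")
    }
    if (mu$sd <= 0 || sig$median <= 0) {
      stop("degenerate posterior in report ", nms[i],
           ": zero posterior SD")
    }
    data.frame(model = nms[i],
               effect_to_sd = abs(mu$mean) / mu$sd,
               effect_to_between_sd = abs(mu$mean) / sig$median,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scale-range conversion heuristic
#'
#' The informal alternative to estimated mapping ratios: convert
#' between instruments by the ratio of their theoretical scale ranges,
#' `range(to) / range(from)` (e.g. LSAS 144 points to CGI-S 7 points
#' gives 7/144 = 0.0486).
#'
#' @param from,to Instrument names.
#' @param instruments Instrument metadata with `instrument` and
#'   `scale_range` columns; defaults to the packaged social-anxiety
#'   instruments.
#' @return Scalar conversion factor.
#' @export
range_ratio_conversion <- function(from, to,
                                   instruments = social_anxiety_instruments()) {
  rng <- function(inst) {
    i <- match(inst, instruments$instrument)
    if (is.na(i)) stop("unknown instrument '", inst, "'")
    r <- instruments$scale_range[i]
    if (is.na(r) || r <= 0) stop("missing scale range for '", inst, "'")
    r
  }
  rng(to) / rng(from)
}

#' Sensitivity of the fit to the assumed score correlation
#'
#' Refits the model at alternative values of the between-instrument
#' correlation `rho` (reusing the baseline seed to damp Monte Carlo
#' noise in the deltas) and reports shifts in the pooled effect, the
#' between-trials SD and the mean residual deviance relative to the
#' baseline `spec$rho`.
#'
#' @param spec A [model_spec()]; its `rho` is the baseline.
#' @param ds A [trial_dataset].
#' @param cfg An [mcmc_config()].
#' @param rhos Correlation values to refit at.
#' @return Data frame with one row per `rho` (baseline first):
#'   `rho`, `mu_mean`, `sigma_median`, `resdev`, and deltas versus
#'   baseline.
#' @export
rho_sensitivity <- function(spec, ds, cfg = mcmc_config(),
                            rhos = c(0.55, 0.75)) {
  if (any(abs(rhos) >= 1)) stop("rho values must lie in (-1, 1)")
  fit_at <- function(r) {
    sp <- spec
    sp$rho <- r
    s <- run_mcmc(sp, ds, cfg)
    rep <- fit_report(s)
    c(mu_mean = rep$mean[rep$parameter == "mu"],
      sigma_median = rep$median[rep$parameter == "sigma"],
      resdev = attr(rep, "resdev"))
  }
  base <- fit_at(spec$rho)
  rows <- lapply(setdiff(rhos, spec$rho), fit_at)
  out <- as.data.frame(rbind(base, do.call(rbind, rows)))
  out$rho <- c(spec$rho, setdiff(rhos, spec$rho))
  out$d_mu <- out$mu_mean - base[["mu_mean"]]
  out$d_resdev <- out$resdev - base[["resdev"]]
  rownames(out) <- NULL
  out[, c("rho", "mu_mean", "sigma_median", "resdev", "d_mu", "d_resdev")]
}

#' Network adjacency table
#'
#' Co-reporting counts per instrument pair, suitable for drawing the
#' instrument network.
#'
#' @param ds A [trial_dataset].
#' @return Data frame `from`, `to`, `n_trials`.
#' @export
network_adjacency <- function(ds) {
  instrument_network(ds)$edges
}
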