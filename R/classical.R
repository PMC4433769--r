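#' Per-trial variance samples for one instrument
#'
#' Extracts, for every trial reporting the instrument, the pooled SD
#' (one value per trial) and the degrees of freedom to attach to it.
#' Two df conventions are available:
#'
#' * `"active_n"` (default): the number of patients randomised to the
#'   active arms of the trial.  This is the convention under which the
#'   packaged social-anxiety LSAS SDs give a Bartlett statistic of
#'   about 279 on 18 df.
#' * `"randomised_minus_arms"`: total randomised sample size minus the
#'   number of arms — the usual df of an SD pooled across all arms.
#'
#' @param ds A [trial_dataset].
#' @param instrument Instrument name.
#' @param df df convention, see above.
#' @return Data frame `trial_id`, `sd`, `df`.
#' @export
variance_samples <- function(ds, instrument = "LSAS",
                             df = c("active_n", "randomised_minus_arms")) {
  stopifnot(inherits(ds, "trial_dataset"))
  df <- match.arg(df)
  obs <- ds$observations
  rows <- lapply(unique(obs$trial_id), function(tid) {
    tr <- obs[obs$trial_id == tid, ]
    sd_i <- unique(tr$pooled_sd[tr$instrument == instrument])
    if (length(sd_i) == 0) return(NULL)
    if (length(sd_i) > 1) {
      stop("trial '", tid, "' carries more than one pooled SD for '",
           instrument, "'")
    }
    n_active <- sum(tapply(tr$n_arm, tr$arm_index, function(v) v[1]))
    n_arms <- length(unique(tr$arm_index)) + 1L
    n_total <- tr$n_control[1] + n_active
    data.frame(trial_id = tid, sd = sd_i,
               df = if (df == "active_n") n_active else n_total - n_arms,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no trial reports instrument '", instrument, "'")
  }
  rownames(out) <- NULL
  out
}

#' Bartlett's test of homogeneity of variance from summary statistics
#'
#' The standard Bartlett statistic with correction factor, computed
#' from per-sample SDs and degrees of freedom (rather than raw data):
#' with `N = sum(df)` and pooled variance `sp2 = sum(df * sd^2) / N`,
#' the statistic is
#' `(N * log(sp2) - sum(df * log(sd^2))) / C`,
#' `C = 1 + (sum(1/df) - 1/N) / (3 (k - 1))`, referred to a chi-square
#' distribution on `k - 1` df.
#'
#' @param sd Positive SDs, one per sample, or a data frame as returned
#'   by [variance_samples()].
#' @param df Degrees of freedom per sample (ignored when `sd` is a
#'   data frame).
#' @return List with `statistic`, `df`, `p.value`, `pooled_sd`.
#' @examples
#' vs <- variance_samples(social_anxiety_data(), "LSAS")
#' bartlett_sd_test(vs)
#' @export
bartlett_sd_test <- function(sd, df = NULL) {
  if (is.data.frame(sd)) {
    df <- sd$df
    sd <- sd$sd
  }
  k <- length(sd)
  if (k < 2) stop("at least 2 variance samples are required")
  if (length(df) != k) stop("sd and df lengths differ")
  if (any(sd <= 0)) stop("SDs must be positive")
  if (any(df < 1)) stop("every sample needs at least 1 degree of freedom")
  N <- sum(df)
  sp2 <- sum(df * sd^2) / N
  stat <- N * log(sp2) - sum(df * log(sd^2))
  C <- 1 + (sum(1 / df) - 1 / N) / (3 * (k - 1))
  stat <- stat / C
  list(statistic = stat, df = k - 1,
       p.value = pchisq(stat, k - 1, lower.tail = FALSE),
       pooled_sd = sqrt(sp2))
}

#' Pooled within-study SD
#'
#' `sqrt(sum(df * sd^2) / sum(df))`: the df-weighted root mean square
#' of the per-trial SDs.
#'
#' @inheritParams bartlett_sd_test
#' @return Scalar pooled SD.
#' @export
pooled_within_sd <- function(sd, df = NULL) {
  if (is.data.frame(sd)) {
    df <- sd$df
    sd <- sd$sd
  }
  if (length(sd) < 1) stop("at least one variance sample is required")
  if (length(df) != length(sd)) stop("sd and df lengths differ")
  if (any(sd <= 0) || any(df <= 0)) stop("sd and df must be positive")
  sqrt(sum(df * sd^2) / sum(df))
}
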