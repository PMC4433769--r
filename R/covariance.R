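#' Within-trial covariance of observed mean differences
#'
#' Builds the variance-covariance matrix of the vector of observed mean
#' treatment differences in one trial, across active arms and
#' instruments.  With `se` the standard error of each difference, `sd`
#' the pooled SD of each instrument in the trial, and `rho` the assumed
#' between-instrument score correlation:
#'
#' * diagonal: `se^2`;
#' * same arm, instruments h != k: `rho * se_h * se_k`;
#' * different arms, same instrument h (shared control arm):
#'   `sd_h^2 / n_control`;
#' * different arms, different instruments:
#'   `rho * sd_h * sd_k / n_control`.
#'
#' The layout follows the canonical row order of the dataset (arm, then
#' instrument).  The result is checked for positive definiteness by
#' Cholesky factorisation; failure signals inconsistent se / sd / n
#' inputs for that trial.
#'
#' @param trial Data frame of the trial's observations (rows of a
#'   [trial_dataset] for a single `trial_id`, in canonical order).
#' @param rho Between-instrument correlation of the underlying test
#'   scores, in (-1, 1).  The packaged analysis uses 0.65 (0.55 and
#'   0.75 as sensitivity values).
#' @return Object of class `trial_covariance`: list with `trial_id`,
#'   `order` (data frame `arm_index`, `instrument`) and `matrix`.
#' @examples
#' ds <- social_anxiety_data()
#' tr <- ds$observations[ds$observations$trial_id == "Davidson (2004)", ]
#' trial_covariance(tr, rho = 0.65)$matrix
#' @export
trial_covariance <- function(trial, rho = 0.65) {
  stopifnot(is.data.frame(trial), nrow(trial) >= 1)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  tid <- trial$trial_id[1]
  if (length(unique(trial$trial_id)) > 1) {
    stop("trial_covariance expects observations from a single trial")
  }
  d <- nrow(trial)
  multi_arm <- length(unique(trial$arm_index)) > 1
  if (multi_arm && anyNA(trial$n_control)) {
    stop("missing n_control in multi-arm trial '", tid, "'")
  }
  if (multi_arm && anyNA(trial$pooled_sd)) {
    stop("missing pooled SD needed for shared-control covariance in ",
         "multi-arm trial '", tid, "'")
  }
  nc <- trial$n_control[1]
  V <- matrix(0, d, d)
  for (j in seq_len(d)) {
    for (l in seq_len(d)) {
      if (j == l) {
        V[j, l] <- trial$se[j]^2
      } else if (trial$arm_index[j] == trial$arm_index[l]) {
        V[j, l] <- rho * trial$se[j] * trial$se[l]
      } else if (trial$instrument[j] == trial$instrument[l]) {
        V[j, l] <- trial$pooled_sd[j] * trial$pooled_sd[l] / nc
      } else {
        V[j, l] <- rho * trial$pooled_sd[j] * trial$pooled_sd[l] / nc
      }
    }
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    stop("covariance matrix for trial '", tid, "' is not positive definite; ",
         "check se, pooled_sd and arm sizes")
  }
  structure(list(trial_id = tid,
                 order = trial[, c("arm_index", "instrument")],
                 matrix = V,
                 chol = ch),
            class = "trial_covariance")
}

#' Covariance matrices for every trial in a dataset
#'
#' @param ds A [trial_dataset].
#' @param rho Between-instrument correlation, see [trial_covariance()].
#' @return Named list of [trial_covariance] objects, one per trial, in
#'   dataset order.
#' @export
build_covariances <- function(ds, rho = 0.65) {
  stopifnot(inherits(ds, "trial_dataset"))
  obs <- ds$observations
  ids <- unique(obs$trial_id)
  setNames(lapply(ids, function(tid) {
    trial_covariance(obs[obs$trial_id == tid, ], rho = rho)
  }), ids)
}

#' @export
print.trial_covariance <- function(x, ...) {
  cat("<trial_covariance> trial '", x$trial_id, "', ",
      nrow(x$matrix), " observations\n", sep = "")
  m <- x$matrix
  dimnames(m) <- list(paste0(x$order$instrument, ":", x$order$arm_index),
                      paste0(x$order$instrument, ":", x$order$arm_index))
  print(round(m, 4))
  invisible(x)
}
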