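#' Trial-level multi-instrument evidence base
#'
#' A `trial_dataset` holds one row per (trial, active arm, instrument):
#' the mean treatment difference versus the common control arm, its
#' standard error, the pooled within-trial SD on that instrument, and
#' the arm sample sizes.  Effects are stored with their published sign
#' (for the packaged social-anxiety data, negative means improvement).
#'
#' @name trial_dataset
#' @seealso [load_trials()], [social_anxiety_data()]
NULL

.required_cols <- c("trial_id", "arm_index", "n_control", "n_arm",
                    "instrument", "mean_diff", "se", "pooled_sd", "basis")

#' Load and validate a trial dataset
#'
#' Reads a table with one row per (trial, active arm, instrument) and
#' returns a validated `trial_dataset`.  Rows are put into a canonical
#' order (trial in order of first appearance, then arm index, then
#' instrument in the order of the instrument table) so that observation
#' vectors, covariance matrices and parameter layouts always agree.
#'
#' @param source A CSV file path, or a data frame with columns
#'   `trial_id`, `arm_index`, `n_control`, `n_arm`, `instrument`,
#'   `mean_diff`, `se`, `pooled_sd`, `basis`.
#' @param instruments Optional instrument metadata: a data frame with
#'   columns `instrument` and `scale_range` (theoretical maximum minus
#'   minimum score; e.g. 144 for LSAS).  Defaults to the instruments
#'   present in the data, with unknown scale ranges.
#' @param standardised Logical; `TRUE` marks effects already divided by
#'   the pooled SD.
#' @return An object of class `trial_dataset`: a list with elements
#'   `observations` (data frame in canonical order), `instruments`,
#'   and `standardised`.
#' @examples
#' ds <- social_anxiety_data()
#' ds
#' count_observations(ds)
#' @export
load_trials <- function(source, instruments = NULL, standardised = FALSE) {
  obs <- if (is.character(source)) {
    if (!file.exists(source)) stop("dataset file not found: ", source)
    read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }

  missing_cols <- setdiff(.required_cols, names(obs))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs <- obs[, .required_cols]

  num_cols <- c("arm_index", "n_control", "n_arm", "mean_diff", "se", "pooled_sd")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(obs[[cl]]))
    if (anyNA(v) && !all(is.na(obs[[cl]]) == is.na(v))) {
      stop("column '", cl, "' contains non-numeric values")
    }
    obs[[cl]] <- v
  }
  if (anyNA(obs$mean_diff) || anyNA(obs$se)) {
    stop("mean_diff and se must be present for every observation")
  }
  if (any(obs$se <= 0)) {
    bad <- obs[obs$se <= 0, ][1, ]
    stop("non-positive standard error in trial '", bad$trial_id,
         "', instrument '", bad$instrument, "'")
  }
  if (any(!is.na(obs$pooled_sd) & obs$pooled_sd <= 0)) {
    stop("pooled_sd must be positive where present")
  }
  if (any(obs$n_control <= 0) || any(obs$n_arm <= 0)) {
    stop("arm sample sizes must be positive")
  }
  key <- paste(obs$trial_id, obs$arm_index, obs$instrument, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (trial, arm, instrument) rows: ",
         paste(unique(obs$trial_id[duplicated(key)]), collapse = ", "))
  }
  nc <- tapply(obs$n_control, obs$trial_id, function(x) length(unique(x)))
  if (any(nc > 1)) {
    stop("inconsistent n_control within trial(s): ",
         paste(names(nc)[nc > 1], collapse = ", "))
  }

  if (is.null(instruments)) {
    instruments <- data.frame(instrument = unique(obs$instrument),
                              scale_range = NA_real_,
                              stringsAsFactors = FALSE)
  }
  if (!all(c("instrument", "scale_range") %in% names(instruments))) {
    stop("instrument metadata needs columns 'instrument' and 'scale_range'")
  }
  if (anyDuplicated(instruments$instrument)) {
    stop("instrument names must be unique")
  }
  if (any(!is.na(instruments$scale_range) & instruments$scale_range <= 0)) {
    stop("scale_range must be positive")
  }
  unknown <- setdiff(obs$instrument, instruments$instrument)
  if (length(unknown) > 0) {
    stop("observation(s) reference unknown instrument(s): ",
         paste(unknown, collapse = ", "))
  }

  # canonical row order
  trial_order <- unique(obs$trial_id)
  inst_order <- instruments$instrument
  obs <- obs[order(match(obs$trial_id, trial_order),
                   obs$arm_index,
                   match(obs$instrument, inst_order)), ]
  rownames(obs) <- NULL

  structure(list(observations = obs,
                 instruments = instruments,
                 standardised = isTRUE(standardised)),
            class = "trial_dataset")
}

#' Social anxiety SSRI trial network
#'
#' The packaged evidence base: 22 placebo-controlled trials of SSRI /
#' SNRI pharmacotherapy for social anxiety disorder (15 two-arm, 6
#' three-arm, 1 four-arm), reporting mean treatment differences on
#' between one and six of nine rating scales (88 observations in all).
#' Scale ranges: LSAS 144, CGI-S 7, BSPS 72, FNE 30, FQ-SP 40, SADS 28,
#' SPAI-SP 192, SDS 30, SPIN 68 points.
#'
#' @return A [trial_dataset].
#' @export
social_anxiety_data <- function() {
  load_trials(system.file("extdata", "social_anxiety_trials.csv",
                          package = "mapmeta", mustWork = TRUE),
              instruments = social_anxiety_instruments())
}

#' @rdname social_anxiety_data
#' @export
social_anxiety_instruments <- function() {
  read.csv(system.file("extdata", "social_anxiety_instruments.csv",
                       package = "mapmeta", mustWork = TRUE),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Count observed mean differences
#'
#' Total number of observed mean treatment differences across all
#' trials, active arms and instruments.
#'
#' @param ds A [trial_dataset].
#' @return Non-negative integer.
#' @export
count_observations <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  nrow(ds$observations)
}

#' Standardise a dataset by pooled SDs
#'
#' Divides each observed mean difference and its standard error by the
#' observation's own pooled SD (Cohen's d style standardisation,
#' applied per instrument within each trial), sets the stored pooled SD
#' to 1 and flags the dataset as standardised.
#'
#' @param ds A [trial_dataset].
#' @return A standardised [trial_dataset].  The original pooled SDs are
#'   kept in the `original_sd` column so the transformation can be
#'   inverted.
#' @export
standardise_dataset <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (isTRUE(ds$standardised)) {
    stop("dataset is already standardised")
  }
  obs <- ds$observations
  if (anyNA(obs$pooled_sd)) {
    bad <- obs[is.na(obs$pooled_sd), ][1, ]
    stop("missing pooled SD for trial '", bad$trial_id,
         "', instrument '", bad$instrument, "'")
  }
  obs$original_sd <- obs$pooled_sd
  obs$mean_diff <- obs$mean_diff / obs$pooled_sd
  obs$se <- obs$se / obs$pooled_sd
  obs$pooled_sd <- 1
  out <- ds
  out$observations <- obs
  out$standardised <- TRUE
  out
}

#' Write a trial dataset back to CSV
#'
#' Writes the same CSV dialect read by [load_trials()], so that
#' load -> write -> load round-trips.
#'
#' @param ds A [trial_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  write.csv(ds$observations[, .required_cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Co-reporting network of test instruments
#'
#' Builds the graph whose nodes are instruments and whose edge between
#' instruments h and k carries the number of trials reporting both.
#' Mapping ratios are only identifiable within a connected component,
#' so disconnection is reported here and enforced at model build.
#'
#' @param ds A [trial_dataset].
#' @return An object of class `instrument_network`: list with `nodes`,
#'   `edges` (data frame `from`, `to`, `n_trials`), `membership`
#'   (component id per node) and `n_components`.
#' @export
instrument_network <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  obs <- ds$observations
  nodes <- ds$instruments$instrument
  pairs <- list()
  for (tid in unique(obs$trial_id)) {
    ins <- sort(unique(obs$instrument[obs$trial_id == tid]))
    if (length(ins) >= 2) {
      cmb <- utils::combn(ins, 2)
      pairs[[tid]] <- data.frame(from = cmb[1, ], to = cmb[2, ],
                                 stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) > 0) {
    pr <- do.call(rbind, pairs)
    key <- paste(pr$from, pr$to, sep = "\r")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    edges <- data.frame(from = parts[, 1], to = parts[, 2],
                        n_trials = as.integer(tab),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        n_trials = integer(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  structure(list(nodes = nodes,
                 edges = edges,
                 membership = setNames(as.integer(comp$membership), nodes),
                 n_components = comp$no),
            class = "instrument_network")
}

#' @export
print.trial_dataset <- function(x, ...) {
  obs <- x$observations
  cat("<trial_dataset> ", length(unique(obs$trial_id)), " trials, ",
      length(unique(obs$instrument)), " instruments, ",
      nrow(obs), " observed mean differences",
      if (isTRUE(x$standardised)) " (standardised)" else "", "\n", sep = "")
  arms <- tapply(obs$arm_index, obs$trial_id, function(a) length(unique(a)))
  cat("  active arms per trial: ",
      paste(names(table(arms)), "arm:", table(arms), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.instrument_network <- function(x, ...) {
  cat("<instrument_network> ", length(x$nodes), " instruments, ",
      nrow(x$edges), " edges, ", x$n_components, " connected component",
      if (x$n_components != 1) "s", "\n", sep = "")
  if (x$n_components > 1) {
    for (cc in seq_len(x$n_components)) {
      cat("  component ", cc, ": ",
          paste(names(x$membership)[x$membership == cc], collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
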