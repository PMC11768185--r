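# Model-qualification statistics: fold errors, AFE/AAFE, classification
# bands, two-fold coverage and visual-predictive-check percentile bands.

check_pairs <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length")
  }
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("fold-error statistics are undefined for zero or negative values")
  }
}

#' Per-observation fold errors
#'
#' Elementwise `predicted / observed`.
#'
#' @param predicted,observed strictly positive vectors of equal length.
#' @return Numeric vector of fold errors.
#' @export
fold_errors <- function(predicted, observed) {
  check_pairs(predicted, observed)
  predicted / observed
}

#' Average fold error (AFE)
#'
#' `10^(mean(log10(predicted/observed)))`: the geometric mean fold error,
#' sensitive to systematic over- or under-prediction. Swapping the inputs
#' inverts it.
#'
#' @inheritParams fold_errors
#' @return Dimensionless AFE.
#' @export
afe <- function(predicted, observed) {
  10^mean(log10(fold_errors(predicted, observed)))
}

#' Absolute average fold error (AAFE)
#'
#' `10^(mean(|log10(predicted/observed)|))`: the spread-type companion of
#' the AFE; always >= 1 and invariant to swapping inputs.
#'
#' @inheritParams fold_errors
#' @return Dimensionless AAFE (>= 1).
#' @export
aafe <- function(predicted, observed) {
  10^mean(abs(log10(fold_errors(predicted, observed))))
}

#' Classify an AFE or AAFE value
#'
#' AFE: satisfactory in `[0.8, 1.25]`; acceptable in `[0.5, 0.8)` or
#' `(1.25, 2]`; poor otherwise. AAFE: satisfactory `<= 1.25`; acceptable in
#' `(1.25, 2]`; poor `> 2`.
#'
#' @param value positive metric value.
#' @param which `"AFE"` or `"AAFE"`.
#' @return `"satisfactory"`, `"acceptable"` or `"poor"`.
#' @export
classify_metric <- function(value, which = c("AFE", "AAFE")) {
  which <- match.arg(which)
  if (!is.numeric(value) || value <= 0) {
    abort_field("value", "must be > 0")
  }
  if (which == "AFE") {
    if (value >= 0.8 && value <= 1.25) return("satisfactory")
    if ((value >= 0.5 && value < 0.8) || (value > 1.25 && value <= 2)) {
      return("acceptable")
    }
    return("poor")
  }
  if (value <= 1.25) return("satisfactory")
  if (value <= 2) return("acceptable")
  "poor"
}

#' Percentage of observations within a fold range
#'
#' `100 * mean(1/fold <= FE <= fold)`; the boundary counts as within.
#'
#' @inheritParams fold_errors
#' @param fold fold bound (> 1); 2 for the classical two-fold criterion.
#' @return Percentage in `[0, 100]`.
#' @export
pct_within_fold <- function(predicted, observed, fold = 2) {
  if (fold <= 1) abort_field("fold", "must be > 1")
  fe <- fold_errors(predicted, observed)
  100 * mean(fe >= 1 / fold & fe <= fold)
}

#' Match model predictions to observation times
#'
#' Linear interpolation of a simulated profile at each observation time.
#'
#' @param profile data.frame with `time`, `conc`.
#' @param obs_time observation times within the profile's time span.
#' @return Interpolated predicted concentrations.
#' @export
predict_at <- function(profile, obs_time) {
  approx(profile$time, profile$conc, xout = obs_time, rule = 2)$y
}

#' Visual-predictive-check percentile bands and outlier count
#'
#' Pointwise percentiles of a simulated ensemble on its common time grid;
#' an observation is an outlier when it lies strictly outside the lower and
#' upper band interpolated at its time.
#'
#' @param ensemble matrix (profiles x time points) of simulated
#'   concentrations on a common grid.
#' @param time common time grid (length = ncol(ensemble)).
#' @param observations optional data.frame with `time`, `conc`.
#' @param percentiles three percentiles (lower, median, upper), default
#'   `c(5, 50, 95)`.
#' @return List with `bands` (data.frame time/lower/median/upper),
#'   `n_outliers`, `outlier` (logical per observation).
#' @export
vpc_percentiles <- function(ensemble, time, observations = NULL,
                            percentiles = c(5, 50, 95)) {
  if (is.null(dim(ensemble)) || nrow(ensemble) < 1L) {
    stop("empty ensemble")
  }
  if (ncol(ensemble) != length(time)) {
    stop("ensemble columns must match the time grid")
  }
  qs <- apply(ensemble, 2, quantile, probs = percentiles / 100, names = FALSE)
  bands <- data.frame(time = time, lower = qs[1, ], median = qs[2, ],
                      upper = qs[3, ])
  n_out <- NA_integer_; flag <- NULL
  if (!is.null(observations)) {
    lo <- approx(time, bands$lower, xout = observations$time, rule = 2)$y
    hi <- approx(time, bands$upper, xout = observations$time, rule = 2)$y
    flag <- observations$conc < lo | observations$conc > hi
    n_out <- sum(flag)
  }
  list(bands = bands, n_outliers = n_out, outlier = flag)
}

#' Full evaluation report
#'
#' Fold errors, AFE/AAFE with classification, fold-coverage percentages
#' (at the configured inner fold line and at 2-fold) for a predicted/
#' observed pair. Observed zeros are excluded with a recorded count (the
#' log-domain statistics are undefined at zero).
#'
#' @param predicted,observed concentration vectors (equal length, >= 0).
#' @param config a [pbpk_config()] (supplies the inner fold line).
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(predicted, observed, config = pbpk_config()) {
  keep <- observed > 0 & predicted > 0
  n_excluded <- sum(!keep)
  predicted <- predicted[keep]; observed <- observed[keep]
  if (length(observed) == 0L) stop("no usable observation pairs")
  a <- afe(predicted, observed)
  aa <- aafe(predicted, observed)
  structure(list(
    n = length(observed), n_excluded_zero = n_excluded,
    fold_errors = fold_errors(predicted, observed),
    afe = a, aafe = aa,
    afe_class = classify_metric(a, "AFE"),
    aafe_class = classify_metric(aa, "AAFE"),
    pct_within_2fold = pct_within_fold(predicted, observed, 2),
    pct_within_fold_line = pct_within_fold(predicted, observed,
                                           config$fold_line),
    fold_line = config$fold_line
  ), class = "evaluation_report")
}

#' Goodness-of-fit plot
#'
#' Observed vs predicted concentrations on log axes with the identity line,
#' the inner fold-error lines and the two-fold lines.
#'
#' @inheritParams evaluation_report
#' @return A ggplot object.
#' @export
gof_plot <- function(predicted, observed, config = pbpk_config()) {
  keep <- observed > 0 & predicted > 0
  df <- data.frame(observed = observed[keep], predicted = predicted[keep])
  fl <- config$fold_line
  ggplot2::ggplot(df, ggplot2::aes(x = observed, y = predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = log10(c(fl, 1 / fl)),
                         colour = "darkgreen", linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = log10(c(2, 0.5)),
                         colour = "blue", linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Observed concentration (µmol/L)",
                  y = "Predicted concentration (µmol/L)")
}
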