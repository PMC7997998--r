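# The threshold permeability model and the descriptor-benchmarking
# statistics: a probe with LogP >= 1 is called cell-permeant, below 1
# impermeant, and each LogP descriptor is scored by how well that rule
# recovers the curated permeability labels.

#' Threshold classifier configuration
#'
#' @param threshold Decision threshold on the LogP scale; the default 1.0 is
#'   the established permeability cut-off. The rule direction is fixed:
#'   `LogP >= threshold` is classified permeant.
#' @return List of class `fl_classifier_config`.
#' @export
classifier_config <- function(threshold = 1.0) {
  stopifnot(is.finite(threshold))
  structure(list(threshold = threshold, rule = ">="),
            class = "fl_classifier_config")
}

#' Classify LogP values as permeant/impermeant
#'
#' `permeant` iff `logp >= threshold` (a value exactly at the threshold is
#' permeant).
#'
#' @param logp Numeric LogP value(s); must be finite (`NA` propagates,
#'   `NaN` is an error).
#' @param config A [classifier_config()].
#' @return Character vector in `{"permeant", "impermeant"}` (NA for NA
#'   input).
#' @examples
#' classify_permeability(c(1, 0.999, -0.01))
#' @export
classify_permeability <- function(logp, config = classifier_config()) {
  stopifnot(inherits(config, "fl_classifier_config"))
  if (any(is.nan(logp))) {
    stop("NaN LogP value(s)", call. = FALSE)
  }
  ifelse(is.na(logp), NA_character_,
         ifelse(logp >= config$threshold, "permeant", "impermeant"))
}

#' Evaluate a LogP descriptor against permeability labels
#'
#' Applies the threshold rule to the descriptor values and scores the result
#' against curated labels: per-class fractions on the correct side of the
#' threshold (also rounded to whole percent, half up, matching the usual
#' reporting style), pooled accuracy, the confusion counts, and a Welch
#' t-test comparing descriptor means between classes. Missing descriptor
#' values are excluded from all statistics and reported in `missing`.
#'
#' @param values Numeric descriptor values (NA = descriptor unavailable for
#'   that molecule).
#' @param labels Character/factor labels, `"permeant"` or `"impermeant"`.
#' @param config A [classifier_config()].
#' @param descriptor_name Name carried into the result (used by ranking).
#' @return List of class `fl_descriptor_eval` with fields
#'   `descriptor_name`, `n_permeant`, `n_impermeant`,
#'   `frac_permeant_ge_threshold`, `frac_impermeant_lt_threshold`,
#'   `pct_permeant_ge_threshold`, `pct_impermeant_lt_threshold`,
#'   `accuracy`, `confusion` (TP, FN, TN, FP), `ttest`, `missing`.
#' @export
evaluate_descriptor <- function(values, labels, config = classifier_config(),
                                descriptor_name = "descriptor") {
  if (length(values) != length(labels)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  labels <- as.character(labels)
  bad <- !labels %in% c("permeant", "impermeant")
  if (any(bad)) {
    stop("labels must be 'permeant' or 'impermeant'; found: ",
         paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(values)
  n_missing <- sum(!keep)
  values <- values[keep]
  labels <- labels[keep]
  n_perm <- sum(labels == "permeant")
  n_imp <- sum(labels == "impermeant")
  if (n_perm == 0L || n_imp == 0L) {
    stop("both classes must be represented (permeant: ", n_perm,
         ", impermeant: ", n_imp, ")", call. = FALSE)
  }
  pred <- classify_permeability(values, config)
  tp <- sum(pred == "permeant" & labels == "permeant")
  fn <- sum(pred == "impermeant" & labels == "permeant")
  tn <- sum(pred == "impermeant" & labels == "impermeant")
  fp <- sum(pred == "permeant" & labels == "impermeant")
  frac_perm <- tp / n_perm
  frac_imp <- tn / n_imp
  round_half_up <- function(x) floor(x * 100 + 0.5)
  structure(
    list(
      descriptor_name = descriptor_name,
      n_permeant = n_perm, n_impermeant = n_imp,
      frac_permeant_ge_threshold = frac_perm,
      frac_impermeant_lt_threshold = frac_imp,
      pct_permeant_ge_threshold = round_half_up(frac_perm),
      pct_impermeant_lt_threshold = round_half_up(frac_imp),
      accuracy = (tp + tn) / (tp + fn + tn + fp),
      confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
      ttest = tryCatch(
        welch_ttest(values[labels == "permeant"],
                    values[labels == "impermeant"]),
        error = function(e) NULL),  # e.g. a class of size 1
      missing = n_missing
    ),
    class = "fl_descriptor_eval"
  )
}

#' Welch two-sample t-test
#'
#' Two-independent-sample t-test with unequal variances
#' (Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param a,b Numeric samples of size >= 2 each; at least one must have
#'   nonzero variance.
#' @return List of class `fl_ttest`: `t_statistic`, `p_value`, `df`,
#'   `mean_a`, `mean_b`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(t_statistic = 0, p_value = 1, df = NA_real_,
                            mean_a = mean(a), mean_b = mean(b)),
                       class = "fl_ttest"))
    }
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(
    list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b)),
    class = "fl_ttest"
  )
}

#' Regression quality metrics
#'
#' Coefficient of determination `R^2 = 1 - SS_res/SS_tot` and mean squared
#' error of predictions against experimental values.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return List with `r_squared` and `mse`.
#' @examples
#' regression_metrics(c(0, 1, 2), c(0, 1, 3))  # R^2 = 0.5, MSE = 1/3
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop("y_true and y_pred must be non-empty and of equal length",
         call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("y_true has zero variance; R^2 is undefined", call. = FALSE)
  }
  ss_res <- sum((y_true - y_pred)^2)
  list(r_squared = 1 - ss_res / ss_tot,
       mse = mean((y_true - y_pred)^2))
}

#' Rank descriptor evaluations by accuracy
#'
#' Descending accuracy; exact ties broken alphabetically by descriptor name
#' so the ranking is deterministic.
#'
#' @param evals List of `fl_descriptor_eval` objects.
#' @return The same list, reordered; names set to descriptor names.
#' @export
rank_descriptors <- function(evals) {
  if (!length(evals)) {
    stop("need at least one evaluation", call. = FALSE)
  }
  acc <- vapply(evals, function(e) e$accuracy, numeric(1))
  nm <- vapply(evals, function(e) e$descriptor_name, character(1))
  ord <- order(-acc, nm)
  out <- evals[ord]
  names(out) <- nm[ord]
  out
}

#' Box-plot summary statistics
#'
#' Quartiles plus 1.5 IQR whiskers (clamped to the data range), emitted as
#' numbers -- the quantities a distribution box plot draws.
#'
#' @param values Numeric vector.
#' @return Named numeric vector: `lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`, `n_outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  c(lower_whisker = min(values[values >= lo_fence]),
    q1 = q[1], median = q[2], q3 = q[3],
    upper_whisker = max(values[values <= hi_fence]),
    n_outliers = sum(values < lo_fence | values > hi_fence))
}
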