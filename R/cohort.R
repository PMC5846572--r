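# Cohort-level analysis: percentile summaries of per-subject metrics and
# the four-level classification of glycemic variability.

GVP_CLASS_LEVELS <- c("minimal", "low", "moderate", "high")

#' Percentile summary of per-subject metric values
#'
#' Summarizes a cohort's per-subject metric by percentiles at levels
#' 0, 2.5, 25, 50, 75, 97.5 and 100 (minimum, outer 2.5% tails, quartile
#' bounds, maximum), using linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values Numeric vector of per-subject metric values (all finite,
#'   at least one).
#' @param cohort_label Label for the cohort.
#' @param metric_name Name of the summarized metric (default `"GVP"`).
#' @param levels Percentile levels in `[0, 100]`.
#' @return A `cohort_summary`: list with a `percentiles` tibble
#'   (`percentile`, `value`), `cohort_label`, `metric_name`, `n_subjects`.
#' @examples
#' percentile_summary(c(10, 20, 30, 40), "demo")
#' @export
percentile_summary <- function(values, cohort_label, metric_name = "GVP",
                               levels = c(0, 2.5, 25, 50, 75, 97.5, 100)) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values))) {
    stop("insufficient data: `values` must contain at least one finite value",
         call. = FALSE)
  }
  if (any(levels < 0 | levels > 100)) {
    stop("`levels` must lie in [0, 100]", call. = FALSE)
  }
  q <- unname(stats::quantile(values, probs = levels / 100, type = 7))
  structure(
    list(percentiles = tibble::tibble(percentile = levels, value = q),
         cohort_label = cohort_label, metric_name = metric_name,
         n_subjects = length(values)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s, metric %s, n = %d\n",
              x$cohort_label, x$metric_name, x$n_subjects))
  print(x$percentiles, n = nrow(x$percentiles))
  invisible(x)
}

#' Classify a GVP value into a variability band
#'
#' Four bands: minimal (GVP <= 20, typical of non-diabetic traces), low
#' (20 < GVP <= 30), moderate (30 < GVP <= 50) and high (GVP > 50).
#' Values falling exactly on a boundary take the lower band, so every
#' value has exactly one label.
#'
#' @param gvp_percent Numeric vector of GVP values in percent (>= 0).
#' @return Ordered factor with levels minimal < low < moderate < high.
#' @examples
#' classify_gvp(c(18.2, 29, 42.3, 52))
#' @export
classify_gvp <- function(gvp_percent) {
  gvp_percent <- as.numeric(gvp_percent)
  if (anyNA(gvp_percent) || any(gvp_percent < 0)) {
    stop("`gvp_percent` must be non-negative", call. = FALSE)
  }
  cut(gvp_percent, breaks = c(-Inf, 20, 30, 50, Inf),
      labels = GVP_CLASS_LEVELS, right = TRUE, ordered_result = TRUE)
}

#' Per-subject GVP report for a cohort of traces
#'
#' Computes GVP for each trace, classifies it, and assembles the
#' percentile summary.  Subjects whose trace cannot support a GVP
#' computation (e.g. all runs singletons after gap splitting) are flagged
#' in the per-subject table rather than aborting the whole cohort, and are
#' excluded from the summary and the class fractions.
#'
#' @param traces List of [glucose_trace()] objects (at least one).
#' @param cohort_label Label for the cohort.
#' @param gap_threshold Minutes; passed to [gvp()].
#' @return List with `summary` (a `cohort_summary` of GVP), `subjects`
#'   (tibble: `subject`, `gvp_percent`, `class`, `note`), and
#'   `class_fractions` (named numeric over the four bands, summing to 1
#'   over non-flagged subjects).
#' @examples
#' coh <- synth_cohort(5, duration_h = 24, seed = 7)
#' cohort_report(coh, "demo")$class_fractions
#' @export
cohort_report <- function(traces, cohort_label, gap_threshold = NULL) {
  if (!is.list(traces) || length(traces) < 1L) {
    stop("insufficient data: `traces` must be a non-empty list", call. = FALSE)
  }
  vals <- vapply(traces, function(tr) {
    tryCatch(gvp(tr, gap_threshold)$gvp_percent,
             error = function(e) NA_real_)
  }, numeric(1))
  note <- ifelse(is.na(vals), "insufficient data", "")
  cls <- factor(rep(NA_character_, length(vals)),
                levels = GVP_CLASS_LEVELS, ordered = TRUE)
  cls[!is.na(vals)] <- classify_gvp(vals[!is.na(vals)])
  subjects <- tibble::tibble(
    subject = seq_along(traces),
    gvp_percent = vals,
    class = cls,
    note = note
  )
  ok <- vals[!is.na(vals)]
  if (length(ok) < 1L) {
    stop("insufficient data: no subject yielded a GVP value", call. = FALSE)
  }
  fr <- table(factor(cls[!is.na(vals)], levels = GVP_CLASS_LEVELS))
  frac <- as.numeric(fr) / sum(fr)
  names(frac) <- GVP_CLASS_LEVELS
  list(
    summary = percentile_summary(ok, cohort_label, metric_name = "GVP"),
    subjects = subjects,
    class_fractions = frac
  )
}
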