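# Kaplan-Meier estimation with isoform-expression cutoff grouping and
# survival start-time filtering. Grouping and filtering semantics are the
# package's own; the product-limit estimate itself is delegated to
# survival::survfit and re-shaped into the km_curve container.

#' Assemble survival samples
#'
#' @param sample_id Character vector.
#' @param time Non-negative follow-up times (days).
#' @param event 0 (censored) / 1 (death).
#' @param expression Non-negative isoform expression used for grouping.
#' @return Data frame of class `survival_samples`.
#' @export
survival_samples <- function(sample_id, time, event, expression) {
  stopifnot(length(sample_id) == length(time),
            length(time) == length(event),
            length(event) == length(expression))
  if (any(is.na(time)) || any(time < 0)) stop("time must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(is.na(expression)) || any(expression < 0)) {
    stop("expression must be non-negative")
  }
  structure(data.frame(sample_id = as.character(sample_id), time = time,
                       event = event, expression = expression,
                       stringsAsFactors = FALSE),
            class = c("survival_samples", "data.frame"))
}

#' Split survival samples at an expression cutoff
#'
#' The default cutoff is the middle of the isoform expression range,
#' `(min + max) / 2`. Samples with expression strictly below the cutoff
#' form the low group; expression equal to the cutoff goes to the high
#' group (deterministic tie rule). An empty group raises a warning, not an
#' error.
#'
#' @param samples A `survival_samples` data frame (>= 2 rows).
#' @param cutoff Numeric cutoff or `"default"` (range midpoint).
#' @return List with `low`, `high` (both `survival_samples`), `cutoff`,
#'   and `sizes` (named integer vector).
#' @export
split_by_cutoff <- function(samples, cutoff = "default") {
  stopifnot(nrow(samples) >= 2)
  if (identical(cutoff, "default")) {
    cutoff <- (min(samples$expression) + max(samples$expression)) / 2
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  low <- samples[samples$expression < cutoff, , drop = FALSE]
  high <- samples[samples$expression >= cutoff, , drop = FALSE]
  if (nrow(low) == 0 || nrow(high) == 0) {
    warning("empty group at cutoff ", format(cutoff),
            "; curves computed for the nonempty group only")
  }
  list(low = low, high = high, cutoff = cutoff,
       sizes = c(low = nrow(low), high = nrow(high)))
}

#' Filter survival samples by a start time
#'
#' Retains samples with `time >= start_time` and re-zeroes retained times
#' to `time - start_time`. This is a plain filter on the displayed cohort,
#' not a delayed-entry (left-truncation) risk-set adjustment.
#'
#' @param samples A `survival_samples` data frame.
#' @param start_time Non-negative number of days.
#' @return Filtered, re-zeroed `survival_samples`.
#' @export
filter_start_time <- function(samples, start_time) {
  stopifnot(is.numeric(start_time), length(start_time) == 1L, start_time >= 0)
  keep <- samples$time >= start_time
  out <- samples[keep, , drop = FALSE]
  out$time <- out$time - start_time
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time t_k with d_k deaths among r_k at risk the
#' survival drops by the factor (1 - d_k/r_k); censored-only times reduce
#' the risk set but add no step. The returned curve starts at the origin
#' (t = 0, S = 1, all at risk) followed by one point per distinct event
#' time. Censoring times are kept for plot tick marks.
#'
#' @param samples A `survival_samples` data frame (or any data frame with
#'   `time` and `event` columns), >= 1 row.
#' @param group_label Label attached to the curve.
#' @return Object of class `km_curve`: list with `times`, `survival`,
#'   `at_risk`, `group_label`, `n`, `censor_times`.
#' @export
km_estimate <- function(samples, group_label = "all") {
  stopifnot(nrow(samples) >= 1)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data.frame(time = samples$time, event = samples$event))
  ev <- fit$n.event > 0
  structure(list(
    times = c(0, fit$time[ev]),
    survival = c(1, fit$surv[ev]),
    at_risk = c(nrow(samples), fit$n.risk[ev]),
    group_label = group_label,
    n = nrow(samples),
    censor_times = rep(fit$time, fit$n.censor)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve '%s': n = %d, %d event time(s), final S = %.4f\n",
              x$group_label, x$n, length(x$times) - 1L,
              x$survival[length(x$survival)]))
  invisible(x)
}

#' Grouped Kaplan-Meier curves at an expression cutoff
#'
#' Convenience composition: start-time filter, cutoff split, one
#' product-limit curve per nonempty group.
#'
#' @param samples A `survival_samples` data frame.
#' @param cutoff Numeric or `"default"` (see [split_by_cutoff()]).
#' @param start_time Survival start-time filter (days), default 0.
#' @return List with `curves` (list of `km_curve`), `cutoff`, `sizes`.
#' @export
km_by_cutoff <- function(samples, cutoff = "default", start_time = 0) {
  samples <- filter_start_time(samples, start_time)
  if (nrow(samples) < 2) stop("fewer than 2 samples after start-time filter")
  sp <- split_by_cutoff(samples, cutoff)
  curves <- list()
  if (nrow(sp$low) > 0) {
    curves <- c(curves, list(km_estimate(
      sp$low, sprintf("expression < %.4g (n = %d)", sp$cutoff, nrow(sp$low)))))
  }
  if (nrow(sp$high) > 0) {
    curves <- c(curves, list(km_estimate(
      sp$high, sprintf("expression >= %.4g (n = %d)", sp$cutoff, nrow(sp$high)))))
  }
  list(curves = curves, cutoff = sp$cutoff, sizes = sp$sizes)
}

#' Log-rank test between two groups (beyond the core display)
#'
#' The rendered figures show curves only; this test is an optional extra
#' for users who want a p-value for the cutoff grouping.
#'
#' @param low,high `survival_samples` data frames.
#' @return List with `chisq` and `p_value`.
#' @export
km_logrank <- function(low, high) {
  df <- rbind(data.frame(time = low$time, event = low$event, g = "low"),
              data.frame(time = high$time, event = high$event, g = "high"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Export Kaplan-Meier curves as TSV
#'
#' Columns: `time`, `survival`, `at_risk`, `group`.
#'
#' @param curves A `km_curve` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_km_tsv <- function(curves, path) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk, group = cv$group_label,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
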