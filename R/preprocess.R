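# Trial- and participant-level exclusion rules.

#' Apply the trial-exclusion rules
#'
#' Removes, with per-trial attribution:
#' \enumerate{
#'   \item trials with discrimination RT outside 200-1000 ms
#'     (`rt_out_of_range`);
#'   \item adjustment-error outliers in a fixed two-step procedure: first
#'     errors larger than +/-45 degrees (`error_gt_45`), then, among the
#'     surviving errors, values beyond `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#'     computed per participant with interpolated quartiles
#'     (`error_iqr_outlier`);
#'   \item adjustment responses slower than 10 s (`adjustment_too_slow`).
#' }
#' A trial is removed if it carries any flag; the +/-45-degree step strictly
#' precedes the IQR fence and the fence is applied in a single pass (not
#' iterated).
#'
#' @param trials An annotated trial table (see [annotate_trials()]).
#' @return A list with `clean` (the retained trials) and `report` (an
#'   `exclusion_report`: per-trial flags, per-participant and per-criterion
#'   counts, retained fractions).
#' @export
exclude_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("exclude_trials(): empty or invalid input")
  if (!"adjustment_error" %in% names(trials))
    stop("exclude_trials(): trials must be annotated (missing adjustment_error)")

  rt_out_of_range <- trials$discrimination_rt < 200 | trials$discrimination_rt > 1000
  error_gt_45 <- abs(trials$adjustment_error) > 45
  adjustment_too_slow <- trials$adjustment_rt > 10000

  error_iqr_outlier <- rep(FALSE, nrow(trials))
  for (p in unique(trials$participant_id)) {
    sel <- trials$participant_id == p & !error_gt_45
    e <- trials$adjustment_error[sel]
    if (length(e) >= 4) {
      q <- stats::quantile(e, c(0.25, 0.75), type = 7, names = FALSE)
      fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
      error_iqr_outlier[sel] <- e < fence[1] | e > fence[2]
    }
  }

  flags <- data.frame(participant_id = trials$participant_id,
                      rt_out_of_range = rt_out_of_range,
                      error_gt_45 = error_gt_45,
                      error_iqr_outlier = error_iqr_outlier,
                      adjustment_too_slow = adjustment_too_slow,
                      stringsAsFactors = FALSE)
  removed <- rt_out_of_range | error_gt_45 | error_iqr_outlier | adjustment_too_slow

  per_participant <- do.call(rbind, lapply(unique(trials$participant_id), function(p) {
    sel <- trials$participant_id == p
    data.frame(participant_id = p,
               n_trials = sum(sel),
               n_removed = sum(removed[sel]),
               retained_fraction = 1 - mean(removed[sel]),
               stringsAsFactors = FALSE)
  }))
  if (any(per_participant$retained_fraction == 0))
    warning("all trials removed for participant(s): ",
            paste(per_participant$participant_id[per_participant$retained_fraction == 0],
                  collapse = ", "))

  report <- structure(list(
    trial_flags = flags,
    removed = removed,
    counts = c(rt_out_of_range = sum(rt_out_of_range),
               error_gt_45 = sum(error_gt_45),
               error_iqr_outlier = sum(error_iqr_outlier),
               adjustment_too_slow = sum(adjustment_too_slow),
               total_removed = sum(removed)),
    per_participant = per_participant,
    overall_retained_fraction = 1 - mean(removed)),
    class = "exclusion_report")
  list(clean = trials[!removed, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Trial exclusion report\n")
  cat(sprintf("  retained %.1f%% of %d trials\n",
              100 * x$overall_retained_fraction, nrow(x$trial_flags)))
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  if (!is.null(x$participants_excluded))
    cat("  participants removed:",
        if (length(x$participants_excluded)) paste(x$participants_excluded, collapse = ", ")
        else "none", "\n")
  invisible(x)
}

#' Apply the participant-exclusion rules
#'
#' Removes participants with (1) more than 25% of trials flagged as
#' outliers, (2) a circular correlation between reported and presented
#' orientation lower than 0.4, or (3) discrimination accuracy or mean
#' discrimination RT more than 3 standard deviations from the group mean
#' (group statistics over all participants, computed before any removal at
#' this step; two-sided; applied to both measures).
#'
#' The circular-correlation and discrimination statistics are computed on
#' trials surviving the response-validity rules (RT window, adjustment
#' timeout) but not the error-based rules: conditioning the
#' quality screen on the adjustment error itself would retain exactly the
#' responses that happen to lie near the probe and so mask a random
#' responder (a uniform responder's retained-trial correlation comes out
#' near 0.4 instead of near 0).
#'
#' @param trials The annotated trial table (all presented trials).
#' @param report The `exclusion_report` from [exclude_trials()].
#' @param outlier_fraction,min_circular_correlation,group_sd Thresholds for
#'   the three rules.
#' @return A list with `kept` (participant ids), `clean` (retained trials of
#'   kept participants) and the updated `report` (a `participants` element
#'   with per-participant flags).
#' @export
exclude_participants <- function(trials, report,
                                 outlier_fraction = 0.25,
                                 min_circular_correlation = 0.4,
                                 group_sd = 3) {
  if (!inherits(report, "exclusion_report"))
    stop("report must come from exclude_trials()")
  ids <- unique(trials$participant_id)
  pp <- report$per_participant
  too_many_outliers <- stats::setNames(
    (1 - pp$retained_fraction)[match(ids, pp$participant_id)] > outlier_fraction, ids)

  valid <- !(report$trial_flags$rt_out_of_range |
               report$trial_flags$adjustment_too_slow)
  retained <- trials[valid, , drop = FALSE]
  low_circ <- vapply(ids, function(p) {
    sel <- retained$participant_id == p
    if (sum(sel) < 3) return(TRUE)
    r <- tryCatch(circular_correlation(retained$reported_orientation[sel],
                                       retained$probe_orientation[sel]),
                  error = function(e) NA_real_)
    is.na(r) || r < min_circular_correlation
  }, logical(1))

  acc <- vapply(ids, function(p)
    mean(retained$discrimination_correct[retained$participant_id == p]), numeric(1))
  mrt <- vapply(ids, function(p)
    mean(retained$discrimination_rt[retained$participant_id == p]), numeric(1))
  if (length(ids) < 2) {
    warning("fewer than 2 participants: group-SD criterion skipped")
    discrim_outlier <- stats::setNames(rep(FALSE, length(ids)), ids)
  } else {
    zs <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else
      (x - mean(x)) / stats::sd(x)
    discrim_outlier <- stats::setNames(
      abs(zs(acc)) > group_sd | abs(zs(mrt)) > group_sd, ids)
  }

  excluded <- too_many_outliers | low_circ | discrim_outlier
  kept <- ids[!excluded]
  report$participants <- data.frame(
    participant_id = ids,
    too_many_outliers = unname(too_many_outliers),
    low_circular_correlation = unname(low_circ),
    discrimination_outlier = unname(discrim_outlier),
    excluded = unname(excluded),
    stringsAsFactors = FALSE)
  report$participants_excluded <- ids[excluded]
  clean <- trials[!report$removed, , drop = FALSE]
  list(kept = kept,
       clean = clean[clean$participant_id %in% kept, , drop = FALSE],
       report = report)
}
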