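# Trial-table schema: the single interchange format of the pipeline.
# One row per trial of the interleaved discrimination + adjustment design.

.trial_columns <- c(
  "participant_id", "session", "trial_index", "location_condition",
  "distractor_present", "distractor_orientation", "distractor_location",
  "probe_orientation", "reported_orientation", "discrimination_correct",
  "discrimination_rt", "adjustment_rt"
)

.derived_columns <- c(
  "adjustment_error", "delta_prev_probe", "delta_distractor",
  "prev_probe_distractor_delta"
)

#' Validate a trial table
#'
#' Checks the schema and per-row invariants of a trial table: all columns
#' present; orientations in `[0, 180)`; reaction times strictly positive;
#' `location_condition` one of `"random"`/`"fixed"`; distractor orientation
#' and location present if and only if `distractor_present` is `TRUE`.
#'
#' @param trials A data frame of trials.
#' @return The validated data frame, invisibly coerced to canonical column
#'   types. Violations raise an error listing the offending rows.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("trials must be a data frame")
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial table is missing column(s): ", paste(missing_cols, collapse = ", "))
  trials$participant_id <- as.character(trials$participant_id)
  trials$session <- as.integer(trials$session)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$location_condition <- as.character(trials$location_condition)
  trials$distractor_present <- as.logical(trials$distractor_present)
  trials$discrimination_correct <- as.logical(trials$discrimination_correct)
  for (col in c("distractor_orientation", "probe_orientation",
                "reported_orientation", "discrimination_rt", "adjustment_rt"))
    trials[[col]] <- as.numeric(trials[[col]])
  trials$distractor_location <- suppressWarnings(as.integer(trials$distractor_location))

  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- character(0)
  add <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(utils::head(rows, 10), collapse = ", "),
                                      if (length(rows) > 10) ", ..." else "", ")"))
  }
  ori_bad <- function(x) bad(x < 0 | x >= 180)
  add(ori_bad(trials$probe_orientation), "probe_orientation outside [0,180)")
  add(ori_bad(trials$reported_orientation), "reported_orientation outside [0,180)")
  add(ori_bad(trials$distractor_orientation), "distractor_orientation outside [0,180)")
  add(bad(trials$discrimination_rt <= 0), "non-positive discrimination_rt")
  add(bad(trials$adjustment_rt <= 0), "non-positive adjustment_rt")
  add(bad(!trials$location_condition %in% c("random", "fixed")),
      "location_condition not 'random'/'fixed'")
  add(bad(is.na(trials$distractor_present)), "missing distractor_present")
  add(bad(trials$distractor_present & is.na(trials$distractor_orientation)),
      "distractor_present but distractor_orientation missing")
  add(bad(trials$distractor_present & is.na(trials$distractor_location)),
      "distractor_present but distractor_location missing")
  add(bad(!trials$distractor_present & !is.na(trials$distractor_orientation)),
      "distractor_orientation given on distractor-absent trial")
  add(bad(!trials$distractor_present & !is.na(trials$distractor_location)),
      "distractor_location given on distractor-absent trial")
  key <- paste(trials$participant_id, trials$session)
  for (k in unique(key)) {
    idx <- trials$trial_index[key == k]
    if (any(diff(idx) <= 0))
      problems <- c(problems, paste0("trial_index not strictly increasing within ", k))
  }
  if (length(problems))
    stop("invalid trial table:\n  ", paste(problems, collapse = "\n  "))
  invisible(trials)
}

#' Read a trial table from delimited text
#'
#' @param path Path to a comma- or tab-separated file with a header naming
#'   every trial column. The delimiter is inferred from the header line.
#'   Empty fields or `NA` encode absent values.
#' @return A validated trial table (data frame).
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  trials <- utils::read.table(path, header = TRUE, sep = sep,
                              na.strings = c("", "NA"),
                              stringsAsFactors = FALSE)
  validate_trials(trials)
}

#' Write a trial table to delimited text
#'
#' Orientations are written at full double precision so that a write/read
#' round trip reproduces the table exactly.
#'
#' @param trials A trial table.
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma separation.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- trials
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  for (col in names(out)) out[[col]][is.na(trials[[col]])] <- NA
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Annotate trials with adjustment errors and orientation differences
#'
#' Adds the derived per-trial quantities on which all serial-dependence
#' analyses operate:
#' \describe{
#'   \item{adjustment_error}{`wrap_diff(reported, probe)`, degrees in
#'     (-90, 90]. Positive at positive delta means attraction toward the
#'     inducing stimulus.}
#'   \item{delta_prev_probe}{previous trial's probe orientation minus the
#'     current probe orientation, wrapped; `NA` on the first trial of each
#'     session (linkage never crosses a session boundary).}
#'   \item{delta_distractor}{current distractor orientation minus current
#'     probe orientation, wrapped; `NA` on distractor-absent trials.}
#'   \item{prev_probe_distractor_delta}{previous probe vs. current
#'     distractor, wrapped; `NA` when either is undefined.}
#' }
#' The previous trial is the immediately preceding *presented* trial within
#' the session, regardless of whether that trial is later excluded:
#' exclusion targets responses, but the stimulus was seen.
#'
#' @param trials A validated trial table sorted by participant, session,
#'   trial_index.
#' @return The table with the four derived columns appended. Deterministic
#'   and idempotent.
#' @export
annotate_trials <- function(trials) {
  trials <- validate_trials(trials)
  key <- paste(trials$participant_id, trials$session)
  ord_key <- order(match(key, unique(key)), trials$trial_index)
  if (any(ord_key != seq_len(nrow(trials))))
    stop("trials must be sorted by participant, session, trial_index")
  prev_probe <- c(NA_real_, trials$probe_orientation[-nrow(trials)])
  first_of_session <- !duplicated(key)
  prev_probe[first_of_session] <- NA_real_

  wd <- function(a, b) {  # NA-tolerant wrap_diff
    d <- (a - b) %% 180
    ifelse(d > 90, d - 180, d)
  }
  trials$adjustment_error <- wd(trials$reported_orientation, trials$probe_orientation)
  trials$delta_prev_probe <- wd(prev_probe, trials$probe_orientation)
  trials$delta_distractor <- ifelse(trials$distractor_present,
                                    wd(trials$distractor_orientation,
                                       trials$probe_orientation), NA_real_)
  trials$prev_probe_distractor_delta <-
    ifelse(trials$distractor_present,
           wd(prev_probe, trials$distractor_orientation), NA_real_)
  trials
}
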