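#' Read and write trial-level data
#'
#' Trial files are UTF-8 comma-separated text with a header row naming the
#' trial fields: `subject_id`, `item_id`, `list_id`, `phase`
#' (`encoding`/`test`), `task` (`ldt`/`semcat`), `blur`
#' (`clear`/`low`/`high`), `frequency` (`high`/`low`/`none`),
#' `stim_class` (`word`/`nonword`/`animal`/`nonanimal`), `status`
#' (`old`/`new`/`na`), `rt` (seconds), `response`, `accuracy` (0/1).
#' Response times are modelled in seconds throughout; files recorded in
#' milliseconds can be read with `rt_unit = "ms"` and are converted on
#' input.
#'
#' @param path file path.
#' @param rt_unit unit of the `rt` column in the file: `"s"` (default) or
#'   `"ms"`.
#' @param trials a trial tibble.
#' @return `read_trials()` returns a tibble of trials (RT in seconds);
#'   `write_trials()` writes `trials` to `path` and returns it invisibly.
#' @export
read_trials <- function(path, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trials <- tibble::as_tibble(raw)
  if (!"rt" %in% names(trials)) abort("trial file has no `rt` column.")
  if (rt_unit == "ms") trials$rt <- trials$rt / 1000
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(trials)
}

validate_trials <- function(trials) {
  needed <- c("subject_id", "rt")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) {
    abort(paste0("trial data lack required column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(trials)
}

new_exclusion_report <- function(n_input_trials, n_rt_trimmed = 0L,
                                 excluded_subjects = tibble::tibble(
                                   subject_id = character(), reason = character()
                                 ),
                                 n_retained = n_input_trials,
                                 n_nonpositive = 0L) {
  structure(
    list(
      n_input_trials = as.integer(n_input_trials),
      n_rt_trimmed = as.integer(n_rt_trimmed),
      pct_rt_trimmed = if (n_input_trials > 0) 100 * n_rt_trimmed / n_input_trials else 0,
      n_nonpositive = as.integer(n_nonpositive),
      excluded_subjects = excluded_subjects,
      n_retained = as.integer(n_retained)
    ),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  input trials:   %d\n", x$n_input_trials))
  cat(sprintf("  RT trimmed:     %d (%.2f%%)\n", x$n_rt_trimmed, x$pct_rt_trimmed))
  if (x$n_nonpositive > 0) {
    cat(sprintf("  (of which nonpositive RTs flagged: %d)\n", x$n_nonpositive))
  }
  if (nrow(x$excluded_subjects)) {
    cat(sprintf("  excluded subjects: %d\n", nrow(x$excluded_subjects)))
    tab <- table(x$excluded_subjects$reason)
    for (r in names(tab)) cat(sprintf("    %s: %d\n", r, tab[[r]]))
  }
  cat(sprintf("  trials retained: %d\n", x$n_retained))
  invisible(x)
}

#' Retrieve the exclusion report attached to a filtered trial set
#'
#' @param trials a tibble returned by [filter_rts()] or
#'   [exclude_participants()].
#' @return the `exclusion_report` object, or `NULL` if none is attached.
#' @export
exclusion_report <- function(trials) attr(trials, "exclusion_report")

#' Serialise an exclusion report as JSON
#'
#' @param report an `exclusion_report`.
#' @return a JSON string.
#' @export
exclusion_report_json <- function(report) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::toJSON(
    list(
      n_input_trials = report$n_input_trials,
      n_rt_trimmed = report$n_rt_trimmed,
      pct_rt_trimmed = report$pct_rt_trimmed,
      n_nonpositive = report$n_nonpositive,
      excluded_subjects = report$excluded_subjects,
      n_retained = report$n_retained
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' Trim fast and slow response times
#'
#' Removes trials with response times outside `[min_rt, max_rt]`. The
#' bounds are inclusive: removal applies to RTs strictly below `min_rt`
#' or strictly above `max_rt`, so boundary values are retained. The
#' defaults (0.2 s and 2.5 s) are the conventional fast/slow guesses and
#' timeout cutoffs for speeded word recognition. Nonpositive RTs are
#' always removed and separately flagged in the report. Input row order
#' is preserved; RT values and condition labels are never altered.
#'
#' @param trials a trial tibble with an `rt` column (seconds).
#' @param min_rt,max_rt inclusive retention bounds in seconds.
#' @return the retained trials, with an [exclusion_report()] attached as
#'   an attribute.
#' @examples
#' tr <- tibble::tibble(subject_id = "s1", rt = c(0.1, 0.5, 3.0))
#' kept <- filter_rts(tr)
#' exclusion_report(kept)
#' @export
filter_rts <- function(trials, min_rt = 0.2, max_rt = 2.5) {
  if (min_rt >= max_rt) abort("`min_rt` must be below `max_rt`.")
  validate_trials(trials)
  n_in <- nrow(trials)
  if (n_in == 0) {
    out <- trials
    attr(out, "exclusion_report") <- new_exclusion_report(0L, 0L, n_retained = 0L)
    return(out)
  }
  nonpos <- !is.na(trials$rt) & trials$rt <= 0
  keep <- !is.na(trials$rt) & trials$rt >= min_rt & trials$rt <= max_rt
  out <- trials[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- new_exclusion_report(
    n_input_trials = n_in,
    n_rt_trimmed = sum(!keep),
    n_retained = sum(keep),
    n_nonpositive = sum(nonpos)
  )
  out
}

#' Exclude participants by accuracy and by identifier lists
#'
#' Removes all trials of subjects whose overall encoding accuracy is
#' strictly below `accuracy_threshold` (the conventional "below 80%"
#' rule: subjects at exactly the threshold are retained), plus any
#' subjects named in `repeat_ids` (repeat participation) or
#' `underage_ids`. Accuracy is computed on all encoding-phase trials
#' before any RT trimming; subjects with zero encoding trials cannot
#' demonstrate threshold accuracy and are excluded with reason
#' `accuracy_below_threshold`.
#'
#' @param trials a trial tibble with `subject_id`, `accuracy`, and
#'   (optionally) `phase` columns.
#' @param accuracy_threshold proportion in (0, 1); default 0.80.
#' @param repeat_ids,underage_ids character vectors of subject ids to
#'   drop with the corresponding reason.
#' @return retained trials with an [exclusion_report()] attribute listing
#'   each excluded subject and its reason.
#' @export
exclude_participants <- function(trials, accuracy_threshold = 0.80,
                                 repeat_ids = character(),
                                 underage_ids = character()) {
  if (accuracy_threshold <= 0 || accuracy_threshold >= 1) {
    abort("`accuracy_threshold` must lie strictly between 0 and 1.")
  }
  validate_trials(trials)
  n_in <- nrow(trials)
  enc <- if ("phase" %in% names(trials)) {
    trials[trials$phase == "encoding", , drop = FALSE]
  } else {
    trials
  }
  all_ids <- unique(as.character(trials$subject_id))
  acc <- enc |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  low_acc <- as.character(acc$subject_id[acc$accuracy < accuracy_threshold])
  no_trials <- setdiff(all_ids, as.character(acc$subject_id))
  excluded <- dplyr::bind_rows(
    tibble::tibble(subject_id = as.character(repeat_ids), reason = "repeat"),
    tibble::tibble(subject_id = as.character(underage_ids), reason = "underage"),
    tibble::tibble(subject_id = c(low_acc, no_trials), reason = "accuracy_below_threshold")
  ) |>
    dplyr::filter(.data$subject_id %in% all_ids) |>
    dplyr::distinct(.data$subject_id, .keep_all = TRUE)
  keep <- !(as.character(trials$subject_id) %in% excluded$subject_id)
  out <- trials[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- new_exclusion_report(
    n_input_trials = n_in,
    n_rt_trimmed = 0L,
    excluded_subjects = excluded,
    n_retained = sum(keep)
  )
  out
}

#' Select the trials entering RT distributional analyses
#'
#' Keeps correct encoding-phase trials of the task's target stimulus
#' class: words for the lexical decision task (`ldt`), non-animal words
#' for semantic categorisation (`semcat`). Nonwords, animal fillers, and
#' error trials never enter the RT analyses.
#'
#' @param trials a trimmed/excluded trial tibble.
#' @param task `"ldt"` or `"semcat"`.
#' @return the subset of `trials` analysed for RTs.
#' @export
select_rt_analysis_trials <- function(trials, task = c("ldt", "semcat")) {
  task <- tryCatch(match.arg(task),
                   error = function(e) abort(paste0("unsupported task: ", task[1])))
  validate_trials(trials)
  target <- switch(task, ldt = "word", semcat = "nonanimal")
  keep <- trials$accuracy == 1
  if ("phase" %in% names(trials)) keep <- keep & trials$phase == "encoding"
  if ("stim_class" %in% names(trials)) keep <- keep & trials$stim_class == target
  trials[keep & !is.na(keep), , drop = FALSE]
}
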