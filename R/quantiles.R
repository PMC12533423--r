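#' Vincentized quantile profiles
#'
#' Computes group RT quantile profiles by Vincentization: RTs of correct
#' trials are sorted within each subject and condition, the requested
#' quantiles are taken per subject (linear interpolation of order
#' statistics, the type-7 convention), and the per-subject quantiles are
#' then averaged across subjects within each condition. Vincentization
#' over a single subject is that subject's raw quantiles.
#'
#' @param trials a tibble of correct encoding trials with columns
#'   `subject_id`, `rt`, and the condition columns named in `by`.
#' @param probs quantile probabilities in (0, 1); default
#'   `c(.1, .3, .5, .7, .9)`, the usual five-point plotting convention.
#' @param by condition column(s); default `"blur"`, use
#'   `c("blur", "frequency")` for factorial designs.
#' @param min_trials per-subject-per-condition trial floor; subjects
#'   with any condition cell below it are dropped (with a message).
#' @return an object of class `quantile_profile`: a tibble with the
#'   condition columns, `prob`, `quantile` (seconds) and `n_subjects`;
#'   the per-subject quantiles are kept in attribute `"subject_quantiles"`.
#'   Quantiles are non-decreasing in `prob` within each condition.
#' @examples
#' tr <- tibble::tibble(subject_id = "s1", blur = "clear", rt = 1:5)
#' vincentize(tr, probs = 0.5, min_trials = 5)
#' @export
vincentize <- function(trials, probs = c(.1, .3, .5, .7, .9),
                       by = "blur", min_trials = length(probs)) {
  stopifnot(all(probs > 0 & probs < 1), !is.unsorted(probs))
  validate_trials(trials)
  if (!all(by %in% names(trials))) {
    abort(paste0("condition column(s) missing: ",
                 paste(setdiff(by, names(trials)), collapse = ", ")))
  }
  counts <- trials |>
    dplyr::count(.data$subject_id, dplyr::across(dplyr::all_of(by)))
  bad <- counts |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(min_n = min(.data$n), .groups = "drop") |>
    dplyr::filter(.data$min_n < min_trials)
  if (nrow(bad) > 0) {
    inform(sprintf(
      "vincentize(): dropping %d subject(s) with fewer than %d trials in some condition: %s",
      nrow(bad), min_trials, paste(head(bad$subject_id, 5), collapse = ", ")
    ))
    trials <- trials[!trials$subject_id %in% bad$subject_id, , drop = FALSE]
  }
  subj_q <- trials |>
    dplyr::group_by(.data$subject_id, dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe(prob = probs,
                   quantile = quantile(.data$rt, probs, type = 7, names = FALSE))
  prof <- subj_q |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$prob) |>
    dplyr::summarise(quantile = mean(.data$quantile),
                     n_subjects = dplyr::n(), .groups = "drop")
  structure(prof,
            class = c("quantile_profile", class(prof)),
            subject_quantiles = subj_q,
            by = by,
            quantile_type = 7)
}

#' Quantile-wise condition differences (delta profile)
#'
#' Computes, at each quantile probability, the difference between a
#' target condition set and a reference condition set of a Vincentized
#' profile. Composite sides are averaged with equal weights before
#' differencing (e.g. high blur minus the mean of clear and low blur),
#' mirroring the contrast weights of the distributional models. The sign
#' convention is fixed by the contrast: the profile is target minus
#' reference at every quantile. Per-subject deltas are retained for
#' dispersion and bootstrap summaries.
#'
#' @param profile a [vincentize()] result.
#' @param target,reference character vectors of condition labels (levels
#'   of the single `by` column of the profile), or named lists
#'   `list(blur = ..., frequency = ...)` selecting cells of a factorial
#'   profile.
#' @param label optional contrast label; defaults to
#'   `"target - reference"`.
#' @return an object of class `delta_profile`: a tibble with `prob` and
#'   `delta` (seconds); per-subject deltas in attribute
#'   `"subject_deltas"`.
#' @export
delta_profile <- function(profile, target, reference, label = NULL) {
  stopifnot(inherits(profile, "quantile_profile"))
  by <- attr(profile, "by")
  subj <- attr(profile, "subject_quantiles")
  sel <- function(d, which) {
    if (is.list(which)) {
      for (col in names(which)) d <- d[d[[col]] %in% which[[col]], , drop = FALSE]
    } else {
      d <- d[d[[by[1]]] %in% which, , drop = FALSE]
    }
    d
  }
  n_cells <- function(which) {
    cells <- sel(dplyr::distinct(profile[, by, drop = FALSE]), which)
    nrow(cells)
  }
  if (n_cells(target) == 0 || n_cells(reference) == 0) {
    abort("target or reference names a condition absent from the profile.")
  }
  side_mean <- function(d, which) {
    sel(d, which) |>
      dplyr::group_by(.data$prob) |>
      dplyr::summarise(q = mean(.data$quantile), .groups = "drop")
  }
  a <- side_mean(profile, target)
  b <- side_mean(profile, reference)
  out <- dplyr::inner_join(a, b, by = "prob", suffix = c("_a", "_b")) |>
    dplyr::transmute(prob = .data$prob, delta = .data$q_a - .data$q_b)
  # per subject: same computation within subject
  sd_a <- sel(subj, target) |>
    dplyr::group_by(.data$subject_id, .data$prob) |>
    dplyr::summarise(q = mean(.data$quantile), .groups = "drop")
  sd_b <- sel(subj, reference) |>
    dplyr::group_by(.data$subject_id, .data$prob) |>
    dplyr::summarise(q = mean(.data$quantile), .groups = "drop")
  subj_d <- dplyr::inner_join(sd_a, sd_b, by = c("subject_id", "prob"),
                              suffix = c("_a", "_b")) |>
    dplyr::transmute(.data$subject_id, prob = .data$prob,
                     delta = .data$q_a - .data$q_b)
  label <- label %||% paste(
    paste(unlist(target), collapse = "+"), "-",
    paste(unlist(reference), collapse = "+")
  )
  structure(out,
            class = c("delta_profile", class(out)),
            subject_deltas = subj_d,
            label = label)
}

#' Classify the qualitative pattern of a delta profile
#'
#' Assigns one of the four canonical quantile-difference patterns.
#' Working on the deltas oriented so that the overall difference is
#' positive (slower condition minus faster reference), with a
#' least-squares slope `b` fitted against quantile index:
#'
#' * `no_difference` — every `|delta|` is below the floor `eps`;
#' * `late_differences` — `b` exceeds `slope_tol` (differences grow
#'   toward the slow tail; small early deltas are allowed);
#' * `early_differences` — `b` is below `-slope_tol` (differences shrink
#'   toward the tail);
#' * `complete_shift` — otherwise, a flat non-zero difference across
#'   quantiles (mean `|delta| >= eps`), i.e. an overall distributional
#'   shift; a flat profile whose mean magnitude stays below `eps` falls
#'   back to `no_difference`.
#'
#' Thresholds are expressed in the time unit of the deltas; rescaling
#' deltas and thresholds together (e.g. seconds to milliseconds) leaves
#' the classification unchanged.
#'
#' @param delta a [delta_profile()] or a plain numeric vector of deltas
#'   over increasing quantile probabilities (at least 3).
#' @param eps magnitude floor in the delta's time unit (default 0.010,
#'   i.e. 10 ms for deltas in seconds).
#' @param slope_tol slope tolerance per quantile step (default 0.005,
#'   i.e. 5 ms per step).
#' @return a single character label.
#' @examples
#' classify_delta_pattern(c(0.05, 0.05, 0.05, 0.05, 0.05))  # complete_shift
#' classify_delta_pattern(c(0, 0.005, 0.02, 0.05, 0.10))    # late_differences
#' @export
classify_delta_pattern <- function(delta, eps = 0.010, slope_tol = 0.005) {
  d <- if (inherits(delta, "delta_profile")) delta$delta else as.numeric(delta)
  k <- length(d)
  if (k < 3) abort("classify_delta_pattern() needs at least 3 quantile points.")
  if (all(abs(d) < eps)) return("no_difference")
  s <- sign(mean(d))
  if (s == 0) s <- 1
  d <- s * d
  idx <- seq_len(k)
  b <- coef(lm(d ~ idx))[[2]]
  if (b > slope_tol) return("late_differences")
  if (b < -slope_tol) return("early_differences")
  if (mean(abs(d)) >= eps) return("complete_shift")
  "no_difference"
}
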