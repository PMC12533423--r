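#' Tabulate old/new recognition responses
#'
#' Classifies every test-phase trial as a hit, miss, false alarm or
#' correct rejection from its item status and the participant's old/new
#' response, and counts the four cells per condition. For designs where
#' new items carry a yoked blur tag (clear-at-test designs with one
#' false-alarm rate per studied blur level), the `blur` column already
#' holds that tag, so the same tabulation yields the three false-alarm
#' rates.
#'
#' @param trials test-phase trials with columns `status`
#'   (`"old"`/`"new"`), `response` (`"old"`/`"new"`), and the condition
#'   columns in `by`.
#' @param by condition column(s); default `"blur"`.
#' @return an object of class `recognition_counts`: a tibble with the
#'   condition columns and `n_old`, `n_new`, `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`.
#' @export
tabulate_recognition <- function(trials, by = "blur") {
  if (!all(c("status", "response") %in% names(trials))) {
    abort("recognition trials need `status` and `response` columns.")
  }
  if (any(!trials$status %in% c("old", "new"))) {
    abort("recognition trials must have status \"old\" or \"new\" (no \"na\").")
  }
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_old = sum(.data$status == "old"),
      n_new = sum(.data$status == "new"),
      hits = sum(.data$status == "old" & .data$response == "old"),
      misses = sum(.data$status == "old" & .data$response == "new"),
      false_alarms = sum(.data$status == "new" & .data$response == "old"),
      correct_rejections = sum(.data$status == "new" & .data$response == "new"),
      .groups = "drop"
    )
  structure(out, class = c("recognition_counts", class(out)), by = by)
}

#' Sensitivity and criterion from recognition counts
#'
#' Equal-variance Gaussian signal detection estimates per condition:
#' `dprime = z(hit_rate) - z(fa_rate)` and criterion
#' `c = -(z(hit_rate) + z(fa_rate)) / 2` (conventional sign: positive is
#' conservative). `c_model = -c` is also returned, matching the probit
#' regression parameterisation in which the intercept carries the
#' reversed-sign criterion.
#'
#' @param counts a [tabulate_recognition()] result (or a tibble with its
#'   columns).
#' @param correction correction for 0/1 rates: `"loglinear"` (default;
#'   add 0.5 to each count and 1 to each denominator) or `"none"`.
#' @return an object of class `sdt_estimates`: a tibble with the
#'   condition columns and `hit_rate`, `fa_rate`, `dprime`, `criterion`,
#'   `c_model`, plus a `correction` attribute recording the rule used.
#' @examples
#' cnt <- tibble::tibble(blur = "clear", n_old = 10, n_new = 10,
#'                       hits = 7, misses = 3,
#'                       false_alarms = 3, correct_rejections = 7)
#' dprime_criterion(cnt)
#' @export
dprime_criterion <- function(counts, correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  stopifnot(all(c("n_old", "n_new", "hits", "false_alarms") %in% names(counts)))
  if (any(counts$n_old <= 0) || any(counts$n_new <= 0)) {
    abort("each condition needs n_old > 0 and n_new > 0.")
  }
  hr <- if (correction == "loglinear") {
    (counts$hits + 0.5) / (counts$n_old + 1)
  } else {
    counts$hits / counts$n_old
  }
  fr <- if (correction == "loglinear") {
    (counts$false_alarms + 0.5) / (counts$n_new + 1)
  } else {
    counts$false_alarms / counts$n_new
  }
  by <- attr(counts, "by") %||% intersect(c("blur", "frequency", "condition"), names(counts))
  out <- dplyr::bind_cols(
    counts[, by, drop = FALSE],
    tibble::tibble(
      hit_rate = hr, fa_rate = fr,
      dprime = qnorm(hr) - qnorm(fr),
      criterion = -(qnorm(hr) + qnorm(fr)) / 2
    )
  )
  out$c_model <- -out$criterion
  structure(out, class = c("sdt_estimates", class(out)),
            correction = correction, by = by)
}

#' Probit regression formulation of the SDT model
#'
#' Fits the probability of an "old" response as a probit-linear function
#' of item status (coded -0.5 for new, +0.5 for old), condition
#' contrasts, and their interactions. Under this coding the
#' status-by-contrast interaction coefficients are d' differences
#' between the contrasted conditions, the status main effect is the
#' grand d' (intercept of the sensitivity model), and the non-status
#' main effects carry criterion differences on the reversed-sign
#' (`-c`) parameterisation.
#'
#' With `family = "binomial"` responses are aggregated to
#' (successes, totals) per condition-by-status cell before fitting;
#' with `"bernoulli"` the trial-level 0/1 responses are used. Without
#' random effects the two give identical point estimates. Cells with
#' all-"old" or all-"new" responding (complete separation) receive the
#' log-linear 0.5/1 correction in binomial mode, and the fit is flagged.
#'
#' @param trials test-phase trials (`status`, `response`, condition
#'   columns).
#' @param contrasts named list of [contrast_spec()]s; default the blur
#'   contrasts.
#' @param family `"binomial"` (aggregated, default) or `"bernoulli"`.
#' @return an object of class `sdt_fit`: a list with `coefficients` (a
#'   tidy tibble of terms), the underlying `glm` object, the aggregated
#'   `cells`, and `flags`. `tidy()` and `glance()` methods are provided.
#' @export
fit_probit_sdt <- function(trials, contrasts = blur_contrasts(),
                           family = c("binomial", "bernoulli")) {
  family <- match.arg(family)
  if (!all(c("status", "response") %in% names(trials))) {
    abort("recognition trials need `status` and `response` columns.")
  }
  facs <- unique(vapply(contrasts, function(ct) ct$factor, character(1)))
  cells <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(facs, "status")))) |>
    dplyr::summarise(say_old = sum(.data$response == "old"),
                     n = dplyr::n(), .groups = "drop")
  flags <- character()
  sep <- cells$say_old == 0 | cells$say_old == cells$n
  if (any(sep)) {
    flags <- c(flags, "separation_corrected")
    cells$say_old <- cells$say_old + 0.5
    cells$n <- cells$n + 1
  }
  X <- contrast_design_matrix(cells[, facs, drop = FALSE], contrasts)
  status_c <- ifelse(cells$status == "old", 0.5, -0.5)
  # predictors: contrasts, status, status x contrasts
  M <- cbind(X, status = status_c, X[, -1, drop = FALSE] * status_c)
  colnames(M) <- c(colnames(X), "status",
                   paste0("status:", colnames(X)[-1]))
  dat <- data.frame(say_old = cells$say_old, n = cells$n)
  if (family == "binomial") {
    # the separation correction makes counts non-integer by design; the
    # binomial likelihood still applies, so the glm nag is silenced
    fit <- withCallingHandlers(
      stats::glm(cbind(say_old, n - say_old) ~ M - 1,
                 family = stats::binomial(link = "probit"), data = dat,
                 control = list(epsilon = 1e-12, maxit = 100)),
      warning = function(w) {
        if (grepl("non-integer", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    # expand to trial level
    idx <- rep(seq_len(nrow(cells)), times = cells$n)
    y <- unlist(purrr::map2(cells$say_old, cells$n, function(s, n) {
      c(rep(1, round(s)), rep(0, round(n - s)))
    }))
    fit <- stats::glm(y ~ M[idx, ] - 1,
                      family = stats::binomial(link = "probit"),
                      control = list(epsilon = 1e-12, maxit = 100))
  }
  coefs <- tibble::tibble(
    term = colnames(M),
    estimate = unname(coef(fit)),
    std_error = unname(sqrt(diag(stats::vcov(fit))))
  )
  structure(
    list(coefficients = coefs, glm = fit, cells = cells,
         contrasts = contrasts, family = family, flags = flags),
    class = "sdt_fit"
  )
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("Probit SDT fit (", x$family, " likelihood)\n", sep = "")
  print(x$coefficients)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
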