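#' Run the full distributional analysis pipeline
#'
#' Executes the complete analysis on trial-level data: RT trimming and
#' participant exclusion, selection of correct target trials, the
#' contrast-coded distributional ex-Gaussian fit with bootstrap effect
#' summaries and hypothesis decisions, Vincentized quantile and delta
#' profiles with pattern classification, and the probit SDT analysis of
#' the test phase. Either supply `trials` or name an `experiment`
#' preset, in which case a synthetic experiment is generated first.
#'
#' @param trials a trial tibble (both phases), or `NULL` to simulate.
#' @param experiment preset passed to [simulate_full_experiment()] when
#'   `trials` is `NULL`.
#' @param task `"ldt"` or `"semcat"`; inferred from the trials when a
#'   `task` column is present.
#' @param contrasts contrast list; defaults to the blur contrasts, with
#'   the frequency contrast added when a `frequency` factor with more
#'   than one level is present.
#' @param n_boot bootstrap draws for effect summaries.
#' @param min_per_cell per-subject cell floor for the distributional
#'   fit.
#' @param seed integer seed driving simulation and bootstrap.
#' @param out_dir optional directory; when given, tables are written as
#'   CSV, the exclusion report as JSON, and the run metadata (seed,
#'   package version) as JSON.
#' @return a list of class `rtfluency_report`: `exclusions`,
#'   `exgauss_fit`, `effects` (summaries + decisions for mu, log sigma,
#'   log beta on every contrast), `quantile_profile`, `delta_profiles`
#'   (with pattern labels), `sdt_counts`, `sdt_estimates`, `sdt_fit`,
#'   and `meta`.
#' @export
run_pipeline <- function(trials = NULL, experiment = "1A", task = NULL,
                         contrasts = NULL, n_boot = 4000,
                         min_per_cell = 10, seed = 1, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  if (is.null(trials)) {
    sim <- stage("simulate", simulate_full_experiment(experiment, seed = seed))
    trials <- sim$trials
  }
  if (nrow(trials) == 0) abort("pipeline stage `preprocess` failed: no trials.")
  task <- task %||% (if ("task" %in% names(trials)) {
    stats::na.omit(unique(trials$task))[1]
  } else "ldt")
  has_freq <- "frequency" %in% names(trials) &&
    length(setdiff(unique(trials$frequency), c("none", NA))) > 1
  contrasts <- contrasts %||% c(
    blur_contrasts(),
    if (has_freq) list(freq = frequency_contrast())
  )
  by <- if (has_freq) c("blur", "frequency") else "blur"

  enc <- trials[trials$phase == "encoding", , drop = FALSE]
  excl <- stage("preprocess", {
    kept <- exclude_participants(enc)
    part_report <- exclusion_report(kept)
    kept <- filter_rts(kept)
    list(trials = kept, rt_report = exclusion_report(kept),
         participant_report = part_report)
  })
  rt_trials <- stage("select", select_rt_analysis_trials(excl$trials, task))

  fit <- stage("exgauss", fit_exgauss_distributional(
    rt_trials, contrasts = contrasts, mode = "two_stage",
    min_per_cell = min_per_cell
  ))
  draws <- stage("bootstrap", bootstrap_contrast_draws(fit, n_boot = n_boot,
                                                       seed = seed + 10))
  eff <- draws |>
    dplyr::filter(.data$term != "intercept") |>
    dplyr::group_by(.data$parameter, .data$term) |>
    dplyr::group_map(function(d, key) {
      s <- summarize_effect(d$value, direction = "greater",
                            parameter = key$parameter, contrast = key$term)
      dplyr::bind_cols(s, decide_hypothesis(s)[, c("supported", "evidence")])
    }) |>
    dplyr::bind_rows()

  qp <- stage("quantiles", vincentize(rt_trials, by = by))
  deltas <- stage("delta", {
    d1 <- delta_profile(qp, target = "high", reference = c("clear", "low"),
                        label = "high - (clear+low)/2")
    d2 <- delta_profile(qp, target = "low", reference = "clear",
                        label = "low - clear")
    tibble::tibble(
      contrast = c("blur1", "blur2"),
      label = c(attr(d1, "label"), attr(d2, "label")),
      profile = list(d1, d2),
      pattern = c(classify_delta_pattern(d1), classify_delta_pattern(d2))
    )
  })

  test <- trials[trials$phase == "test", , drop = FALSE]
  sdt <- if (nrow(test) > 0) {
    stage("sdt", {
      counts <- tabulate_recognition(test, by = by)
      list(counts = counts,
           estimates = dprime_criterion(counts),
           fit = fit_probit_sdt(test, contrasts = contrasts))
    })
  } else {
    list(counts = NULL, estimates = NULL, fit = NULL)
  }

  report <- structure(list(
    exclusions = excl[c("rt_report", "participant_report")],
    exgauss_fit = fit,
    effects = eff,
    quantile_profile = qp,
    delta_profiles = deltas,
    sdt_counts = sdt$counts,
    sdt_estimates = sdt$estimates,
    sdt_fit = sdt$fit,
    meta = list(seed = seed, task = task, n_boot = n_boot,
                package_version = as.character(utils::packageVersion("rtfluency")),
                r_version = R.version.string)
  ), class = "rtfluency_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(eff, file.path(out_dir, "exgauss_effects.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(qp), file.path(out_dir, "quantile_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(deltas[, c("contrast", "label", "pattern")],
                     file.path(out_dir, "delta_patterns.csv"), row.names = FALSE)
    if (!is.null(sdt$estimates)) {
      utils::write.csv(as.data.frame(sdt$estimates),
                       file.path(out_dir, "sdt_estimates.csv"), row.names = FALSE)
    }
    writeLines(exclusion_report_json(excl$rt_report),
               file.path(out_dir, "exclusion_report.json"))
    writeLines(jsonlite::toJSON(report$meta, auto_unbox = TRUE),
               file.path(out_dir, "run_meta.json"))
  }
  report
}

#' @export
print.rtfluency_report <- function(x, ...) {
  cat("rtfluency pipeline report (seed ", x$meta$seed, ")\n\n", sep = "")
  cat("Ex-Gaussian contrast effects:\n")
  eff <- x$effects
  eff$evidence_ratio <- ifelse(is.infinite(eff$evidence_ratio), "Inf",
                               format(round(eff$evidence_ratio, 2)))
  print(eff[, c("parameter", "contrast", "mean", "se", "cri_lower",
                "cri_upper", "posterior_prob", "evidence_ratio", "supported")],
        n = Inf)
  cat("\nDelta-plot patterns:\n")
  print(x$delta_profiles[, c("contrast", "label", "pattern")])
  if (!is.null(x$sdt_estimates)) {
    cat("\nRecognition (SDT) estimates:\n")
    print(x$sdt_estimates)
  }
  invisible(x)
}
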