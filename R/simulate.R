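#' Generative parameter presets for encoding RTs
#'
#' Condition-specific ex-Gaussian generating parameters implementing the
#' three qualitative theoretical scenarios for how blurring should act
#' on the RT distribution:
#'
#' * `stage_specific` — high blur elevates both `mu` (shift) and `tau`
#'   (tail), low blur gives a small `mu` shift only;
#' * `compensatory` — high blur elevates `mu` only;
#' * `metacognitive` — both blur levels elevate `tau` only;
#' * `null` — all conditions identical.
#'
#' Effect magnitudes echo the scale typical of speeded word recognition:
#' baseline (clear) `mu = 0.55` s, `sigma = 0.08` s, `tau = 0.20` s; the
#' stage-specific high-blur cell adds 0.107 s to `mu` relative to the
#' clear/low mean and 0.427 to `log(tau)`, with a 0.016 s low-blur shift
#' — the magnitudes observed for the blur manipulation in lexical
#' decision. Error (lapse) rates are higher for high blur.
#'
#' With `frequency = TRUE` (semantic-categorisation style designs) a
#' low-frequency penalty (+0.04 s on `mu`, +0.18 on `log(tau)`) and an
#' over-additive high-blur-by-frequency tail interaction are added.
#'
#' @param scenario preset name.
#' @param frequency include a 2-level word-frequency factor.
#' @return a tibble with columns `blur` (and `frequency`), `mu`,
#'   `sigma`, `tau`, `error_rate`.
#' @export
encoding_preset <- function(scenario = c("stage_specific", "compensatory",
                                         "metacognitive", "null"),
                            frequency = FALSE) {
  scenario <- match.arg(scenario)
  base <- tibble::tibble(
    blur = c("clear", "low", "high"),
    mu = 0.55, sigma = 0.08, tau = 0.20,
    error_rate = c(0.03, 0.03, 0.08)
  )
  base <- switch(
    scenario,
    stage_specific = base |>
      dplyr::mutate(
        mu = c(0.550, 0.566, mean(c(0.550, 0.566)) + 0.107),
        tau = c(0.20, 0.20, 0.20 * exp(0.427)),
        sigma = c(0.08, 0.08, 0.08 * exp(0.157))
      ),
    compensatory = base |>
      dplyr::mutate(mu = c(0.550, 0.550, 0.657)),
    metacognitive = base |>
      dplyr::mutate(tau = c(0.20, 0.20 * exp(0.30), 0.20 * exp(0.30))),
    null = dplyr::mutate(base, error_rate = 0.03)
  )
  if (!frequency) return(base)
  hi <- dplyr::mutate(base, frequency = "high")
  lo <- dplyr::mutate(base, frequency = "low",
                      mu = .data$mu + 0.04, tau = .data$tau * exp(0.18))
  if (scenario == "stage_specific") {
    # over-additive tail effect for blurred low-frequency words
    lo$tau[lo$blur == "high"] <- lo$tau[lo$blur == "high"] * exp(0.15)
  }
  dplyr::bind_rows(hi, lo) |>
    dplyr::select("blur", "frequency", dplyr::everything())
}

#' Generative SDT presets for recognition
#'
#' Condition-specific true d' and criterion. The default
#' (`memory_benefit = TRUE`) gives high-blur items a d' advantage of
#' 0.13 over the clear/low mean (the magnitude reported for the blur
#' manipulation) around a baseline d' of 0.9, with a small criterion
#' spread; `memory_benefit = FALSE` equates all conditions.
#'
#' @param frequency include the frequency factor (low-frequency words
#'   get a baseline memory advantage; the blur benefit is confined to
#'   high-frequency words, the selective pattern of interest).
#' @param memory_benefit give high-blur items the d' advantage.
#' @return a tibble with `blur` (and `frequency`), `dprime`,
#'   `criterion`.
#' @export
recognition_preset <- function(frequency = FALSE, memory_benefit = TRUE) {
  base <- tibble::tibble(
    blur = c("clear", "low", "high"),
    dprime = if (memory_benefit) c(0.90, 0.90, 1.03) else rep(0.90, 3),
    criterion = c(0.15, 0.05, 0.12)
  )
  if (!frequency) return(base)
  hi <- dplyr::mutate(base, frequency = "high")
  lo <- dplyr::mutate(base, frequency = "low",
                      dprime = if (memory_benefit) c(1.05, 1.05, 1.05) else .data$dprime + 0.15)
  dplyr::bind_rows(hi, lo) |>
    dplyr::select("blur", "frequency", dplyr::everything())
}

#' Simulate encoding-phase trials
#'
#' Draws one encoding trial per subject-by-study-item row of the design.
#' With the ex-Gaussian generator, RTs are condition ex-Gaussian draws
#' with Gaussian subject and item random intercepts added on the link
#' scales (identity for `mu`, log for `sigma` and `tau`), and accuracy
#' is Bernoulli with the condition lapse rate. With the diffusion
#' generator, RT and accuracy come jointly from simulated
#' first passages (upper boundary = correct). RTs are not truncated:
#' the preprocessing trim is applied downstream, so trimming-induced
#' bias is itself testable.
#'
#' @param design a design tibble (`list_id`, `item_id`, `blur`, ...)
#'   restricted to study items, or a full counterbalance from the design
#'   builders (the `status == "old"` rows and fillers are used).
#' @param subjects a tibble `subject_id`, `list_id` from
#'   [assign_participants()].
#' @param params condition parameter table: columns `blur` (and
#'   `frequency`) plus `mu`, `sigma`, `tau`, `error_rate` (ex-Gaussian)
#'   or `v`, `a`, `z`, `ter` (diffusion).
#' @param generator `"exgauss"` or `"ddm"`.
#' @param subject_sd,item_sd named numeric vectors of random-intercept
#'   SDs on the link scales, entries `mu`, `log_sigma`, `log_tau` (the
#'   defaults emulate typical between-subject and between-item spread).
#' @param task task label stamped on the trials.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a trial tibble (`phase = "encoding"`).
#' @export
simulate_encoding <- function(design, subjects, params,
                              generator = c("exgauss", "ddm"),
                              subject_sd = c(mu = 0.05, log_sigma = 0.2, log_tau = 0.3),
                              item_sd = c(mu = 0.02, log_sigma = 0.1, log_tau = 0.1),
                              task = "ldt", seed = 1) {
  generator <- match.arg(generator)
  study <- design[design$status %in% c("old", "filler"), , drop = FALSE]
  facs <- intersect(c("blur", "frequency"), names(params))
  miss <- dplyr::anti_join(
    dplyr::distinct(study[, facs, drop = FALSE]), params, by = facs
  )
  if (nrow(miss) > 0) {
    abort("design contains condition cells absent from `params`.")
  }
  trials <- dplyr::inner_join(subjects, study, by = "list_id",
                              relationship = "many-to-many") |>
    dplyr::inner_join(params, by = facs)
  if (nrow(trials) == 0) {
    return(dplyr::mutate(trials, rt = numeric(0), accuracy = integer(0),
                         phase = character(0), task = character(0)))
  }
  withr::with_seed(seed, {
    if (generator == "exgauss") {
      sid <- unique(trials$subject_id)
      iid <- unique(trials$item_id)
      s_eff <- tibble::tibble(
        subject_id = sid,
        s_mu = rnorm(length(sid), 0, subject_sd[["mu"]]),
        s_ls = rnorm(length(sid), 0, subject_sd[["log_sigma"]]),
        s_lt = rnorm(length(sid), 0, subject_sd[["log_tau"]])
      )
      i_eff <- tibble::tibble(
        item_id = iid,
        i_mu = rnorm(length(iid), 0, item_sd[["mu"]]),
        i_ls = rnorm(length(iid), 0, item_sd[["log_sigma"]]),
        i_lt = rnorm(length(iid), 0, item_sd[["log_tau"]])
      )
      trials <- trials |>
        dplyr::left_join(s_eff, by = "subject_id") |>
        dplyr::left_join(i_eff, by = "item_id") |>
        dplyr::mutate(
          mu_t = .data$mu + .data$s_mu + .data$i_mu,
          sigma_t = exp(log(.data$sigma) + .data$s_ls + .data$i_ls),
          tau_t = exp(log(.data$tau) + .data$s_lt + .data$i_lt)
        )
      n <- nrow(trials)
      trials$rt <- rnorm(n, trials$mu_t, trials$sigma_t) +
        rexp(n, rate = 1 / trials$tau_t)
      trials$accuracy <- as.integer(runif(n) >= trials$error_rate)
      trials <- dplyr::select(
        trials, -dplyr::any_of(c("s_mu", "s_ls", "s_lt", "i_mu", "i_ls", "i_lt",
                                 "mu_t", "sigma_t", "tau_t",
                                 "mu", "sigma", "tau", "error_rate"))
      )
    } else {
      cond_key <- do.call(paste, c(trials[, facs, drop = FALSE], sep = "|"))
      rt <- numeric(nrow(trials)); acc <- integer(nrow(trials))
      for (k in unique(cond_key)) {
        idx <- which(cond_key == k)
        p <- trials[idx[1], c("v", "a", "z", "ter")]
        sim <- simulate_ddm_trials(length(idx), p$v, p$a, p$z, p$ter,
                                   seed = sample.int(2^31 - 1, 1))
        rt[idx] <- sim$rt
        acc[idx] <- as.integer(sim$boundary == "upper")
      }
      trials$rt <- rt
      trials$accuracy <- acc
      trials <- dplyr::select(trials, -dplyr::any_of(c("v", "a", "z", "ter")))
    }
  })
  trials |>
    dplyr::mutate(phase = "encoding", task = task, status = "na") |>
    dplyr::select(dplyr::any_of(c(
      "subject_id", "item_id", "list_id", "phase", "task", "blur",
      "frequency", "stim_class", "status", "rt", "accuracy"
    )))
}

#' Simulate old/new recognition responses
#'
#' Responses follow the equal-variance Gaussian SDT model with the
#' reversed-sign criterion parameterisation: with item status coded
#' -0.5 (new) / +0.5 (old),
#' `P("old") = Phi(dprime * status_c - criterion)`, so hits occur with
#' probability `Phi(dprime/2 - c)` and false alarms with
#' `Phi(-dprime/2 - c)`.
#'
#' @param design a counterbalance tibble restricted to test items
#'   (`status` in `old`/`new`).
#' @param subjects subject-to-list assignment tibble.
#' @param params condition table with `dprime` and `criterion` columns
#'   (conventional sign) keyed by `blur` (and `frequency`).
#' @param seed integer seed.
#' @return a trial tibble (`phase = "test"`) with `response`
#'   (`"old"`/`"new"`) and `accuracy`.
#' @export
simulate_recognition <- function(design, subjects, params, seed = 1) {
  test <- design[design$status %in% c("old", "new"), , drop = FALSE]
  facs <- intersect(c("blur", "frequency"), names(params))
  trials <- dplyr::inner_join(subjects, test, by = "list_id",
                              relationship = "many-to-many") |>
    dplyr::inner_join(params, by = facs)
  if (nrow(trials) == 0) abort("no test items matched the parameter table.")
  withr::with_seed(seed, {
    status_c <- ifelse(trials$status == "old", 0.5, -0.5)
    p_old <- pnorm(trials$dprime * status_c - trials$criterion)
    say_old <- runif(nrow(trials)) < p_old
    trials$response <- ifelse(say_old, "old", "new")
  })
  trials$accuracy <- as.integer(trials$response ==
                                  ifelse(trials$status == "old", "old", "new"))
  trials$rt <- NA_real_
  trials |>
    dplyr::mutate(phase = "test") |>
    dplyr::select(-dplyr::any_of(c("dprime", "criterion"))) |>
    dplyr::select(dplyr::any_of(c(
      "subject_id", "item_id", "list_id", "phase", "blur", "frequency",
      "stim_class", "status", "rt", "response", "accuracy"
    )))
}

#' Simulate a complete synthetic experiment
#'
#' Generates encoding and test phases for one of the three study
#' layouts, with known ground truth:
#'
#' * `"1A"` — lexical decision, 6 counterbalanced lists over 168 words
#'   (84 study + 84 new per list, 28 per blur level) plus 84 nonword
#'   fillers at encoding; blur reinstated at test. 216 subjects
#'   (36 per list).
#' * `"1B"` — as 1A, but test items render clear; each new item keeps
#'   the blur tag of the studied set it is yoked to, giving one
#'   false-alarm rate per studied blur level.
#' * `"2"` — semantic categorisation with the frequency factor:
#'   90 non-animal study words (blur-by-frequency counterbalanced over
#'   6 lists) plus 45 animal fillers at study (2:1 ratio), 90 non-animal
#'   new words at test, 432 subjects (72 per list).
#'
#' @param experiment `"1A"`, `"1B"`, or `"2"`.
#' @param n_subjects total subjects (default 216, or 432 for
#'   experiment 2); must divide evenly over the 6 lists. 0 returns an
#'   empty trial set with ground truth only.
#' @param scenario encoding preset name (see [encoding_preset()]).
#' @param encoding_params,recognition_params optional overrides of the
#'   preset parameter tables.
#' @param subject_sd,item_sd random-intercept SDs, passed to
#'   [simulate_encoding()].
#' @param seed integer seed.
#' @return a list with `trials` (all phases bound together),
#'   `design`, and `ground_truth` (the generating parameter tables).
#' @export
simulate_full_experiment <- function(experiment = c("1A", "1B", "2"),
                                     n_subjects = NULL,
                                     scenario = "stage_specific",
                                     encoding_params = NULL,
                                     recognition_params = NULL,
                                     subject_sd = c(mu = 0.05, log_sigma = 0.2, log_tau = 0.3),
                                     item_sd = c(mu = 0.02, log_sigma = 0.1, log_tau = 0.1),
                                     seed = 1) {
  experiment <- match.arg(experiment)
  has_freq <- experiment == "2"
  n_subjects <- n_subjects %||% if (has_freq) 432L else 216L
  enc_par <- encoding_params %||% encoding_preset(scenario, frequency = has_freq)
  rec_par <- recognition_params %||% recognition_preset(frequency = has_freq)
  task <- if (has_freq) "semcat" else "ldt"

  if (experiment %in% c("1A", "1B")) {
    words <- build_counterbalanced_lists(168, seed = seed)
    words$stim_class <- "word"
    words$frequency <- "none"
    nonwords <- purrr::map_dfr(sort(unique(words$list_id)), function(l) {
      blur <- rep(c("clear", "low", "high"), each = 28)
      shift <- ((seq_along(blur) + l - 2) %% 3) + 1
      tibble::tibble(
        list_id = l, item_id = paste0("nw", seq_len(84)),
        status = "filler", blur = c("clear", "low", "high")[shift],
        stim_class = "nonword", frequency = "none"
      )
    })
    design <- dplyr::bind_rows(words, nonwords)
  } else {
    design <- build_exp2_study_list(seed = seed)
  }
  if (n_subjects %% 6 != 0 && n_subjects != 0) {
    abort("`n_subjects` must be divisible by the 6 lists.")
  }
  subjects <- if (n_subjects > 0) {
    assign_participants(design, n_subjects / 6)
  } else {
    tibble::tibble(subject_id = character(), list_id = integer())
  }

  # nonword fillers respond at a slower, noisier cell: reuse the clear
  # cell shifted by 60 ms with a higher lapse rate
  enc_design <- design
  enc_par_full <- enc_par
  if (experiment %in% c("1A", "1B")) {
    word_rows <- enc_design$stim_class == "word"
  } else {
    word_rows <- enc_design$stim_class == "nonanimal"
  }
  ground_truth <- list(encoding = enc_par, recognition = rec_par,
                      scenario = scenario,
                      subject_sd = subject_sd, item_sd = item_sd)
  if (n_subjects == 0) {
    return(list(trials = tibble::tibble(), design = design,
                ground_truth = ground_truth))
  }

  # encoding: target words under the scenario parameters; fillers
  # (nonwords / animal words) under a displaced clear-like cell
  enc_targets <- simulate_encoding(
    enc_design[word_rows | enc_design$status == "old", , drop = FALSE] |>
      dplyr::filter(.data$status %in% c("old")),
    subjects, enc_par, generator = "exgauss",
    subject_sd = subject_sd, item_sd = item_sd, task = task, seed = seed + 1
  )
  fillers <- enc_design[enc_design$status == "filler", , drop = FALSE]
  enc_fillers <- if (nrow(fillers) > 0) {
    filler_par <- dplyr::distinct(fillers[, intersect(c("blur", "frequency"), names(enc_par)),
                                          drop = FALSE]) |>
      dplyr::mutate(mu = 0.61, sigma = 0.09, tau = 0.22, error_rate = 0.06)
    simulate_encoding(fillers, subjects, filler_par, generator = "exgauss",
                      subject_sd = subject_sd, item_sd = item_sd,
                      task = task, seed = seed + 2)
  } else {
    NULL
  }

  test_design <- design[design$status %in% c("old", "new") &
                          design$stim_class %in% c("word", "nonanimal"), ,
                        drop = FALSE]
  rec_trials <- simulate_recognition(test_design, subjects, rec_par,
                                     seed = seed + 3)
  if (experiment %in% c("1B", "2")) {
    # clear at test: the blur column keeps the yoked condition tag used
    # for the analysis; record the rendered (clear) surface separately
    rec_trials$rendered <- "clear"
  }
  trials <- dplyr::bind_rows(enc_targets, enc_fillers, rec_trials)
  list(trials = trials, design = design, ground_truth = ground_truth)
}
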