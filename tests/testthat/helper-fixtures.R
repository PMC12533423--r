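# Small in-code fixtures shared across test files.

toy_trials <- function(rt = c(0.1, 0.19, 0.2, 0.5, 0.8, 1.0, 1.5, 2.5, 2.51, 3.0),
                       subject_id = "s1") {
  tibble::tibble(
    subject_id = subject_id,
    item_id = paste0("w", seq_along(rt)),
    phase = "encoding",
    blur = "clear",
    stim_class = "word",
    rt = rt,
    accuracy = 1L
  )
}

# trials for several subjects with given per-subject encoding accuracies
accuracy_trials <- function(accs, n_trials = 20) {
  purrr::imap_dfr(accs, function(acc, i) {
    n_correct <- round(acc * n_trials)
    tibble::tibble(
      subject_id = paste0("s", i),
      phase = "encoding",
      rt = 0.5,
      accuracy = c(rep(1L, n_correct), rep(0L, n_trials - n_correct))
    )
  })
}

# balanced two-condition RT data from known ex-Gaussian cells
exgauss_cell_trials <- function(n_subjects, n_per_cell, cells, seed,
                                subject_sd = c(mu = 0.03, log_sigma = 0.1, log_tau = 0.15)) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      s_mu <- rnorm(1, 0, subject_sd[["mu"]])
      s_ls <- rnorm(1, 0, subject_sd[["log_sigma"]])
      s_lt <- rnorm(1, 0, subject_sd[["log_tau"]])
      purrr::pmap_dfr(cells, function(blur, mu, sigma, tau, ...) {
        tibble::tibble(
          subject_id = sprintf("s%03d", s),
          blur = blur,
          phase = "encoding",
          stim_class = "word",
          accuracy = 1L,
          rt = rnorm(n_per_cell, mu + s_mu, sigma * exp(s_ls)) +
            rexp(n_per_cell, 1 / (tau * exp(s_lt)))
        )
      })
    })
  })
}
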