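test_that("a single subject's profile is its raw quantiles", {
  tr <- tibble::tibble(subject_id = "s1", blur = "clear", rt = c(1, 2, 3, 4, 5))
  prof <- vincentize(tr, probs = 0.5, min_trials = 5)
  expect_equal(prof$quantile, 3)
  prof5 <- vincentize(tr, min_trials = 5)
  expect_equal(prof5$quantile,
               unname(quantile(1:5, c(.1, .3, .5, .7, .9), type = 7)))
})

test_that("two subjects average to the midpoint of their quantile vectors", {
  tr <- dplyr::bind_rows(
    tibble::tibble(subject_id = "s1", blur = "clear", rt = c(1, 2, 3, 4, 5)),
    tibble::tibble(subject_id = "s2", blur = "clear", rt = c(2, 4, 6, 8, 10))
  )
  prof <- vincentize(tr, min_trials = 5)
  q1 <- quantile(1:5, c(.1, .3, .5, .7, .9), type = 7)
  q2 <- quantile(c(2, 4, 6, 8, 10), c(.1, .3, .5, .7, .9), type = 7)
  expect_equal(prof$quantile, unname((q1 + q2) / 2))
  expect_equal(unique(prof$n_subjects), 2)
})

test_that("default probabilities follow the five-point plotting convention", {
  tr <- tibble::tibble(subject_id = "s1", blur = "clear", rt = runif(50, 0.3, 1))
  prof <- vincentize(tr)
  expect_equal(unique(prof$prob), c(.1, .3, .5, .7, .9))
})

test_that("profiles are monotone in probability for random inputs", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      tr <- tidyr::expand_grid(subject_id = paste0("s", 1:6),
                               blur = c("clear", "high"),
                               i = 1:25) |>
        dplyr::mutate(rt = rexgauss(dplyr::n(), 0.5, 0.08, 0.2))
    })
    prof <- vincentize(tr)
    mono <- prof |>
      dplyr::group_by(.data$blur) |>
      dplyr::summarise(ok = !is.unsorted(.data$quantile), .groups = "drop")
    expect_true(all(mono$ok))
  }
})

test_that("subjects below the trial floor are dropped with a message", {
  tr <- dplyr::bind_rows(
    tibble::tibble(subject_id = "s1", blur = "clear", rt = runif(30, 0.3, 1)),
    tibble::tibble(subject_id = "s2", blur = "clear", rt = c(0.4, 0.5))
  )
  expect_message(prof <- vincentize(tr), "dropping")
  expect_equal(unique(prof$n_subjects), 1)
})

make_two_cond_profile <- function(mu_by_cond, tau_by_cond, seed,
                                  n_subj = 12, n_per = 60) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subj), function(s) {
      purrr::imap_dfr(mu_by_cond, function(mu, cond) {
        tibble::tibble(
          subject_id = sprintf("s%02d", s), blur = cond,
          rt = rnorm(n_per, mu, 0.05) + rexp(n_per, 1 / tau_by_cond[[cond]])
        )
      })
    })
  }) |>
    vincentize()
}

test_that("delta profiles subtract conditions and are antisymmetric", {
  prof <- make_two_cond_profile(list(clear = 0.5, high = 0.55),
                                list(clear = 0.2, high = 0.2), seed = 9)
  d1 <- delta_profile(prof, "high", "clear")
  d2 <- delta_profile(prof, "clear", "high")
  expect_equal(d1$delta, -d2$delta)
  expect_error(delta_profile(prof, "absent", "clear"), "absent")
})

test_that("identical conditions give an all-zero delta and no_difference", {
  tr <- tidyr::expand_grid(subject_id = paste0("s", 1:8), i = 1:40) |>
    dplyr::mutate(rt = withr::with_seed(3, rexgauss(dplyr::n(), 0.5, 0.06, 0.2)))
  both <- dplyr::bind_rows(dplyr::mutate(tr, blur = "clear"),
                           dplyr::mutate(tr, blur = "low"))
  prof <- vincentize(both)
  d <- delta_profile(prof, "low", "clear")
  expect_equal(d$delta, rep(0, 5))
  expect_equal(classify_delta_pattern(d), "no_difference")
})

test_that("a pure location shift classifies as a complete shift", {
  prof <- make_two_cond_profile(list(clear = 0.50, high = 0.55),
                                list(clear = 0.20, high = 0.20), seed = 15,
                                n_subj = 24, n_per = 100)
  d <- delta_profile(prof, "high", "clear")
  expect_lt(abs(mean(d$delta) - 0.05), 0.02)
  expect_equal(classify_delta_pattern(d), "complete_shift")
})

test_that("a shift-plus-tail effect classifies as late differences", {
  prof <- make_two_cond_profile(list(clear = 0.50, high = 0.57),
                                list(clear = 0.20, high = 0.31), seed = 16)
  d <- delta_profile(prof, "high", "clear")
  expect_gt(d$delta[5], d$delta[1])
  expect_equal(classify_delta_pattern(d), "late_differences")
})

test_that("composite references average the reference conditions", {
  cells <- list(clear = 0.5, low = 0.52, high = 0.6)
  taus <- list(clear = 0.2, low = 0.2, high = 0.2)
  prof <- make_two_cond_profile(cells, taus, seed = 17)
  d <- delta_profile(prof, "high", c("clear", "low"))
  manual <- prof |>
    tidyr::pivot_wider(names_from = "blur", values_from = "quantile") |>
    dplyr::mutate(delta = .data$high - (.data$clear + .data$low) / 2)
  expect_equal(d$delta, manual$delta)
})

test_that("the classifier handles the canonical toy patterns", {
  expect_equal(classify_delta_pattern(c(0, 0, 0, 0, 0)), "no_difference")
  expect_equal(classify_delta_pattern(c(0.05, 0.05, 0.05, 0.05, 0.05)),
               "complete_shift")
  expect_equal(classify_delta_pattern(c(0.001, 0.004, 0.02, 0.05, 0.1)),
               "late_differences")
  expect_equal(classify_delta_pattern(c(0.1, 0.05, 0.02, 0.004, 0.001)),
               "early_differences")
  # mirrored (negative) versions classify identically
  expect_equal(classify_delta_pattern(-c(0.001, 0.004, 0.02, 0.05, 0.1)),
               "late_differences")
  expect_error(classify_delta_pattern(c(0, 1)), "at least 3")
})

test_that("the printed frequency-effect quantile rows classify as expected", {
  # group delta rows in milliseconds: thresholds rescaled to match the unit
  clear_row <- c(12.10, 17.17, 18.59, 19.24, 25.06)
  high_row <- c(31.46, 41.84, 48.68, 67.18, 98.36)
  low_row <- c(9.93, 12.14, 11.99, 13.62, 17.73)
  expect_equal(classify_delta_pattern(clear_row, eps = 10, slope_tol = 5),
               "complete_shift")
  expect_gt(coef(lm(clear_row ~ seq_along(clear_row)))[[2]], 0)
  expect_equal(classify_delta_pattern(high_row, eps = 10, slope_tol = 5),
               "late_differences")
  expect_equal(classify_delta_pattern(low_row, eps = 10, slope_tol = 5),
               "complete_shift")
})

test_that("classification is invariant to rescaling deltas with thresholds", {
  for (seed in 1:5) {
    withr::with_seed(seed, d <- cumsum(rnorm(5, 0.01, 0.02)))
    sec <- classify_delta_pattern(d, eps = 0.01, slope_tol = 0.005)
    ms <- classify_delta_pattern(d * 1000, eps = 10, slope_tol = 5)
    expect_equal(sec, ms)
  }
})

test_that("quantile and delta plots build without error", {
  prof <- make_two_cond_profile(list(clear = 0.5, high = 0.6),
                                list(clear = 0.2, high = 0.25), seed = 23)
  p1 <- autoplot(prof)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(delta_profile(prof, "high", "clear"))
  expect_s3_class(p2, "ggplot")
})
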