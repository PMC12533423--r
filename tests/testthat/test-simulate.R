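test_that("generation is deterministic given the seed", {
  a <- simulate_full_experiment("1A", n_subjects = 12, seed = 5)
  b <- simulate_full_experiment("1A", n_subjects = 12, seed = 5)
  c <- simulate_full_experiment("1A", n_subjects = 12, seed = 6)
  expect_equal(a$trials, b$trials)
  expect_false(isTRUE(all.equal(a$trials$rt, c$trials$rt)))
})

test_that("the lexical-decision preset has the reference design structure", {
  sim <- simulate_full_experiment("1A", n_subjects = 216, seed = 2)
  enc <- sim$trials[sim$trials$phase == "encoding", ]
  test <- sim$trials[sim$trials$phase == "test", ]
  expect_equal(dplyr::n_distinct(sim$trials$subject_id), 216)
  expect_equal(dplyr::n_distinct(sim$trials$list_id), 6)
  one_enc <- enc[enc$subject_id == enc$subject_id[1], ]
  expect_equal(sum(one_enc$stim_class == "word"), 84)
  expect_equal(sum(one_enc$stim_class == "nonword"), 84)
  expect_equal(dplyr::count(one_enc[one_enc$stim_class == "word", ], blur)$n,
               rep(28, 3))
  one_test <- test[test$subject_id == test$subject_id[1], ]
  expect_equal(nrow(one_test), 168)
  expect_equal(sum(one_test$status == "old"), 84)
})

test_that("zero subjects yields ground truth only", {
  sim <- simulate_full_experiment("1A", n_subjects = 0, seed = 1)
  expect_equal(nrow(sim$trials), 0)
  expect_named(sim$ground_truth$encoding,
               c("blur", "mu", "sigma", "tau", "error_rate"))
})

test_that("the semantic-categorisation preset keeps the 2:1 composition", {
  sim <- simulate_full_experiment("2", n_subjects = 6, seed = 3)
  enc <- sim$trials[sim$trials$phase == "encoding", ]
  one <- enc[enc$subject_id == enc$subject_id[1], ]
  expect_equal(sum(one$stim_class == "nonanimal"), 90)
  expect_equal(sum(one$stim_class == "animal"), 45)
  expect_setequal(unique(one$frequency[one$stim_class == "nonanimal"]),
                  c("high", "low"))
  expect_equal(unique(sim$trials$task[sim$trials$phase == "encoding"]), "semcat")
})

test_that("clear-at-test designs keep the yoked blur tag on test trials", {
  sim <- simulate_full_experiment("1B", n_subjects = 6, seed = 4)
  test <- sim$trials[sim$trials$phase == "test", ]
  expect_true(all(test$rendered == "clear"))
  expect_setequal(unique(test$blur[test$status == "new"]),
                  c("clear", "low", "high"))
})

test_that("the stage-specific scenario elevates mean and skew for high blur", {
  sim <- simulate_full_experiment("1A", n_subjects = 60,
                                  scenario = "stage_specific", seed = 7)
  rts <- select_rt_analysis_trials(sim$trials[sim$trials$phase == "encoding", ],
                                   "ldt")
  by_blur <- rts |>
    dplyr::group_by(.data$blur) |>
    dplyr::summarise(m = mean(.data$rt),
                     skew = mean((.data$rt - mean(.data$rt))^3) / sd(.data$rt)^3,
                     .groups = "drop")
  m <- setNames(by_blur$m, by_blur$blur)
  sk <- setNames(by_blur$skew, by_blur$blur)
  expect_gt(m[["high"]] - m[["clear"]], 0.1)
  expect_gt(sk[["high"]], sk[["clear"]])
})

test_that("identical generating cells give exchangeable condition means", {
  sim <- simulate_full_experiment("1A", n_subjects = 60, scenario = "null",
                                  subject_sd = c(mu = 0, log_sigma = 0, log_tau = 0),
                                  item_sd = c(mu = 0, log_sigma = 0, log_tau = 0),
                                  seed = 8)
  rts <- select_rt_analysis_trials(sim$trials[sim$trials$phase == "encoding", ],
                                   "ldt")
  by_blur <- rts |>
    dplyr::group_by(.data$blur) |>
    dplyr::summarise(m = mean(.data$rt), n = dplyr::n(), .groups = "drop")
  mc_se <- sqrt(0.08^2 + 0.2^2) / sqrt(min(by_blur$n))
  expect_lt(max(by_blur$m) - min(by_blur$m), 4 * mc_se)
})

test_that("the diffusion generator links accuracy to drift and ter orderings", {
  design <- tidyr::expand_grid(blur = c("clear", "high"), idx = 1:400) |>
    dplyr::mutate(list_id = 1, item_id = paste0("w", dplyr::row_number()),
                  status = "old", stim_class = "word")
  subjects <- tibble::tibble(subject_id = "s1", list_id = 1)
  params <- tibble::tibble(blur = c("clear", "high"),
                           v = c(2.5, 1.5), a = 1.4, z = 0.5,
                           ter = c(0.35, 0.45))
  tr <- simulate_encoding(design, subjects, params, generator = "ddm", seed = 9)
  acc <- tr |>
    dplyr::group_by(.data$blur) |>
    dplyr::summarise(acc = mean(.data$accuracy), m = mean(.data$rt),
                     .groups = "drop")
  a <- setNames(acc$acc, acc$blur)
  expect_gt(a[["clear"]], a[["high"]])
  expect_equal(a[["clear"]], ddm_boundary_prob(2.5, 1.4, 0.5, "upper"),
               tolerance = 0.05)
})

test_that("mismatched condition labels are rejected", {
  design <- tibble::tibble(list_id = 1, item_id = "w1", status = "old",
                           blur = "extreme", stim_class = "word")
  subjects <- tibble::tibble(subject_id = "s1", list_id = 1)
  params <- encoding_preset("null")
  expect_error(simulate_encoding(design, subjects, params), "absent")
})

test_that("recognition generation respects status coding and seed", {
  design <- tibble::tibble(list_id = 1, item_id = paste0("w", 1:100),
                           status = rep(c("old", "new"), 50), blur = "clear")
  subjects <- tibble::tibble(subject_id = c("s1", "s2"), list_id = 1)
  params <- tibble::tibble(blur = "clear", dprime = 3, criterion = 0)
  tr <- simulate_recognition(design, subjects, params, seed = 10)
  expect_equal(nrow(tr), 200)
  # strong sensitivity: hits far outnumber false alarms
  cnt <- tabulate_recognition(tr)
  expect_gt(cnt$hits / cnt$n_old, 0.9)
  expect_lt(cnt$false_alarms / cnt$n_new, 0.1)
  expect_equal(simulate_recognition(design, subjects, params, seed = 10), tr)
})
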