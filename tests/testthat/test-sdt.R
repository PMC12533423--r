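rec_trials <- function(n_old, n_new, n_hits, n_fas, blur = "clear") {
  dplyr::bind_rows(
    tibble::tibble(status = "old", blur = blur,
                   response = c(rep("old", n_hits), rep("new", n_old - n_hits))),
    tibble::tibble(status = "new", blur = blur,
                   response = c(rep("old", n_fas), rep("new", n_new - n_fas)))
  ) |>
    dplyr::mutate(subject_id = "s1", phase = "test", rt = NA_real_)
}

test_that("recognition tabulation reproduces hand counts", {
  tr <- rec_trials(10, 10, 7, 3)
  cnt <- tabulate_recognition(tr)
  expect_equal(cnt$hits, 7)
  expect_equal(cnt$misses, 3)
  expect_equal(cnt$false_alarms, 3)
  expect_equal(cnt$correct_rejections, 7)
  expect_equal(cnt$hits + cnt$misses, cnt$n_old)
  expect_equal(cnt$false_alarms + cnt$correct_rejections, cnt$n_new)
})

test_that("tabulation is order-invariant and all-correct data have empty error cells", {
  tr <- rec_trials(8, 8, 8, 0)
  cnt <- tabulate_recognition(tr)
  expect_equal(cnt$misses, 0)
  expect_equal(cnt$false_alarms, 0)
  withr::with_seed(5, shuffled <- tr[sample(nrow(tr)), ])
  expect_equal(tabulate_recognition(shuffled), cnt)
  bad <- dplyr::mutate(tr, status = "na")
  expect_error(tabulate_recognition(bad), "old")
})

test_that("d-prime and criterion follow the inverse-normal formulas", {
  # hit 0.691 / fa 0.309 is the d' = 1, c = 0 point of the equal-variance model
  cnt <- tibble::tibble(blur = "clear", n_old = 1000, n_new = 1000,
                        hits = 691, misses = 309,
                        false_alarms = 309, correct_rejections = 691)
  est <- dprime_criterion(cnt, correction = "none")
  expect_equal(est$dprime, qnorm(0.691) - qnorm(0.309), tolerance = 1e-12)
  expect_equal(est$dprime, 1, tolerance = 0.01)
  expect_equal(est$criterion, 0, tolerance = 1e-10)
  expect_equal(est$c_model, -est$criterion)
})

test_that("equal hit and false-alarm rates give zero sensitivity", {
  cnt <- tibble::tibble(blur = "x", n_old = 50, n_new = 50, hits = 30,
                        misses = 20, false_alarms = 30, correct_rejections = 20)
  expect_equal(dprime_criterion(cnt, correction = "none")$dprime, 0)
})

test_that("the log-linear correction keeps extreme rates finite", {
  cnt <- tibble::tibble(blur = "x", n_old = 20, n_new = 20, hits = 20,
                        misses = 0, false_alarms = 0, correct_rejections = 20)
  est <- dprime_criterion(cnt)
  expect_true(is.finite(est$dprime))
  expect_equal(est$hit_rate, 20.5 / 21)
  expect_equal(est$fa_rate, 0.5 / 21)
})

test_that("generative d-prime and criterion are recovered at n = 500/500", {
  design <- tibble::tibble(list_id = 1,
                           item_id = paste0("w", 1:1000),
                           status = rep(c("old", "new"), each = 500),
                           blur = "clear")
  subjects <- tibble::tibble(subject_id = "s1", list_id = 1)
  params <- tibble::tibble(blur = "clear", dprime = 0.8, criterion = 0.2)
  tr <- simulate_recognition(design, subjects, params, seed = 12)
  est <- dprime_criterion(tabulate_recognition(tr))
  expect_lt(abs(est$dprime - 0.8), 0.1)
  expect_lt(abs(est$criterion - 0.2), 0.1)
})

test_that("chance and moderate-sensitivity generative rates match theory", {
  design <- tibble::tibble(list_id = 1, item_id = paste0("w", 1:4000),
                           status = rep(c("old", "new"), each = 2000),
                           blur = "clear")
  subjects <- tibble::tibble(subject_id = "s1", list_id = 1)
  chance <- simulate_recognition(design, subjects,
                                 tibble::tibble(blur = "clear", dprime = 0,
                                                criterion = 0), seed = 3)
  cnt <- tabulate_recognition(chance)
  expect_equal(cnt$hits / cnt$n_old, 0.5, tolerance = 0.03)
  expect_equal(cnt$false_alarms / cnt$n_new, 0.5, tolerance = 0.03)
  d1 <- simulate_recognition(design, subjects,
                             tibble::tibble(blur = "clear", dprime = 1,
                                            criterion = 0), seed = 4)
  cnt1 <- tabulate_recognition(d1)
  expect_equal(cnt1$hits / cnt1$n_old, pnorm(0.5), tolerance = 0.03)
  expect_equal(cnt1$false_alarms / cnt1$n_new, pnorm(-0.5), tolerance = 0.03)
})

test_that("rate-based estimates equal the two-cell probit regression exactly", {
  tr <- rec_trials(40, 40, 28, 12)
  est <- dprime_criterion(tabulate_recognition(tr))
  fit <- fit_probit_sdt(tr, contrasts = list(c0 = contrast_spec("blur", c(clear = 0))))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # the status coefficient is d', the intercept is -c; the regression uses
  # the same log-linear correction as the rate path when cells are extreme,
  # here no correction applies on either path
  est_raw <- dprime_criterion(tabulate_recognition(tr), correction = "none")
  expect_equal(unname(co[["status"]]), est_raw$dprime, tolerance = 1e-8)
  expect_equal(unname(co[["intercept"]]), est_raw$c_model, tolerance = 1e-8)
})

test_that("bernoulli and binomial likelihoods give identical point estimates", {
  tr <- dplyr::bind_rows(rec_trials(30, 30, 22, 9, blur = "clear"),
                         rec_trials(30, 30, 25, 7, blur = "high"))
  cts <- list(b1 = contrast_spec("blur", c(clear = -0.5, high = 0.5)))
  fb <- fit_probit_sdt(tr, contrasts = cts, family = "binomial")
  fm <- fit_probit_sdt(tr, contrasts = cts, family = "bernoulli")
  expect_equal(fb$coefficients$estimate, fm$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("status-by-contrast interactions recover d-prime differences", {
  design <- tidyr::expand_grid(
    blur = c("clear", "high"),
    status = c("old", "new"),
    idx = 1:2000
  ) |>
    dplyr::mutate(list_id = 1, item_id = paste0("w", dplyr::row_number()))
  subjects <- tibble::tibble(subject_id = "s1", list_id = 1)
  params <- tibble::tibble(blur = c("clear", "high"),
                           dprime = c(1.0, 1.3), criterion = 0.1)
  tr <- simulate_recognition(design, subjects, params, seed = 31)
  cts <- list(b1 = contrast_spec("blur", c(clear = -0.5, high = 0.5)))
  fit <- fit_probit_sdt(tr, contrasts = cts)
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$std_error, fit$coefficients$term)
  expect_lt(abs(co[["status:b1"]] - 0.3), 3 * se[["status:b1"]])
  expect_equal(unname(co[["status"]]), 1.15, tolerance = 0.1)
})

test_that("a null single condition gives a status coefficient covering zero", {
  design <- tibble::tibble(list_id = 1, item_id = paste0("w", 1:2000),
                           status = rep(c("old", "new"), each = 1000),
                           blur = "clear")
  subjects <- tibble::tibble(subject_id = "s1", list_id = 1)
  tr <- simulate_recognition(design, subjects,
                             tibble::tibble(blur = "clear", dprime = 0,
                                            criterion = 0), seed = 41)
  fit <- fit_probit_sdt(tr, contrasts = list(c0 = contrast_spec("blur", c(clear = 0))))
  co <- fit$coefficients
  st <- co[co$term == "status", ]
  expect_lt(abs(st$estimate), 2.5 * st$std_error)
})

test_that("d-prime is invariant under full response/status relabeling", {
  tr <- rec_trials(50, 50, 35, 15)
  flipped <- tr |>
    dplyr::mutate(status = ifelse(.data$status == "old", "new", "old"),
                  response = ifelse(.data$response == "old", "new", "old"))
  a <- dprime_criterion(tabulate_recognition(tr))
  b <- dprime_criterion(tabulate_recognition(flipped))
  expect_equal(a$dprime, b$dprime, tolerance = 1e-12)
})

test_that("separation in a cell is corrected and flagged", {
  tr <- dplyr::bind_rows(rec_trials(20, 20, 20, 0, blur = "clear"),
                         rec_trials(20, 20, 15, 5, blur = "high"))
  cts <- list(b1 = contrast_spec("blur", c(clear = -0.5, high = 0.5)))
  fit <- fit_probit_sdt(tr, contrasts = cts)
  expect_true("separation_corrected" %in% fit$flags)
  expect_true(all(is.finite(fit$coefficients$estimate)))
})

test_that("sdt estimates plot and tidy methods work", {
  tr <- rec_trials(30, 30, 20, 10)
  est <- dprime_criterion(tabulate_recognition(tr))
  expect_s3_class(autoplot(est), "ggplot")
  fit <- fit_probit_sdt(tr, contrasts = list(c0 = contrast_spec("blur", c(clear = 0))))
  expect_true(all(c("term", "estimate") %in% names(tidy(fit))))
  expect_equal(glance(fit)$family, "binomial")
})
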