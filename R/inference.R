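#' Summarise a draw set for one contrast effect
#'
#' Condenses bootstrap (or posterior) draws of a contrast coefficient
#' into the standard reporting row: mean, SE (the draw SD), an
#' equal-tailed credible interval — 90% for directional hypotheses, 95%
#' for two-sided ones — the posterior probability that the effect lies
#' in the hypothesised direction, and the evidence ratio
#' `ER = p / (1 - p)` (the directional posterior odds; `Inf` when every
#' draw falls on the hypothesised side).
#'
#' @param draws numeric vector of at least 1000 draws.
#' @param direction `"greater"`, `"less"`, or `"two_sided"`.
#' @param cri_level interval mass in percent; defaults to 90 for
#'   directional hypotheses and 95 for two-sided.
#' @param parameter,contrast optional labels carried into the output.
#' @return a one-row tibble of class `effect_summary` with columns
#'   `parameter`, `contrast`, `direction`, `mean`, `se`, `cri_level`,
#'   `cri_lower`, `cri_upper`, `posterior_prob`, `evidence_ratio`.
#' @examples
#' summarize_effect(rnorm(2000, 0.3, 0.1), direction = "greater")
#' @export
summarize_effect <- function(draws, direction = c("greater", "less", "two_sided"),
                             cri_level = NULL, parameter = NA_character_,
                             contrast = NA_character_) {
  direction <- match.arg(direction)
  if (length(draws) < 1000) {
    abort("summarize_effect() needs at least 1000 draws.")
  }
  cri_level <- cri_level %||% if (direction == "two_sided") 95 else 90
  alpha <- (100 - cri_level) / 100
  ci <- unname(quantile(draws, c(alpha / 2, 1 - alpha / 2), type = 7))
  p_dir <- switch(direction,
    greater = mean(draws > 0),
    less = mean(draws < 0),
    # two-sided: probability mass on the side of the point estimate
    two_sided = max(mean(draws > 0), mean(draws < 0))
  )
  er <- if (p_dir >= 1) Inf else p_dir / (1 - p_dir)
  out <- tibble::tibble(
    parameter = parameter, contrast = contrast, direction = direction,
    mean = mean(draws), se = sd(draws),
    cri_level = cri_level, cri_lower = ci[1], cri_upper = ci[2],
    posterior_prob = p_dir, evidence_ratio = er
  )
  structure(out, class = c("effect_summary", class(out)))
}

#' Apply the directional hypothesis decision rule
#'
#' A directional hypothesis is `supported` only if all three hold: zero
#' is excluded from the credible interval, the posterior probability
#' reaches `prob_floor`, and the evidence ratio exceeds `er_threshold`.
#' The tri-state evidence label follows the conventional reading of the
#' evidence ratio: above 3 is moderate-to-strong support, below 0.3
#' supports the alternative, and values between are inconclusive.
#'
#' @param summary an [summarize_effect()] row (or tibble of rows).
#' @param er_threshold evidence-ratio bar (default 3).
#' @param prob_floor posterior-probability bar (default 0.95).
#' @return a tibble with one row per input row: `supported`,
#'   `zero_excluded`, `posterior_prob_high`, `er_above_threshold`, and
#'   the `evidence` label (`"supported"` / `"alternative"` /
#'   `"inconclusive"`).
#' @export
decide_hypothesis <- function(summary, er_threshold = 3, prob_floor = 0.95) {
  stopifnot(all(c("cri_lower", "cri_upper", "posterior_prob",
                  "evidence_ratio") %in% names(summary)))
  zero_excluded <- summary$cri_lower > 0 | summary$cri_upper < 0
  prob_high <- summary$posterior_prob >= prob_floor
  er_above <- summary$evidence_ratio > er_threshold
  evidence <- dplyr::case_when(
    summary$evidence_ratio > er_threshold ~ "supported",
    summary$evidence_ratio < 1 / er_threshold ~ "alternative",
    TRUE ~ "inconclusive"
  )
  tibble::tibble(
    parameter = summary$parameter %||% NA_character_,
    contrast = summary$contrast %||% NA_character_,
    supported = zero_excluded & prob_high & er_above,
    zero_excluded = zero_excluded,
    posterior_prob_high = prob_high,
    er_above_threshold = er_above,
    evidence = evidence
  )
}

#' Bootstrap draws of contrast coefficients
#'
#' Case-resampling bootstrap over subjects. For a two-stage
#' distributional fit (or any object carrying a per-subject coefficient
#' table) each bootstrap replicate resamples subjects with replacement
#' and averages their coefficients, yielding seed-deterministic draws of
#' every contrast coefficient. The default draw count (16,000) mirrors
#' the posterior sample sizes typical of the hierarchical Bayesian
#' counterpart of this analysis.
#'
#' @param fit an `exgauss_dist_fit` (two-stage), or a tibble with
#'   columns `subject_id`, `parameter`, `term`, `estimate`, or a plain
#'   numeric vector of per-subject values (one coefficient).
#' @param n_boot number of bootstrap draws (default 16000; below 1000 a
#'   warning is issued).
#' @param seed integer seed.
#' @return a tibble with columns `parameter`, `term`, `draw` (replicate
#'   index), `value`; for a numeric input, a numeric vector of draws.
#' @export
bootstrap_contrast_draws <- function(fit, n_boot = 16000, seed = 1) {
  if (n_boot < 1000) warn("fewer than 1000 bootstrap draws requested.")
  if (is.numeric(fit)) {
    x <- fit[is.finite(fit)]
    if (length(x) < 2) abort("bootstrap needs at least 2 subjects.")
    return(withr::with_seed(seed, {
      idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                    nrow = n_boot)
      rowMeans(matrix(x[idx], nrow = n_boot))
    }))
  }
  subj <- if (inherits(fit, "exgauss_dist_fit")) {
    if (is.null(fit$subject_coefficients)) {
      abort("bootstrap_contrast_draws() needs a two-stage fit with subject-level coefficients.")
    }
    fit$subject_coefficients
  } else {
    fit
  }
  stopifnot(all(c("subject_id", "parameter", "term", "estimate") %in% names(subj)))
  wide <- subj |>
    tidyr::pivot_wider(names_from = c("parameter", "term"),
                       values_from = "estimate", names_sep = "\r")
  ids <- wide$subject_id
  if (length(ids) < 2) abort("bootstrap needs at least 2 subjects.")
  M <- as.matrix(wide[, setdiff(names(wide), "subject_id")])
  draws <- withr::with_seed(seed, {
    idx <- matrix(sample.int(nrow(M), nrow(M) * n_boot, replace = TRUE),
                  nrow = n_boot)
    out <- matrix(NA_real_, n_boot, ncol(M))
    for (j in seq_len(ncol(M))) {
      col <- M[, j]
      out[, j] <- rowMeans(matrix(col[idx], nrow = n_boot))
    }
    out
  })
  keys <- strsplit(colnames(M), "\r", fixed = TRUE)
  purrr::imap_dfr(seq_len(ncol(M)), function(j, i) {
    tibble::tibble(
      parameter = keys[[j]][1], term = keys[[j]][2],
      draw = seq_len(n_boot), value = draws[, j]
    )
  })
}

#' Exact one-sample power via the noncentral t distribution
#'
#' Power of the one-sample t test for a standardised effect `delta` at
#' sample size `n`: noncentrality `delta * sqrt(n)`, rejection at the
#' upper `alpha` t quantile (one-sided) or `alpha/2` (two-sided, power
#' summed over both tails).
#'
#' @param n sample size (>= 2).
#' @param delta standardised effect size.
#' @param alpha type-I error rate.
#' @param sided `"one"` or `"two"`.
#' @return the power (proportion).
#' @examples
#' power_one_sample(216, 0.20)  # ~0.90
#' @export
power_one_sample <- function(n, delta, alpha = 0.05, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- delta * sqrt(n)
  if (sided == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    (1 - pt(crit, df, ncp)) + pt(-crit, df, ncp)
  }
}
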