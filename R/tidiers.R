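#' Tidy an ex-Gaussian ML fit
#'
#' @param x an `exgauss_fit`.
#' @param ... unused.
#' @return a tibble with `term` and `estimate`.
#' @export
tidy.exgauss_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.exgauss_fit
#' @export
glance.exgauss_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, convergence = x$convergence)
}

#' Tidy a distributional ex-Gaussian fit
#'
#' @param x an `exgauss_dist_fit`.
#' @param ... unused.
#' @return the coefficient tibble (`parameter`, `term`, `estimate`,
#'   `se`, `n_subjects`).
#' @export
tidy.exgauss_dist_fit <- function(x, ...) x$coefficients

#' @rdname tidy.exgauss_dist_fit
#' @export
glance.exgauss_dist_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_subjects = if (!is.null(x$subject_coefficients)) {
      length(unique(x$subject_coefficients$subject_id))
    } else {
      NA_integer_
    },
    n_dropped = length(x$dropped_subjects)
  )
}

#' Tidy a per-condition Wiener diffusion fit
#'
#' @param x a `ddm_fit`.
#' @param ... unused.
#' @return a long tibble with `condition`, `term`, `estimate`.
#' @export
tidy.ddm_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("v", "a", "z", "ter"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::select("condition", "term", "estimate")
}

#' @rdname tidy.ddm_fit
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("condition", "loglik", "n", "status")]
}

#' Tidy a probit SDT fit
#'
#' @param x an `sdt_fit`.
#' @param ... unused.
#' @return the coefficient tibble (`term`, `estimate`, `std_error`).
#'   The `status` coefficient is the grand d'; `status:` interaction
#'   terms are d' differences; plain contrast terms are criterion
#'   differences on the reversed-sign scale.
#' @export
tidy.sdt_fit <- function(x, ...) x$coefficients

#' @rdname tidy.sdt_fit
#' @export
glance.sdt_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    deviance = x$glm$deviance,
    n_cells = nrow(x$cells),
    flags = paste(x$flags, collapse = ";")
  )
}
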