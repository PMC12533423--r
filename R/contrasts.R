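#' Contrast codes for the blur and frequency factors
#'
#' The two orthogonal planned comparisons for the three-level blur
#' factor, as coded in the distributional and recognition models:
#'
#' * `blur1` — high blur against the average of clear and low blur:
#'   high = 0.5, clear = -0.5, low = -0.5. Note these printed weights do
#'   not sum to zero; `centered = TRUE` switches to the zero-sum variant
#'   (high = 0.5, clear = -0.25, low = -0.25), which is not the default.
#' * `blur2` — low blur against clear: low = 0.5, clear = -0.5,
#'   high = 0.
#'
#' The two-level frequency factor is coded high = 0.5, low = -0.5.
#'
#' @param centered use the zero-sum variant of `blur1` (default `FALSE`,
#'   i.e. the printed weights).
#' @return `blur_contrasts()`: a named list of two [contrast_spec()]s;
#'   `frequency_contrast()`: a single [contrast_spec()].
#' @export
blur_contrasts <- function(centered = FALSE) {
  c1 <- if (centered) {
    c(clear = -0.25, low = -0.25, high = 0.5)
  } else {
    c(clear = -0.5, low = -0.5, high = 0.5)
  }
  list(
    blur1 = contrast_spec("blur", c1),
    blur2 = contrast_spec("blur", c(clear = -0.5, low = 0.5, high = 0))
  )
}

#' @rdname blur_contrasts
#' @export
frequency_contrast <- function() {
  contrast_spec("frequency", c(high = 0.5, low = -0.5))
}

#' Define a contrast over the levels of a factor
#'
#' @param factor name of the factor column the contrast applies to.
#' @param weights named numeric vector mapping every level to its
#'   weight.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(factor, weights) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    abort("`weights` must be a fully named numeric vector.")
  }
  structure(list(factor = factor, weights = weights), class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("Contrast on", x$factor, ":",
      paste(names(x$weights), x$weights, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Design matrix over condition cells for a set of contrasts (plus all
# interactions between contrasts on different factors), with intercept.
# `cells` is a data frame of condition columns; returns a matrix with one
# row per cell, invertible when the contrasts saturate the cells.
contrast_design_matrix <- function(cells, contrasts) {
  stopifnot(is.list(contrasts), length(contrasts) > 0)
  cols <- lapply(contrasts, function(ct) {
    lev <- as.character(cells[[ct$factor]])
    missing_lev <- setdiff(unique(lev), names(ct$weights))
    if (length(missing_lev)) {
      abort(paste0("contrast on ", ct$factor, " lacks weights for level(s): ",
                   paste(missing_lev, collapse = ", ")))
    }
    unname(ct$weights[lev])
  })
  names(cols) <- names(contrasts) %||% paste0("c", seq_along(contrasts))
  X <- cbind(intercept = 1, do.call(cbind, cols))
  # interactions across distinct factors
  facs <- vapply(contrasts, function(ct) ct$factor, character(1))
  nm <- colnames(X)[-1]
  if (length(unique(facs)) > 1) {
    for (i in seq_along(contrasts)) {
      for (j in seq_along(contrasts)) {
        if (i < j && facs[i] != facs[j]) {
          X <- cbind(X, X[, nm[i]] * X[, nm[j]])
          colnames(X)[ncol(X)] <- paste0(nm[i], ":", nm[j])
        }
      }
    }
  }
  X
}
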