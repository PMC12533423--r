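#' Wiener first-passage-time density
#'
#' Defective density of the first-passage time of a drift-diffusion
#' process (unit diffusion coefficient) with drift `v`, boundary
#' separation `a`, relative start point `z` (start at `z * a`), and
#' non-decision time `ter`, absorbed at the named boundary. The two
#' defective densities integrate to the closed-form absorption
#' probabilities and jointly to 1.
#'
#' Evaluation uses the standard pair of series expansions of the
#' zero-drift unit-boundary kernel — a small-time expansion over mirrored
#' start points and a large-time Fourier sine expansion — truncated at
#' the number of terms required for an absolute tolerance `eps`, and for
#' each `t` the expansion needing fewer terms is used.
#'
#' @param t vector of response times (seconds). Density is 0 for
#'   `t <= ter`.
#' @param v drift rate (evidence units per second); positive drifts
#'   favour the upper boundary.
#' @param a boundary separation (> 0).
#' @param z relative start point in (0, 1); 0.5 is unbiased.
#' @param ter non-decision time in seconds (>= 0), shifting the whole
#'   distribution right.
#' @param boundary which absorbing boundary: `"upper"` or `"lower"`.
#' @param eps absolute truncation tolerance (default 1e-8).
#' @return vector of defective density values.
#' @examples
#' tt <- seq(0.31, 2, by = 0.01)
#' d <- dwiener(tt, v = 1, a = 1.5, z = 0.5, ter = 0.3, boundary = "upper")
#' @export
dwiener <- function(t, v, a, z = 0.5, ter = 0,
                    boundary = c("upper", "lower"), eps = 1e-8) {
  boundary <- match.arg(boundary)
  check_ddm_params(v, a, z, ter)
  if (boundary == "upper") {
    v <- -v
    z <- 1 - z
  }
  # density at the LOWER boundary of a process with drift v, start w = z
  out <- numeric(length(t))
  u <- (t - ter) / a^2
  pos <- is.finite(t) & u > 0
  if (any(pos)) {
    f0 <- wiener_kernel(u[pos], z, eps * a^2)
    out[pos] <- f0 / a^2 * exp(-v * a * z - v^2 * (t[pos] - ter) / 2)
  }
  out
}

# zero-drift, unit-boundary first-passage kernel at the lower boundary,
# start point w; adaptive choice between small- and large-time expansions
wiener_kernel <- function(u, w, eps) {
  ks <- kappa_small(u, eps)
  kl <- kappa_large(u, eps)
  vapply(seq_along(u), function(i) {
    if (ks[i] <= kl[i]) {
      wiener_kernel_small(u[i], w, ks[i])
    } else {
      wiener_kernel_large(u[i], w, kl[i])
    }
  }, numeric(1))
}

# required mirrored-path terms for absolute error < eps (small-time)
kappa_small <- function(u, eps) {
  k <- rep(2, length(u))
  cond <- 2 * sqrt(2 * pi * u) * eps < 1
  k[cond] <- 2 + sqrt(-2 * u[cond] * log(2 * sqrt(2 * pi * u[cond]) * eps))
  ceiling(pmax(k, sqrt(u) + 1))
}

# required Fourier terms for absolute error < eps (large-time)
kappa_large <- function(u, eps) {
  k <- rep(1, length(u))
  cond <- pi * u * eps < 1
  k[cond] <- sqrt(-2 * log(pi * u[cond] * eps) / (pi^2 * u[cond]))
  ceiling(pmax(k, 1 / (pi * sqrt(u))))
}

wiener_kernel_small <- function(u, w, K) {
  ks <- seq(-ceiling(K / 2), ceiling(K / 2))
  terms <- (w + 2 * ks) * exp(-(w + 2 * ks)^2 / (2 * u))
  sum(terms) / sqrt(2 * pi * u^3)
}

wiener_kernel_large <- function(u, w, K) {
  ks <- seq_len(max(ceiling(K), 1))
  pi * sum(ks * exp(-ks^2 * pi^2 * u / 2) * sin(ks * pi * w))
}

check_ddm_params <- function(v, a, z, ter) {
  if (!is.finite(v)) abort("`v` must be finite.")
  if (!is.finite(a) || a <= 0) abort("`a` must be > 0.")
  if (!is.finite(z) || z <= 0 || z >= 1) abort("`z` must lie in (0, 1).")
  if (!is.finite(ter) || ter < 0) abort("`ter` must be >= 0.")
  invisible(NULL)
}

#' Closed-form boundary absorption probabilities
#'
#' Probability that the diffusion (drift `v`, separation `a`, start
#' `z * a`, unit diffusion) is absorbed at the named boundary:
#' `P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))`, with the
#' zero-drift limit `P(upper) = z`.
#'
#' @inheritParams dwiener
#' @return absorption probability.
#' @export
ddm_boundary_prob <- function(v, a, z = 0.5, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  check_ddm_params(v, a, z, 0)
  p_upper <- if (abs(v) < 1e-10) {
    z
  } else {
    expm1(-2 * v * a * z) / expm1(-2 * v * a)
  }
  if (boundary == "upper") p_upper else 1 - p_upper
}

#' Simulate drift-diffusion trials
#'
#' Euler-Maruyama simulation of the diffusion with a Brownian-bridge
#' crossing correction: at each step the probability that the bridge
#' between successive interior positions crossed a boundary,
#' `exp(-2 d0 d1 / dt)` for distances `d0`, `d1` to that boundary, is
#' applied, which removes most of the discretisation bias of plain Euler
#' stepping.
#'
#' @inheritParams dwiener
#' @param n number of trials.
#' @param dt integration step in seconds (default 1e-3).
#' @param seed integer seed; simulation is deterministic given `seed`.
#' @param t_max decision-time cap in seconds; the rare paths still
#'   unabsorbed at `t_max` are assigned the boundary they are closer to
#'   at the cap.
#' @return a tibble with columns `rt` (first-passage time + `ter`,
#'   seconds) and `boundary` (`"upper"`/`"lower"`).
#' @export
simulate_ddm_trials <- function(n, v, a, z = 0.5, ter = 0,
                                dt = 1e-3, seed = 1, t_max = 20) {
  check_ddm_params(v, a, z, ter)
  withr::with_seed(seed, {
    x <- rep(z * a, n)
    t_dec <- rep(NA_real_, n)
    hit_upper <- rep(NA, n)
    alive <- seq_len(n)
    sq <- sqrt(dt)
    step <- 0L
    while (length(alive) > 0 && step * dt < t_max) {
      step <- step + 1L
      x_new <- x[alive] + v * dt + sq * rnorm(length(alive))
      crossed_up <- x_new >= a
      crossed_lo <- x_new <= 0
      interior <- !crossed_up & !crossed_lo
      if (any(interior)) {
        xi0 <- x[alive][interior]; xi1 <- x_new[interior]
        p_lo <- exp(-2 * xi0 * xi1 / dt)
        p_up <- exp(-2 * (a - xi0) * (a - xi1) / dt)
        uu <- runif(length(xi0))
        bridge_lo <- uu < p_lo
        bridge_up <- !bridge_lo & uu < p_lo + p_up
        idx <- which(interior)
        crossed_lo[idx[bridge_lo]] <- TRUE
        crossed_up[idx[bridge_up]] <- TRUE
      }
      done <- crossed_up | crossed_lo
      if (any(done)) {
        gi <- alive[done]
        t_dec[gi] <- step * dt
        hit_upper[gi] <- crossed_up[done]
      }
      x[alive] <- x_new
      alive <- alive[!done]
    }
    if (length(alive) > 0) {  # cap stragglers
      t_dec[alive] <- t_max
      hit_upper[alive] <- x[alive] > a / 2
    }
    tibble::tibble(
      rt = t_dec + ter,
      boundary = ifelse(hit_upper, "upper", "lower")
    )
  })
}

#' EZ-diffusion closed-form estimates
#'
#' Method-of-moments estimator mapping accuracy, correct-RT variance and
#' correct-RT mean to diffusion parameters (unit diffusion scaling,
#' unbiased start `z = 0.5`): with `L = logit(p)`,
#' `v = sign(p - 1/2) * (L (p^2 L - p L + p - 1/2) / VRT)^{1/4}`,
#' `a = L / v`, and `ter = MRT - (a / 2v) (1 - e^{-va}) / (1 + e^{-va})`.
#' Used as the starting point of the full ML fit; at its own forward
#' moments the inversion is exact.
#'
#' Edge rule: accuracies of exactly 0, 0.5 or 1 are perturbed — `p` is
#' clamped to `[1/(2n), 1 - 1/(2n)]` (or `[0.001, 0.999]` if `n` is
#' unknown) and `p = 0.5` is nudged by half that clamp — so the closed
#' form is always defined.
#'
#' @param p_correct proportion correct in (0, 1).
#' @param rt_var variance of correct RTs (s^2).
#' @param rt_mean mean of correct RTs (s).
#' @param n number of trials behind `p_correct` (for the edge
#'   correction); optional.
#' @return a tibble with columns `v`, `a`, `z`, `ter`.
#' @examples
#' m <- ez_forward_moments(v = 1.2, a = 1.4, ter = 0.3)
#' ez_diffusion_estimate(m$p_correct, m$rt_var, m$rt_mean)  # exact round trip
#' @export
ez_diffusion_estimate <- function(p_correct, rt_var, rt_mean, n = NULL) {
  edge <- if (is.null(n)) 0.001 else 1 / (2 * n)
  p <- min(max(p_correct, edge), 1 - edge)
  if (abs(p - 0.5) < 1e-9) p <- 0.5 + edge / 2
  L <- log(p / (1 - p))
  x <- L * (L * p^2 - L * p + p - 0.5) / rt_var
  v <- sign(p - 0.5) * x^(1 / 4)
  a <- L / v
  y <- exp(-v * a)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  tibble::tibble(v = v, a = a, z = 0.5, ter = rt_mean - mdt)
}

#' Forward EZ-diffusion moments
#'
#' Predicted accuracy, correct-RT variance and mean for an unbiased
#' diffusion; the algebraic inverse of [ez_diffusion_estimate()].
#'
#' @inheritParams dwiener
#' @return a tibble with `p_correct`, `rt_var`, `rt_mean`.
#' @export
ez_forward_moments <- function(v, a, ter) {
  y <- exp(-v * a)
  p <- 1 / (1 + y)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  vrt <- (a / (2 * v^3)) * (1 - 2 * a * v * y - y^2) / (y + 1)^2
  tibble::tibble(p_correct = p, rt_var = vrt, rt_mean = mdt + ter)
}

#' Fit the four-parameter Wiener model per condition
#'
#' Maximum-likelihood fit of drift rate `v`, boundary separation `a` and
#' non-decision time `ter` (start point fixed at `z = 0.5` unless given)
#' to response times and binary outcomes, separately for each level of
#' `condition`. Accuracy coding is the default: correct responses absorb
#' at the upper boundary, errors at the lower. EZ-diffusion moments
#' provide starting values.
#'
#' @param trials a tibble with columns `rt` (seconds) and `accuracy`
#'   (0/1), plus optionally `condition` (any label; one fit per level).
#' @param z fixed relative start point (default 0.5).
#' @param min_trials trial floor per condition below which the fit is
#'   flagged with a warning status (default 40).
#' @return an object of class `ddm_fit`: a tibble with one row per
#'   condition and columns `condition`, `v`, `a`, `z`, `ter`, `loglik`,
#'   `n`, `status`. `tidy()` and `glance()` methods are provided.
#' @export
fit_ddm <- function(trials, z = 0.5, min_trials = 40) {
  stopifnot(all(c("rt", "accuracy") %in% names(trials)))
  if (!"condition" %in% names(trials)) trials$condition <- "all"
  fits <- trials |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ fit_ddm_one(.x, z = z, min_trials = min_trials)) |>
    dplyr::ungroup()
  structure(fits, class = c("ddm_fit", class(fits)))
}

fit_ddm_one <- function(d, z, min_trials) {
  rt <- d$rt
  correct <- d$accuracy == 1
  n <- length(rt)
  status <- "converged"
  if (n < min_trials) status <- "warning_few_trials"
  if (all(correct) || all(!correct)) status <- paste(status, "degenerate_accuracy", sep = ";")
  p_c <- mean(correct)
  ez <- ez_diffusion_estimate(p_c, max(var(rt[correct]), 1e-4),
                              mean(rt[correct]), n = n)
  ter0 <- min(max(ez$ter, 1e-3), min(rt) * 0.95)
  start <- c(ez$v, log(max(ez$a, 0.3)), qlogis(min(ter0 / min(rt), 0.98)))
  nll <- function(th) {
    v <- th[1]; a <- exp(th[2]); ter <- plogis(th[3]) * min(rt)
    du <- dwiener(rt[correct], v, a, z, ter, boundary = "upper")
    dl <- dwiener(rt[!correct], v, a, z, ter, boundary = "lower")
    ll <- sum(log(pmax(du, 1e-300))) + sum(log(pmax(dl, 1e-300)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 1500, reltol = 1e-9))
  if (opt$convergence != 0 && !grepl("warning", status)) status <- "warning_no_convergence"
  tibble::tibble(
    v = opt$par[1], a = exp(opt$par[2]), z = z,
    ter = plogis(opt$par[3]) * min(rt),
    loglik = -opt$value, n = n, status = status
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Wiener diffusion ML fits (z fixed)\n")
  NextMethod()
}
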