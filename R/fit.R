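#' Starting values for a Richards fit, read off the data
#'
#' Heuristic initialisation used by [fit_richards()]: `abs_min` from the
#' minimum OD, `abs_max` from the maximum, `t_i` from the midpoint of the
#' interval with the steepest discrete slope (the earliest such interval on
#' ties), and `mu_max` by inverting the model's maximum-slope identity
#' `max dABS/dt = (abs_max - abs_min) * mu_max * m * (1 + m)^(-(1 + 1/m))`.
#'
#' @param time,od Numeric vectors of equal length: hours and OD600 readings.
#' @param m Fixed dampening parameter the fit will use.
#' @param min_dynamic_range Minimum OD rise required to treat the well as
#'   grown (default 0.05 OD); below it a "no-growth" error is thrown.
#' @return A [richards_params()] object of starting values.
#' @export
initialize_richards <- function(time, od, m = 0.5, min_dynamic_range = 0.05) {
  check_curve(time, od)
  ord <- order(time)
  time <- time[ord]; od <- od[ord]
  rng <- max(od) - min(od)
  if (rng < min_dynamic_range) {
    stop_no_growth(rng, min_dynamic_range)
  }
  slopes <- diff(od) / diff(time)
  j <- which.max(slopes)                      # which.max takes the earliest tie
  t_i0 <- (time[j] + time[j + 1]) / 2
  peak <- m * (1 + m)^(-(1 + 1 / m))
  mu0 <- max(slopes) / (rng * peak)
  richards_params(
    abs_min = min(od),
    abs_max = max(od),
    mu_max  = min(max(mu0, 1e-3), 5),
    t_i     = max(t_i0, min(diff(time)) / 2),
    m       = m
  )
}

check_curve <- function(time, od) {
  if (length(time) != length(od)) {
    stop("`time` and `od` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(time)) || !all(is.finite(od))) {
    stop("`time` and `od` must be finite", call. = FALSE)
  }
  if (any(od < 0)) stop("OD readings must be >= 0", call. = FALSE)
  if (length(unique(time)) < 6) {
    stop("need at least 6 distinct time points to fit 4 parameters",
         call. = FALSE)
  }
  invisible(TRUE)
}

stop_no_growth <- function(rng, min_dynamic_range) {
  stop(structure(
    class = c("platefit_no_growth", "error", "condition"),
    list(message = sprintf(
      "no growth detected: OD dynamic range %.4g is below the minimum %.4g",
      rng, min_dynamic_range), call = NULL)))
}

# Deterministic multiplicative perturbations for restart starting values:
# no RNG involved, so fits are bit-reproducible for identical input.
restart_factors <- function(n) {
  base <- c(0.5, 2, 0.8, 1.25, 0.65, 1.5, 0.9, 1.1, 0.4, 2.5)
  f <- expand.grid(mu = base, ti = base)
  f[seq_len(min(n, nrow(f))), , drop = FALSE]
}

#' Fit the Richards model to one growth curve
#'
#' Nonlinear least squares (Levenberg–Marquardt via [minpack.lm::nlsLM()])
#' of the fixed-shape Richards absorbance model to one well's OD600 series.
#' Raw OD is fitted directly: the model carries an explicit `abs_min`, so no
#' blank subtraction or log transform is applied. Box constraints keep the
#' asymptotes from running away on truncated curves:
#' `abs_min` in \[0, max OD\], `abs_max` in (0, 2 max OD\],
#' `mu_max` in (0, 5\] per hour, `t_i` in \[0, 1.5 t_last\].
#'
#' The optimiser starts from [initialize_richards()]; if it fails to converge
#' (or errors), up to `n_restarts` deterministic perturbations of the start
#' are tried and the best converged solution kept.
#'
#' @inheritParams initialize_richards
#' @param n_restarts Maximum perturbed restarts after a failed first attempt.
#' @param start Optional [richards_params()] starting values overriding the
#'   data-derived initialiser.
#' @param max_iter,ftol Optimiser iteration cap and relative tolerance on the
#'   residual-sum-of-squares change.
#' @return An object of class `richards_fit`: list with elements `params`
#'   ([richards_params()]), `rss`, `n_points`, `converged`, `n_iterations`,
#'   `initializer` and `data`.
#' @examples
#' p <- richards_params(0.05, 1.0, 0.70, 8.0)
#' tt <- 0:22
#' fit <- fit_richards(tt, richards_abs(tt, p))
#' tidy(fit)
#' @export
fit_richards <- function(time, od, m = 0.5, min_dynamic_range = 0.05,
                         n_restarts = 20, start = NULL,
                         max_iter = 500, ftol = 1e-10) {
  check_curve(time, od)
  ord <- order(time)
  time <- time[ord]; od <- od[ord]
  init <- if (is.null(start)) {
    initialize_richards(time, od, m = m, min_dynamic_range = min_dynamic_range)
  } else {
    as_richards_params(start)
  }

  lower <- c(abs_min = 0, abs_max = 1e-8, mu_max = 1e-8, t_i = 1e-8)
  upper <- c(abs_min = max(od), abs_max = 2 * max(od), mu_max = 5,
             t_i = 1.5 * max(time))
  clamp <- function(p) pmin(pmax(p, lower + 1e-9), upper - 1e-9)

  one_attempt <- function(p0) {
    st <- clamp(c(abs_min = p0$abs_min, abs_max = p0$abs_max,
                  mu_max = p0$mu_max, t_i = p0$t_i))
    dat <- data.frame(time = time, od = od)
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      od ~ abs_min + (abs_max - abs_min) *
        (1 + m * exp(-mu_max * m * (time - t_i)))^(-1 / m),
      data = dat, start = as.list(st),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = ftol, ptol = 1e-12)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    est <- stats::coef(fit)
    if (est[["abs_max"]] <= est[["abs_min"]]) return(NULL)
    list(est = est, rss = sum(stats::resid(fit)^2),
         iter = fit$convInfo$finIter,
         converged = isTRUE(fit$convInfo$isConv))
  }

  best <- one_attempt(init)
  tried <- 1L
  fac <- restart_factors(n_restarts)
  n_polish <- min(6L, nrow(fac))   # always-run restarts guard local minima
  for (k in seq_len(nrow(fac))) {
    if (k > n_polish && !is.null(best) && best$converged) break
    p0 <- init
    p0$mu_max <- min(max(init$mu_max * fac$mu[k], 1e-3), 5)
    p0$t_i <- min(max(init$t_i * fac$ti[k], 0.1), 1.4 * max(time))
    cand <- one_attempt(p0)
    tried <- tried + 1L
    if (is.null(cand)) next
    if (is.null(best) ||
        (cand$converged && !best$converged) ||
        (cand$converged == best$converged && cand$rss < best$rss - 1e-14)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0(
      "Richards fit did not converge after %d starts; ",
      "initial values: abs_min=%.3g abs_max=%.3g mu_max=%.3g t_i=%.3g"),
      tried, init$abs_min, init$abs_max, init$mu_max, init$t_i),
      call. = FALSE)
  }

  params <- richards_params(best$est[["abs_min"]], best$est[["abs_max"]],
                            best$est[["mu_max"]], best$est[["t_i"]], m = m)
  structure(list(
    params = params,
    rss = best$rss,
    n_points = length(time),
    converged = best$converged,
    n_iterations = best$iter,
    initializer = unclass(init),
    data = tibble::tibble(time = time, od = od)
  ), class = "richards_fit")
}

#' @export
print.richards_fit <- function(x, ...) {
  cat("Richards fit (", x$n_points, " points, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(x$params)
  cat(sprintf("  RSS = %.3g OD^2 in %d iterations\n", x$rss, x$n_iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.richards_fit <- function(x, ...) {
  tibble::tibble(
    term = c("abs_min", "abs_max", "mu_max", "t_i"),
    estimate = c(x$params$abs_min, x$params$abs_max,
                 x$params$mu_max, x$params$t_i)
  )
}

#' @exportS3Method generics::glance
glance.richards_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points, m = x$params$m,
                 converged = x$converged, n_iterations = x$n_iterations)
}

#' Fit every well in a plate table
#'
#' Groups a long plate table by its identifier columns (every column other
#' than `time` and `od`) and fits the Richards model per well with
#' [fit_richards()]. Wells that fail (no growth, non-convergence) are kept
#' in the output with `converged = FALSE`, `NA` parameters and the error
#' message in `note`, so downstream summaries can report them honestly.
#'
#' @param data Data frame with numeric `time` (hours) and `od` columns plus
#'   any identifier columns (typically `experiment`, `lineage`, `clone`,
#'   `replicate`).
#' @param average_replicates Fit each clone's replicate-averaged curve
#'   instead of each well (`FALSE`, the default: per-replicate fits with
#'   clone averaging downstream).
#' @inheritParams fit_richards
#' @return A tibble with one row per well: the identifier columns plus
#'   `abs_min`, `abs_max`, `mu_max`, `t_i`, `m`, `rss`, `n_points`,
#'   `converged`, `note`.
#' @export
fit_growth_curves <- function(data, m = 0.5, min_dynamic_range = 0.05,
                              average_replicates = FALSE, ...) {
  stopifnot(is.data.frame(data))
  if (!all(c("time", "od") %in% names(data))) {
    stop("`data` must contain `time` and `od` columns", call. = FALSE)
  }
  if (average_replicates && "replicate" %in% names(data)) {
    keys <- setdiff(names(data), c("od", "replicate"))
    data <- dplyr::summarise(
      dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
      od = mean(.data$od), .groups = "drop")
  }
  id_cols <- setdiff(names(data), c("time", "od"))
  nested <- tidyr::nest(dplyr::group_by(
    dplyr::as_tibble(data), dplyr::across(dplyr::all_of(id_cols))))
  fit_one <- function(d) {
    res <- try(fit_richards(d$time, d$od, m = m,
                            min_dynamic_range = min_dynamic_range, ...),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      return(tibble::tibble(abs_min = NA_real_, abs_max = NA_real_,
                            mu_max = NA_real_, t_i = NA_real_, m = m,
                            rss = NA_real_, n_points = nrow(d),
                            converged = FALSE,
                            note = conditionMessage(attr(res, "condition"))))
    }
    tibble::tibble(abs_min = res$params$abs_min, abs_max = res$params$abs_max,
                   mu_max = res$params$mu_max, t_i = res$params$t_i, m = m,
                   rss = res$rss, n_points = res$n_points,
                   converged = res$converged, note = NA_character_)
  }
  out <- dplyr::ungroup(tidyr::unnest(
    dplyr::mutate(nested, .fit = purrr::map(data, fit_one), data = NULL),
    ".fit"))
  n_bad <- sum(!out$converged)
  if (n_bad > 0) {
    warning(n_bad, " well(s) did not yield a converged fit; see `note` column",
            call. = FALSE)
  }
  out
}
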