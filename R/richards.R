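#' Richards growth-model parameters
#'
#' Bundle and validate the four free parameters of the fixed-shape Richards
#' absorbance model, plus the fixed dampening exponent `m`.
#'
#' The model describes one well's OD600 trajectory as
#' \deqn{ABS(t) = ABS_{min} + (ABS_{max} - ABS_{min})\,
#'   \left[1 + m\, e^{-\mu_{max} m (t - t_i)}\right]^{-1/m}}
#' i.e. the solution of the Richards growth equation
#' \eqn{dA/dt = \mu_{max} A (1 - (A/K)^m)} for the above-baseline absorbance,
#' re-parameterised by the inflection time \eqn{t_i}. Under this form
#' `mu_max` is the exponential-phase maximum specific growth rate (per hour)
#' and the curve's inflection (zero second derivative, maximum slope) falls
#' exactly at `t = t_i` (hours). The dampening exponent `m` controls the
#' asymmetry of the sigmoid: at `m = 1` the curve is the symmetric logistic
#' with inflection at half height; smaller `m` pushes the inflection below
#' half height, which matches plate-reader absorbance curves. `m` is fixed at
#' 0.5 by default and is not estimated.
#'
#' @param abs_min Asymptotic minimum absorbance (OD600), `>= 0`.
#' @param abs_max Asymptotic maximum absorbance (OD600), `> abs_min`.
#' @param mu_max Maximum specific growth rate (h^-1), `> 0`.
#' @param t_i Time at the inflection point, i.e. the TTI (hours), `> 0`.
#' @param m Fixed dimensionless dampening (shape) parameter; default 0.5.
#'
#' @return An object of class `richards_params`: a named list with the five
#'   fields above.
#' @examples
#' p <- richards_params(0.05, 1.0, 0.674, 7.54)
#' richards_abs(0:22, p)
#' @export
richards_params <- function(abs_min, abs_max, mu_max, t_i, m = 0.5) {
  vals <- c(abs_min = abs_min, abs_max = abs_max, mu_max = mu_max,
            t_i = t_i, m = m)
  if (any(!is.finite(vals))) {
    stop("all Richards parameters must be finite numbers", call. = FALSE)
  }
  if (abs_min < 0) {
    stop("`abs_min` must be >= 0 (got ", abs_min, ")", call. = FALSE)
  }
  if (abs_max <= abs_min) {
    stop("`abs_max` must exceed `abs_min` (got abs_max = ", abs_max,
         ", abs_min = ", abs_min, ")", call. = FALSE)
  }
  if (mu_max <= 0) stop("`mu_max` must be > 0", call. = FALSE)
  if (t_i <= 0) stop("`t_i` must be > 0", call. = FALSE)
  if (m <= 0) stop("`m` must be > 0", call. = FALSE)
  structure(list(abs_min = abs_min, abs_max = abs_max, mu_max = mu_max,
                 t_i = t_i, m = m),
            class = "richards_params")
}

#' @export
print.richards_params <- function(x, ...) {
  cat("Richards growth parameters (m fixed at ", format(x$m), ")\n", sep = "")
  cat(sprintf("  abs_min = %.4g OD   abs_max = %.4g OD\n", x$abs_min, x$abs_max))
  cat(sprintf("  mu_max  = %.4g /h   t_i (TTI) = %.4g h\n", x$mu_max, x$t_i))
  invisible(x)
}

as_richards_params <- function(x) {
  if (inherits(x, "richards_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    m <- if (is.null(x$m)) 0.5 else x$m
    return(richards_params(x$abs_min, x$abs_max, x$mu_max, x$t_i, m))
  }
  stop("cannot interpret `params` as Richards parameters", call. = FALSE)
}

# Damped exponential core: w(t) = m * exp(-mu * m * (t - t_i)).
# w -> Inf at early times is fine: (1 + w)^(-1/m) underflows to 0.
richards_w <- function(t, p) p$m * exp(-p$mu_max * p$m * (t - p$t_i))

#' Evaluate the Richards absorbance model
#'
#' @param t Time(s) in hours; may be any finite value (negative times probe
#'   the lower asymptote).
#' @param params A [richards_params()] object (or coercible list).
#' @return Absorbance (OD600) at each `t`; strictly increasing in `t`, with
#'   limits `abs_min` as `t -> -Inf` and `abs_max` as `t -> Inf`.
#' @examples
#' p <- richards_params(0.05, 1.0, 0.674, 7.54)
#' richards_abs(c(0, 7.54, 22), p)
#' @export
richards_abs <- function(t, params) {
  p <- as_richards_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  w <- richards_w(t, p)
  p$abs_min + (p$abs_max - p$abs_min) * (1 + w)^(-1 / p$m)
}

#' First derivative of the Richards absorbance model
#'
#' `dABS/dt` in OD600 per hour. Its maximum over `t` is attained exactly at
#' `t = t_i`, where it equals
#' `(abs_max - abs_min) * mu_max * m * (1 + m)^(-(1 + 1/m))`.
#'
#' @inheritParams richards_abs
#' @return The slope of the growth curve at each `t` (OD/h, `>= 0`).
#' @export
richards_derivative <- function(t, params) {
  p <- as_richards_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  w <- richards_w(t, p)
  # log-scale evaluation keeps w = Inf (deep lag phase) from producing NaN
  out <- numeric(length(w))
  ok <- is.finite(w) & w > 0
  out[ok] <- (p$abs_max - p$abs_min) * p$mu_max *
    exp(log(w[ok]) - (1 + 1 / p$m) * log1p(w[ok]))
  out[!ok] <- 0
  out
}
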