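#' Fit the sub-asymptotic parametric tail
#'
#' Fits `p(lambda) = q * exp(-a * (lambda - b)^c)` to the empirical
#' exceedance function above the cut-on level `lambda0`, by weighted least
#' squares on the log scale: the objective is
#' `sum_j w_j * (log p_hat(lambda_j) - log q + a * (lambda_j - b)^c)^2` with
#' weights `w_j = (log ci_hi_j - log ci_lo_j)^(-2)`, so precisely estimated
#' levels dominate.  For fixed `(b, c)` the log-model is linear in
#' `(log q, a)` and solved in closed form; the outer search over `(b, c)`
#' uses Nelder-Mead from a deterministic ladder of starts, with `b`
#' constrained below `lambda0` and `c` to `c_bounds`.  The same procedure is
#' applied to the lower and upper confidence curves, giving band parameters
#' whose inversion yields extrapolated confidence intervals.
#'
#' At `c = 1` the model has a pure exponential (Gumbel-like) tail; `c != 1`
#' captures sub-asymptotic curvature that a limiting extreme-value fit would
#' miss at finite levels.
#'
#' @param func A `riskcast_acer` object, or any data frame with columns
#'   `lambda` and `estimate` (optionally `numer`, `ci_lo`, `ci_hi`; without
#'   confidence columns all points get unit weight).
#' @param cut_on Level lambda0 where tail fitting starts (grid points at or
#'   above it are used).  Defaults to the smallest grid level.
#' @param c_bounds Allowed range of the shape exponent `c`.
#' @return A `riskcast_tail_fit` with elements `params` (list `q`, `a`, `b`,
#'   `c`), `band_params` (same for the lower/upper confidence curves, `NULL`
#'   where a band could not be fitted), `cut_on`, `objective`, `n_points`.
#' @export
fit_tail <- function(func, cut_on = NULL, c_bounds = c(0.1, 10)) {
  df <- tibble::as_tibble(func)
  stopifnot(all(c("lambda", "estimate") %in% names(df)))
  cut_on <- cut_on %||% min(df$lambda)
  has_num <- "numer" %in% names(df)
  usable <- df$lambda >= cut_on & is.finite(df$estimate) & df$estimate > 0
  if (has_num) usable <- usable & df$numer > 0
  df <- df[usable, ]
  if (nrow(df) < 4) {
    stop_riskcast(
      sprintf("only %d usable grid points at or above cut-on %g (need >= 4)",
              nrow(df), cut_on),
      "riskcast_tail_error"
    )
  }
  has_ci <- all(c("ci_lo", "ci_hi") %in% names(df))
  w <- rep(1, nrow(df))
  if (has_ci) {
    rng <- log(df$ci_hi) - log(df$ci_lo)
    w <- ifelse(is.finite(rng) & rng > 0, rng^-2, 0)
    if (sum(w > 0) < 4) w <- rep(1, nrow(df))
  }
  # If the CI-based weights concentrate on a flat or rising segment no
  # admissible decreasing fit exists there; fall back to unit weights over
  # the whole usable tail.
  fit <- tryCatch(fit_tail_curve(df$lambda, df$estimate, w, cut_on, c_bounds),
                  riskcast_tail_error = function(e) NULL)
  weighting <- "ci"
  if (is.null(fit)) {
    w <- rep(1, nrow(df))
    weighting <- "uniform"
    fit <- fit_tail_curve(df$lambda, df$estimate, w, cut_on, c_bounds)
  }
  band <- list(lo = NULL, hi = NULL)
  if (has_ci) {
    for (side in c("lo", "hi")) {
      y <- df[[paste0("ci_", side)]]
      ok <- is.finite(y) & y > 0 & w > 0
      if (sum(ok) >= 4) {
        band[[side]] <- tryCatch(
          fit_tail_curve(df$lambda[ok], y[ok], w[ok], cut_on, c_bounds)$params,
          riskcast_tail_error = function(e) NULL
        )
      }
    }
  }
  structure(
    list(params = fit$params, band_params = band, cut_on = cut_on,
         objective = fit$objective, n_points = nrow(df),
         weighting = weighting, data = df),
    class = "riskcast_tail_fit"
  )
}

# Weighted log-scale least squares for one curve.  Inner step: closed-form
# WLS in (log q, a) at fixed (b, c); outer: Nelder-Mead over transformed
# (b, c) from a deterministic grid of starts.
fit_tail_curve <- function(lambda, p, w, cut_on, c_bounds) {
  y <- log(p)
  inner <- function(b, cc) {
    u <- (lambda - b)^cc
    sw <- sum(w)
    su <- sum(w * u)
    suu <- sum(w * u * u)
    sy <- sum(w * y)
    suy <- sum(w * u * y)
    det <- sw * suu - su^2
    if (!is.finite(det) || det <= 0) return(list(obj = Inf))
    # y ~ logq - a*u
    a <- (su * sy - sw * suy) / det
    logq <- (sy + a * su) / sw
    if (logq > 0) { # q capped at 1: refit slope with logq = 0
      logq <- 0
      a <- if (suu > 0) -suy / suu else NA_real_
    }
    if (!is.finite(a) || a <= 0) return(list(obj = Inf))
    res <- y - (logq - a * u)
    list(obj = sum(w * res^2), logq = logq, a = a)
  }
  b_of <- function(th) cut_on - exp(th)
  c_of <- function(th) c_bounds[1] + diff(c_bounds) * stats::plogis(th)
  objfn <- function(th) {
    v <- inner(b_of(th[1]), c_of(th[2]))
    v$obj
  }
  spread <- max(diff(range(lambda)), abs(cut_on), 1e-8)
  b_starts <- cut_on - c(0.1, 0.5, 1, 2) * spread
  if (cut_on > 0) b_starts <- c(b_starts, cut_on * 1e-3) # near the natural zero bound
  c_starts <- c(0.5, 1, 2)
  c_starts <- pmin(pmax(c_starts, c_bounds[1] * 1.001), c_bounds[2] * 0.999)
  best <- NULL
  for (b0 in b_starts) {
    for (c0 in c_starts) {
      th0 <- c(log(cut_on - b0),
               stats::qlogis((c0 - c_bounds[1]) / diff(c_bounds)))
      opt <- tryCatch(
        stats::optim(th0, objfn, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (!is.null(opt) && is.finite(opt$value) &&
          (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
  }
  if (is.null(best)) {
    stop_riskcast("tail optimizer failed to produce any admissible fit",
                  "riskcast_tail_error")
  }
  b <- b_of(best$par[1])
  cc <- c_of(best$par[2])
  v <- inner(b, cc)
  list(
    params = list(q = exp(v$logq), a = v$a, b = b, c = cc),
    objective = v$obj
  )
}

#' Evaluate a fitted tail
#' @param params Parameter list `(q, a, b, c)` or a `riskcast_tail_fit`.
#' @param lambda Levels at which to evaluate.
#' @return Fitted exceedance probabilities `q * exp(-a * (lambda - b)^c)`.
#' @export
tail_prob <- function(params, lambda) {
  if (inherits(params, "riskcast_tail_fit")) params <- params$params
  params$q * exp(-params$a * pmax(lambda - params$b, 0)^params$c)
}

#' @export
print.riskcast_tail_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<riskcast_tail_fit> q=%.4g a=%.4g b=%.4g c=%.4g | cut-on %g, %d points, objective %.3g\n",
    p$q, p$a, p$b, p$c, x$cut_on, x$n_points, x$objective
  ))
  invisible(x)
}

#' Convert a return period to a per-event exceedance probability
#'
#' @param return_period Return period in years.
#' @param events_per_year Relevant events per year (1 for a pointwise-max
#'   annual merge; `N / span` for an interleaved merge).
#' @return `1 / (return_period * events_per_year)`.
#' @export
return_period_to_prob <- function(return_period, events_per_year = 1) {
  if (return_period <= 0 || events_per_year <= 0) {
    stop_riskcast("return_period and events_per_year must be positive",
                  "riskcast_domain_error")
  }
  1 / (return_period * events_per_year)
}

#' Invert a fitted tail to the level with a target exceedance probability
#'
#' Solves `p(level) = target_prob` for the fitted tail, and likewise for the
#' band parameters, giving the extrapolated confidence interval.
#'
#' @param fit A `riskcast_tail_fit`.
#' @param target_prob Target per-event exceedance probability in `(0, q)`.
#' @param return_period,events_per_year Optional bookkeeping recorded in the
#'   forecast (use [return_period_to_prob()] to derive `target_prob`).
#' @return A `riskcast_forecast` list: `level`, `ci_lo`, `ci_hi`,
#'   `target_prob`, `return_period`, `events_per_year`.
#' @export
predict_level <- function(fit, target_prob, return_period = NA_real_,
                          events_per_year = NA_real_) {
  stopifnot(inherits(fit, "riskcast_tail_fit"))
  invert <- function(params, p, strict = FALSE) {
    if (is.null(params)) return(NA_real_)
    if (p >= params$q) {
      if (strict) {
        stop_riskcast(
          sprintf("target probability %g is not below q = %g: no tail inversion", p, params$q),
          "riskcast_inversion_error"
        )
      }
      return(NA_real_)
    }
    params$b + (log(params$q / p) / params$a)^(1 / params$c)
  }
  if (!is.numeric(target_prob) || target_prob <= 0) {
    stop_riskcast("target_prob must be a positive probability", "riskcast_domain_error")
  }
  level <- invert(fit$params, target_prob, strict = TRUE)
  structure(
    list(
      level = level,
      ci_lo = invert(fit$band_params$lo, target_prob),
      ci_hi = invert(fit$band_params$hi, target_prob),
      target_prob = target_prob,
      return_period = return_period,
      events_per_year = events_per_year
    ),
    class = "riskcast_forecast"
  )
}

#' @export
print.riskcast_forecast <- function(x, ...) {
  cat(sprintf(
    "<riskcast_forecast> level %.5g [%.5g, %.5g] at exceedance prob %.3g\n",
    x$level, x$ci_lo, x$ci_hi, x$target_prob
  ))
  invisible(x)
}

#' Forecast a return level from a fitted tail
#'
#' Convenience wrapper combining [return_period_to_prob()] and
#' [predict_level()].
#'
#' @inheritParams predict_level
#' @inheritParams return_period_to_prob
#' @export
forecast_return_level <- function(fit, return_period, events_per_year = 1) {
  p <- return_period_to_prob(return_period, events_per_year)
  predict_level(fit, p, return_period = return_period,
                events_per_year = events_per_year)
}
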