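# Two-state thermal melting analysis: van't Hoff fit with sloping
# pre-/post-transitional baselines, folded fraction, Tm at f = 0.5,
# ligand-induced Tm shifts, and a residual bootstrap for Tm uncertainty.

.as_melting_curve <- function(curve) {
  curve <- as_tibble(curve)
  if (!all(c("temperature", "ellipticity") %in% names(curve))) {
    abort("a melting curve needs `temperature` and `ellipticity` columns")
  }
  if (nrow(curve) < 10) abort("a melting curve needs at least 10 points")
  if (any(diff(curve$temperature) <= 0)) {
    abort("temperatures must be strictly increasing")
  }
  curve
}

# smoothed-derivative extremum used to seed Tm and to test for a transition
.transition_guess <- function(curve) {
  n <- nrow(curve)
  w <- min(max(5, 2 * floor(n / 30) + 1), n)
  y <- stats::filter(curve$ellipticity, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- curve$ellipticity[is.na(y)]
  dy <- diff(y) / diff(curve$temperature)
  i <- which.max(abs(dy))
  margin <- max(2, floor(0.02 * n))
  list(
    tm = mean(curve$temperature[i + 0:1]),
    interior = i > margin && i < length(dy) - margin + 1,
    slope = max(abs(dy))
  )
}

#' Fit a two-state melting model with sloping baselines
#'
#' Least-squares fit of
#' `theta(T) = f(T) (a_f + b_f T) + (1 - f(T)) (a_u + b_u T)` with the
#' van't Hoff folded fraction
#' `f(T) = 1 / (1 + exp(-(dH/R)(1/T_K - 1/Tm_K)))` in absolute
#' temperature, so that f(Tm) = 0.5 exactly. The fit is initialized from
#' the smoothed-derivative extremum (Tm), the curve ends (baselines) and a
#' generic enthalpy, and is solved with Levenberg-Marquardt least squares.
#' A `"interpolation"` method is also provided: linear baselines are fit to
#' the curve ends, the folded fraction is formed by baseline subtraction,
#' and Tm is read off at f = 0.5 by linear interpolation.
#'
#' @param curve A tibble with `temperature` (Celsius, increasing) and
#'   `ellipticity` columns.
#' @param method `"vanthoff"` (default) or `"interpolation"`.
#' @param baseline_frac Fraction of points at each end used to seed (or,
#'   for the interpolation method, fit) the baselines.
#' @return An object of class `qdh_melt_fit` with elements `tm`, `dh`,
#'   `baseline_folded`, `baseline_unfolded`, `residual_norm`, `method`,
#'   `fit` (the nls object for the van't Hoff route) and `curve`.
#' @export
fit_melting <- function(curve, method = c("vanthoff", "interpolation"),
                        baseline_frac = 0.15) {
  method <- match.arg(method)
  curve <- .as_melting_curve(curve)
  tg <- .transition_guess(curve)
  n <- nrow(curve)
  k <- max(3, floor(baseline_frac * n))
  lo <- curve[seq_len(k), ]
  hi <- curve[seq(n - k + 1, n), ]
  bf0 <- coef(stats::lm(ellipticity ~ temperature, data = lo))
  bu0 <- coef(stats::lm(ellipticity ~ temperature, data = hi))
  rng <- diff(range(curve$ellipticity))
  if (rng == 0) abort("no transition detected: constant signal")

  if (method == "interpolation") {
    thf <- bf0[1] + bf0[2] * curve$temperature
    thu <- bu0[1] + bu0[2] * curve$temperature
    f <- (curve$ellipticity - thu) / (thf - thu)
    f <- pmin(1, pmax(0, f))
    cross <- which(diff(sign(f - 0.5)) != 0)
    if (length(cross) == 0) abort("no transition detected: f never crosses 0.5")
    i <- cross[which.min(abs(curve$temperature[cross] - tg$tm))]
    tmi <- approx(f[i + 0:1], curve$temperature[i + 0:1], xout = 0.5)$y
    out <- list(
      tm = tmi, dh = NA_real_,
      baseline_folded = unname(bf0), baseline_unfolded = unname(bu0),
      residual_norm = NA_real_, method = method, fit = NULL, curve = curve
    )
    class(out) <- "qdh_melt_fit"
    return(out)
  }

  model_fn <- function(temperature, tm, dh, af, bf, au, bu) {
    f <- .vanthoff_f(temperature, tm, dh)
    f * (af + bf * temperature) + (1 - f) * (au + bu * temperature)
  }
  # seed Tm where the baseline-subtracted folded fraction crosses one half;
  # this is robust where a noisy derivative extremum is not
  f0 <- (curve$ellipticity - (bu0[1] + bu0[2] * curve$temperature)) /
    ((bf0[1] + bf0[2] * curve$temperature) - (bu0[1] + bu0[2] * curve$temperature))
  wsm <- min(max(5, 2 * floor(n / 30) + 1), n)
  f0s <- stats::filter(f0, rep(1 / wsm, wsm), sides = 2)
  f0s[is.na(f0s)] <- f0[is.na(f0s)]
  tm0 <- curve$temperature[which.min(abs(f0s - 0.5))]
  fit <- try(
    minpack.lm::nlsLM(
      ellipticity ~ model_fn(temperature, tm, dh, af, bf, au, bu),
      data = curve,
      start = list(
        tm = tm0, dh = 50,
        af = unname(bf0[1]), bf = unname(bf0[2]),
        au = unname(bu0[1]), bu = unname(bu0[2])
      ),
      lower = c(min(curve$temperature), 1, -Inf, -Inf, -Inf, -Inf),
      upper = c(max(curve$temperature), 500, Inf, Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    abort(paste0("two-state fit did not converge: ", attr(fit, "condition")$message))
  }
  cf <- coef(fit)
  # a fit is only a transition if the two baselines are genuinely separated
  # at the midpoint and the midpoint is interior to the measured range
  amp <- abs((cf["af"] + cf["bf"] * cf["tm"]) - (cf["au"] + cf["bu"] * cf["tm"]))
  t_lo <- curve$temperature[2]
  t_hi <- curve$temperature[n - 1]
  if (amp < 0.05 * rng || cf["tm"] <= t_lo || cf["tm"] >= t_hi) {
    abort("no transition detected: no interior two-state midpoint in the data")
  }
  out <- list(
    tm = unname(cf["tm"]), dh = unname(cf["dh"]),
    baseline_folded = unname(cf[c("af", "bf")]),
    baseline_unfolded = unname(cf[c("au", "bu")]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    method = method, fit = fit, curve = curve
  )
  class(out) <- "qdh_melt_fit"
  out
}

#' @export
print.qdh_melt_fit <- function(x, ...) {
  cat("<qdh_melt_fit> two-state melting fit (", x$method, ")\n", sep = "")
  cat(sprintf("  Tm = %.2f C", x$tm))
  if (is.finite(x$dh)) cat(sprintf(", dH(vH) = %.1f kcal/mol", x$dh))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a melting fit into one row per parameter
#'
#' @param x A `qdh_melt_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.qdh_melt_fit <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    return(tibble(
      term = rownames(s), estimate = s[, 1], std.error = s[, 2]
    ))
  }
  tibble(
    term = c("tm", "af", "bf", "au", "bu"),
    estimate = c(
      x$tm, x$baseline_folded, x$baseline_unfolded
    ),
    std.error = NA_real_
  )
}

#' One-row summary of a melting fit
#'
#' @param x A `qdh_melt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `tm`, `dh`, `residual_norm`, `n`, `method`.
#' @export
glance.qdh_melt_fit <- function(x, ...) {
  tibble(
    tm = x$tm, dh = x$dh, residual_norm = x$residual_norm,
    n = nrow(x$curve), method = x$method
  )
}

#' Folded fraction from a curve and its fitted baselines
#'
#' `f(T) = (theta(T) - theta_u(T)) / (theta_f(T) - theta_u(T))`, clipped to
#' [0, 1].
#'
#' @param curve A melting-curve tibble.
#' @param fit A `qdh_melt_fit`.
#' @return A tibble with columns `temperature`, `f`.
#' @export
folded_fraction <- function(curve, fit) {
  curve <- .as_melting_curve(curve)
  thf <- fit$baseline_folded[1] + fit$baseline_folded[2] * curve$temperature
  thu <- fit$baseline_unfolded[1] + fit$baseline_unfolded[2] * curve$temperature
  den <- thf - thu
  if (any(abs(den) < 1e-9 * max(abs(thf), 1))) {
    abort("degenerate baselines: folded and unfolded signals coincide")
  }
  f <- (curve$ellipticity - thu) / den
  tibble(temperature = curve$temperature, f = pmin(1, pmax(0, f)))
}

#' Ligand-induced melting-temperature shift
#'
#' `|Tm(complex) - Tm(free)|`; accepts fits or bare Tm values.
#'
#' @param fit_complex,fit_free `qdh_melt_fit` objects or numeric Tm in
#'   Celsius.
#' @return Absolute Tm difference in Celsius.
#' @export
delta_tm <- function(fit_complex, fit_free) {
  tm1 <- if (inherits(fit_complex, "qdh_melt_fit")) fit_complex$tm else fit_complex
  tm2 <- if (inherits(fit_free, "qdh_melt_fit")) fit_free$tm else fit_free
  abs(tm1 - tm2)
}

#' Residual bootstrap of the melting temperature
#'
#' Refits the curve on residual-resampled replicates and reports the mean
#' and standard deviation of Tm (emulating replicate-to-replicate scatter);
#' failed refits are counted and skipped.
#'
#' @param curve A melting-curve tibble.
#' @param n_resamples Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A list with `tm_mean`, `tm_sd`, `n_failed`, `tm` (replicate
#'   values).
#' @export
bootstrap_tm <- function(curve, n_resamples = 200, seed = 1) {
  curve <- .as_melting_curve(curve)
  fit0 <- fit_melting(curve)
  yhat <- as.numeric(predict(fit0$fit))
  res <- curve$ellipticity - yhat
  tms <- .with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      yb <- yhat + sample(res, length(res), replace = TRUE)
      fb <- try(fit_melting(tibble(temperature = curve$temperature, ellipticity = yb)),
        silent = TRUE
      )
      if (inherits(fb, "try-error")) NA_real_ else fb$tm
    }, 0)
  })
  list(
    tm_mean = mean(tms, na.rm = TRUE),
    tm_sd = sd(tms, na.rm = TRUE),
    n_failed = sum(is.na(tms)),
    tm = tms
  )
}
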