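# Two-state melting: simulation, van't Hoff fit, folded fraction, Tm shifts.

test_that("the simulated folded fraction is exactly half at Tm and decreasing", {
  p <- melting_params(tm = 61.6, dh = 45)
  f <- qdhkit:::.vanthoff_f(61.6, 61.6, 45)
  expect_equal(f, 0.5)
  Tg <- seq(5, 95, by = 0.5)
  ff <- qdhkit:::.vanthoff_f(Tg, 61.6, 45)
  expect_true(all(diff(ff) < 0))
  expect_gt(ff[1], 0.95)
  expect_lt(ff[length(ff)], 0.1)
})

test_that("noiseless curves are recovered to high accuracy", {
  curve <- simulate_melting_curve(melting_params(tm = 61.6, dh = 45))
  fit <- fit_melting(curve)
  expect_lt(abs(fit$tm - 61.6), 0.05)
  expect_lt(abs(fit$dh - 45), 0.5)
  # folded fraction at the fitted Tm is one half
  ff <- folded_fraction(curve, fit)
  f_at_tm <- approx(ff$temperature, ff$f, xout = fit$tm)$y
  expect_equal(f_at_tm, 0.5, tolerance = 1e-3)
  expect_gt(ff$f[1], 0.99)
  expect_lt(tail(ff$f, 1), 0.01)
  # interpolation route lands close to the same Tm
  fit2 <- fit_melting(curve, method = "interpolation")
  expect_lt(abs(fit2$tm - 61.6), 0.5)
})

test_that("tidy and glance expose the fitted parameters", {
  curve <- simulate_melting_curve(melting_params(tm = 65, dh = 50, noise_sd = 0.05))
  fit <- fit_melting(curve)
  td <- tidy(fit)
  expect_true(all(c("tm", "dh") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_lt(abs(gl$tm - 65), 0.5)
})

test_that("baseline-only data raise a no-transition error", {
  flat <- tibble::tibble(
    temperature = seq(5, 95, by = 1),
    ellipticity = 3 - 0.01 * seq(5, 95, by = 1)
  )
  expect_error(fit_melting(flat), "no transition")
})

test_that("Tm shifts are symmetric, non-negative, and match the worked example", {
  free <- fit_melting(simulate_melting_curve(melting_params(tm = 61.6)))
  cplx <- fit_melting(simulate_melting_curve(melting_params(tm = 75.1)))
  expect_equal(delta_tm(cplx, free), 13.5, tolerance = 0.1)
  expect_equal(delta_tm(free, cplx), delta_tm(cplx, free))
  expect_equal(delta_tm(free, free), 0)
  expect_equal(delta_tm(75.1, 61.6), 13.5)
})

test_that("the fit is invariant to affine rescaling of the signal", {
  curve <- simulate_melting_curve(melting_params(tm = 68, dh = 55, noise_sd = 0.03))
  fit1 <- fit_melting(curve)
  scaled <- dplyr::mutate(curve, ellipticity = 40 * ellipticity - 7)
  fit2 <- fit_melting(scaled)
  expect_lt(abs(fit1$tm - fit2$tm), 0.01)
})

test_that("parameter recovery is unbiased wherever the transition is resolved", {
  # applicability condition of any two-state baseline fit: both baselines
  # must be observable, i.e. the folded fraction must traverse ~1 -> ~0
  # inside the measured window. Corners whose unfolded branch lies beyond
  # the 95 C ceiling are information-limited (see the methods vignette).
  errs <- c()
  for (tm in c(55, 65, 80)) {
    for (dh in c(30, 50, 70)) {
      resolved <- qdhkit:::.vanthoff_f(95, tm, dh) < 0.03 &&
        qdhkit:::.vanthoff_f(5, tm, dh) > 0.97
      if (!resolved) next
      p0 <- melting_params(tm = tm, dh = dh)
      range0 <- diff(range(simulate_melting_curve(p0)$ellipticity))
      for (seed in 1:3) {
        curve <- simulate_melting_curve(melting_params(
          tm = tm, dh = dh, noise_sd = 0.02 * range0, seed = seed
        ))
        errs <- c(errs, fit_melting(curve)$tm - tm)
      }
    }
  }
  expect_gt(length(errs), 15)
  expect_lt(abs(mean(errs)), 0.2)
  expect_lt(sqrt(mean(errs^2)), 0.5)
})

test_that("bootstrap Tm spread is deterministic and tracks the noise level", {
  sds <- vapply(c(0.02, 0.1, 0.3), function(ns) {
    curve <- simulate_melting_curve(melting_params(tm = 62, noise_sd = ns, seed = 4))
    bootstrap_tm(curve, n_resamples = 40, seed = 9)$tm_sd
  }, 0)
  expect_true(all(diff(sds) > 0))
  clean <- simulate_melting_curve(melting_params(tm = 62))
  b0 <- bootstrap_tm(clean, n_resamples = 20, seed = 2)
  expect_lt(b0$tm_sd, 0.01)
  b1 <- bootstrap_tm(clean, n_resamples = 20, seed = 2)
  expect_equal(b0, b1)
})
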