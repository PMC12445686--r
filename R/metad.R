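# Well-tempered metadynamics on a periodic 1D collective variable, with an
# overdamped Langevin sampler on analytic periodic potentials for
# validation, free-energy reconstruction, and minima counting.
# Angles in degrees, energies in kcal/mol throughout.

#' Minimal signed angular difference
#'
#' `a - b` wrapped into (-180, 180].
#'
#' @param a,b Angles in degrees (vectorized).
#' @return Signed difference in degrees.
#' @export
periodic_delta <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Well-tempered bias state
#'
#' Holds the deposited Gaussian hills (shared width), the initial hill
#' height, the temperature and the bias factor gamma = (T + dT) / T. The
#' default hill parameters (sigma 10 degrees, w0 0.2 kcal/mol, gamma 10,
#' stride 500 steps) are conventional settings for a soft 1D angular CV
#' and are all configurable.
#'
#' @param sigma Hill width in degrees.
#' @param w0 Initial hill height in kcal/mol.
#' @param temperature Temperature in K.
#' @param gamma Bias factor (> 1).
#' @param stride Deposition stride in integrator steps.
#' @return A list of class `qdh_bias`.
#' @export
bias_state <- function(sigma = 10, w0 = 0.2, temperature = 300, gamma = 10,
                       stride = 500) {
  stopifnot(sigma > 0, w0 > 0, gamma > 1, temperature > 0, stride >= 1)
  structure(
    list(
      centers = numeric(0), heights = numeric(0), sigma = sigma, w0 = w0,
      temperature = temperature, gamma = gamma, stride = as.integer(stride)
    ),
    class = "qdh_bias"
  )
}

#' Evaluate the deposited bias potential
#'
#' `V(s) = sum_k h_k exp(-delta(s, c_k)^2 / (2 sigma^2))` with the periodic
#' angular difference, so the bias is smooth across the +/-180 seam.
#'
#' @param state A `qdh_bias`.
#' @param s Angles in degrees (vectorized).
#' @return Bias energy in kcal/mol.
#' @export
bias_potential <- function(state, s) {
  if (length(state$centers) == 0) {
    return(rep(0, length(s)))
  }
  vapply(s, function(si) {
    d <- periodic_delta(si, state$centers)
    sum(state$heights * exp(-d^2 / (2 * state$sigma^2)))
  }, 0)
}

# derivative of the bias wrt s (kcal/mol per degree)
.bias_grad <- function(state, s) {
  if (length(state$centers) == 0) {
    return(0)
  }
  d <- periodic_delta(s, state$centers)
  -sum(state$heights * exp(-d^2 / (2 * state$sigma^2)) * d / state$sigma^2)
}

#' Deposit a well-tempered hill
#'
#' Appends a Gaussian at `s` with height `w0 * exp(-V(s) / (kB dT))`,
#' `dT = (gamma - 1) T`: revisited regions receive exponentially smaller
#' hills, the defining property of well-tempered metadynamics.
#'
#' @param state A `qdh_bias`.
#' @param s Deposition center in degrees.
#' @return The updated `qdh_bias`.
#' @export
deposit <- function(state, s) {
  dT <- (state$gamma - 1) * state$temperature
  h <- state$w0 * exp(-bias_potential(state, s) / (.kB * dT))
  state$centers <- c(state$centers, s)
  state$heights <- c(state$heights, h)
  state
}

#' Reconstruct the free-energy profile from the bias
#'
#' In the well-tempered limit the bias converges to
#' `-(gamma - 1) / gamma * F`, so the estimator is
#' `F(s) = -gamma / (gamma - 1) * V(s)`, shifted so that min F = 0, on a
#' uniform periodic grid over (-180, 180].
#'
#' @param state A `qdh_bias` with at least one hill.
#' @param n_grid Number of grid points.
#' @return A tibble of class `qdh_fes` with columns `angle`,
#'   `free_energy`.
#' @export
fes_estimate <- function(state, n_grid = 360) {
  if (length(state$centers) == 0) abort("empty bias: no hills deposited")
  grid <- seq(-180 + 360 / n_grid, 180, length.out = n_grid)
  f <- -(state$gamma / (state$gamma - 1)) * bias_potential(state, grid)
  f <- f - min(f)
  out <- tibble(angle = grid, free_energy = f)
  class(out) <- c("qdh_fes", class(out))
  attr(out, "gamma") <- state$gamma
  out
}

#' Locate significant minima of a periodic free-energy profile
#'
#' Grid local minima with basin depth (the lower of the two barriers to the
#' neighboring maxima along the circle) at least `depth_min`; minima closer
#' than `merge_radius` are merged into the deeper one. Sorted by depth,
#' descending.
#'
#' @param profile A `qdh_fes` tibble (or any tibble with `angle`,
#'   `free_energy` on a periodic grid).
#' @param depth_min Minimum basin depth in kcal/mol.
#' @param merge_radius Merge radius in degrees.
#' @return A tibble with columns `position`, `value`, `depth`.
#' @export
find_minima <- function(profile, depth_min = 1, merge_radius = 20) {
  f <- profile$free_energy
  a <- profile$angle
  n <- length(f)
  prv <- c(n, seq_len(n - 1))
  nxt <- c(2:n, 1)
  is_min <- f <= f[prv] & f <= f[nxt] & (f < f[prv] | f < f[nxt])
  mins <- which(is_min)
  if (length(mins) == 0) {
    return(tibble(position = double(), value = double(), depth = double()))
  }
  # barrier walk in each direction until a lower point than the minimum
  depth_of <- function(i) {
    walk <- function(step) {
      j <- i
      peak <- f[i]
      for (k in seq_len(n)) {
        j <- if (step > 0) nxt[j] else prv[j]
        if (f[j] < f[i]) break
        peak <- max(peak, f[j])
      }
      peak - f[i]
    }
    min(walk(1), walk(-1))
  }
  out <- tibble(
    position = a[mins], value = f[mins],
    depth = vapply(mins, depth_of, 0)
  )
  out <- out[out$depth >= depth_min, ]
  out <- out[order(-out$depth, out$position), ]
  # merge near-coincident minima, keeping the deeper
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out))[-1]) {
      for (j in seq_len(i - 1)) {
        if (keep[j] && abs(periodic_delta(out$position[i], out$position[j])) < merge_radius) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  out[keep, ]
}

#' Overdamped Langevin dynamics on a periodic potential
#'
#' The Euler-Maruyama update
#' `s <- s - U'(s) dt / friction + sqrt(2 kB T dt / friction) * xi`,
#' wrapped to (-180, 180]. A desk-scale surrogate for molecular
#' trajectories: it validates the CV/bias/free-energy machinery, not any
#' molecular ensemble.
#'
#' @param potential Function of angle (degrees) returning kcal/mol;
#'   must be 360-periodic.
#' @param gradient Optional analytic derivative (kcal/mol per degree);
#'   central differences are used when absent.
#' @param friction Friction coefficient (kcal/mol per degree^2 per step
#'   unit time).
#' @param temperature Temperature in K.
#' @param dt Time step (arbitrary units).
#' @param steps Number of steps.
#' @param seed Integer seed.
#' @param s0 Initial angle in degrees.
#' @param bias Optional `qdh_bias` whose (fixed) potential is added.
#' @return A tibble with columns `step`, `angle`.
#' @export
run_langevin <- function(potential, gradient = NULL, friction = 1,
                         temperature = 300, dt = 1, steps = 10000,
                         seed = 1, s0 = 0, bias = NULL) {
  stopifnot(dt > 0, temperature > 0, steps >= 1)
  grad <- gradient %||% function(s) {
    (potential(s + 1e-4) - potential(s - 1e-4)) / 2e-4
  }
  noise_sd <- sqrt(2 * .kB * temperature * dt / friction)
  .with_seed(seed, {
    xi <- rnorm(steps)
    s <- numeric(steps)
    cur <- s0
    for (i in seq_len(steps)) {
      g <- grad(cur)
      if (!is.null(bias)) g <- g + .bias_grad(bias, cur)
      cur <- cur - g * dt / friction + noise_sd * xi[i]
      cur <- periodic_delta(cur, 0)
      s[i] <- cur
    }
    tibble(step = seq_len(steps), angle = s)
  })
}

#' Well-tempered metadynamics on a periodic potential
#'
#' Overdamped Langevin dynamics under `U + V_bias` with a hill deposited at
#' the current position every `stride` steps, followed by free-energy
#' reconstruction.
#'
#' @inheritParams run_langevin
#' @param bias A fresh [bias_state()] carrying the hill parameters and
#'   deposition stride.
#' @param n_grid Grid resolution of the returned profile.
#' @param average_from Fraction of the run after which the grid bias starts
#'   being time-averaged for the returned profile; averaging over the
#'   late, slowly-changing bias removes most of the hill-by-hill
#'   oscillation of the instantaneous estimator.
#' @return A list with `trajectory` (tibble step, angle), `bias` (the
#'   final `qdh_bias`), `fes` (time-averaged profile, a `qdh_fes` tibble)
#'   and `fes_final` (the instantaneous end-of-run estimate).
#' @export
run_wtmetad <- function(potential, gradient = NULL, bias = bias_state(),
                        friction = 1, temperature = 300, dt = 1,
                        steps = 100000, seed = 1, s0 = 0, n_grid = 360,
                        average_from = 0.5) {
  stopifnot(inherits(bias, "qdh_bias"), dt > 0, steps >= 1)
  grad <- gradient %||% function(s) {
    (potential(s + 1e-4) - potential(s - 1e-4)) / 2e-4
  }
  noise_sd <- sqrt(2 * .kB * temperature * dt / friction)
  grid <- seq(-180 + 360 / n_grid, 180, length.out = n_grid)
  vgrid <- numeric(n_grid)
  vsum <- numeric(n_grid)
  navg <- 0L
  .with_seed(seed, {
    xi <- rnorm(steps)
    s <- numeric(steps)
    cur <- s0
    for (i in seq_len(steps)) {
      g <- grad(cur) + .bias_grad(bias, cur)
      cur <- cur - g * dt / friction + noise_sd * xi[i]
      cur <- periodic_delta(cur, 0)
      s[i] <- cur
      if (i %% bias$stride == 0) {
        bias <- deposit(bias, cur)
        h <- bias$heights[length(bias$heights)]
        d <- periodic_delta(grid, cur)
        vgrid <- vgrid + h * exp(-d^2 / (2 * bias$sigma^2))
        if (i >= average_from * steps) {
          vsum <- vsum + vgrid
          navg <- navg + 1L
        }
      }
    }
    vavg <- if (navg > 0) vsum / navg else vgrid
    f <- -(bias$gamma / (bias$gamma - 1)) * vavg
    f <- f - min(f)
    fes <- tibble(angle = grid, free_energy = f)
    class(fes) <- c("qdh_fes", class(fes))
    attr(fes, "gamma") <- bias$gamma
    list(
      trajectory = tibble(step = seq_len(steps), angle = s),
      bias = bias,
      fes = fes,
      fes_final = fes_estimate(bias, n_grid)
    )
  })
}

#' Analytic periodic test potentials
#'
#' `single_well()` is `depth/2 * (1 - cos(s - center))`; `double_well()` is
#' `depth/2 * (1 - cos(2 (s - center))) + asym/2 * (1 - cos(s - center))`,
#' giving two minima 180 degrees apart whose free energies differ by
#' `asym`.
#'
#' @param depth Well relief in kcal/mol.
#' @param center Location of (one) minimum in degrees.
#' @param asym Free-energy offset between the two wells (double well).
#' @return A function of angle in degrees; the analytic gradient is
#'   attached as attribute `"gradient"`.
#' @export
single_well <- function(depth = 3, center = 0) {
  f <- function(s) depth / 2 * (1 - cos((s - center) * pi / 180))
  attr(f, "gradient") <- function(s) {
    depth / 2 * sin((s - center) * pi / 180) * pi / 180
  }
  f
}

#' @rdname single_well
#' @export
double_well <- function(depth = 3, center = 0, asym = 0) {
  f <- function(s) {
    depth / 2 * (1 - cos(2 * (s - center) * pi / 180)) +
      asym / 2 * (1 - cos((s - center) * pi / 180))
  }
  attr(f, "gradient") <- function(s) {
    depth * sin(2 * (s - center) * pi / 180) * pi / 180 +
      asym / 2 * sin((s - center) * pi / 180) * pi / 180
  }
  f
}
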