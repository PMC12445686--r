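# Synthetic NOE volume tables (isolated spin-pair r^-6 with multiplicative
# log-normal noise) and synthetic two-state CD melting curves with sloping
# baselines.

#' Simulate an NOE cross-peak volume table from a model
#'
#' Emits one record per proton pair closer than `cutoff`, with volume
#' proportional to d^-6 under the isolated spin-pair approximation and
#' optional multiplicative log-normal noise. The cytosine H5-H6 reference
#' rows are emitted with the volume corresponding to the nominal 2.45
#' angstrom calibration distance (the simulated spectrometer is calibrated
#' by construction), so at zero noise ISPA calibration inverts the
#' generator exactly.
#'
#' @param structure A single-model structure tibble with base hydrogens.
#' @param cutoff Distance cutoff in angstroms (default 6).
#' @param sigma Log-normal noise sigma (0 = noiseless).
#' @param seed Integer seed for the noise stream.
#' @param scale Overall volume scale constant.
#' @return A tibble with columns `res_i`, `atom_i`, `res_j`, `atom_j`,
#'   `volume` and a logical `reference` marking the cytosine H5-H6 rows.
#' @export
simulate_noe_table <- function(structure, cutoff = 6.0, sigma = 0, seed = 1,
                               scale = 1e6) {
  stopifnot(cutoff > 0, sigma >= 0)
  if (n_models(structure) > 1) abort("simulate_noe_table() expects a single model")
  h <- structure[structure$element == "H" & !structure$ligand, ]
  if (nrow(h) == 0) abort("model has no hydrogens; build with base templates first")
  cyt <- h[h$base == "C" & h$atom %in% c("H5", "H6"), ]
  if (length(unique(cyt$resid[duplicated(cyt$resid) | duplicated(cyt$resid, fromLast = TRUE)])) == 0) {
    abort("no cytosine H5-H6 reference pair in the model")
  }
  xyz <- as.matrix(h[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(dmat) & dmat <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    idx <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
  }
  tab <- tibble(
    res_i = h$resid[idx[, "row"]], atom_i = h$atom[idx[, "row"]],
    res_j = h$resid[idx[, "col"]], atom_j = h$atom[idx[, "col"]],
    distance = dmat[idx]
  )
  is_ref <- tab$res_i == tab$res_j &
    h$base[match(tab$res_i, h$resid)] == "C" &
    purrr::map2_lgl(tab$atom_i, tab$atom_j, ~ setequal(c(.x, .y), c("H5", "H6")))
  # reference rows must exist even under a tiny cutoff
  if (!any(is_ref)) {
    refres <- unique(cyt$resid[cyt$resid %in% cyt$resid[duplicated(cyt$resid)]])
    extra <- tibble(
      res_i = refres, atom_i = "H5", res_j = refres, atom_j = "H6",
      distance = NA_real_
    )
    tab <- bind_rows(tab, extra)
    is_ref <- c(is_ref, rep(TRUE, nrow(extra)))
  }
  d_eff <- ifelse(is_ref, 2.45, tab$distance)
  eps <- if (sigma > 0) {
    .with_seed(seed, rnorm(nrow(tab), sd = sigma))
  } else {
    rep(0, nrow(tab))
  }
  tab$volume <- scale * d_eff^-6 * exp(eps)
  tab$reference <- is_ref
  select(tab, "res_i", "atom_i", "res_j", "atom_j", "volume", "reference")
}

#' Parameters for simulated two-state melting curves
#'
#' @param tm Melting temperature in degrees Celsius.
#' @param dh Van't Hoff enthalpy in kcal/mol (> 0).
#' @param baseline_folded,baseline_unfolded Length-2 numeric
#'   `c(intercept, slope)` of the pre-/post-transitional ellipticity
#'   baselines (signal units, slope per degree Celsius).
#' @param temperatures Strictly increasing temperature grid in Celsius.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed for the noise stream.
#' @return A list of class `qdh_melting_params`.
#' @export
melting_params <- function(tm = 61.6, dh = 45,
                           baseline_folded = c(10, -0.02),
                           baseline_unfolded = c(2, -0.01),
                           temperatures = seq(5, 95, by = 0.5),
                           noise_sd = 0, seed = 1) {
  stopifnot(dh > 0, all(diff(temperatures) > 0), noise_sd >= 0)
  structure(
    list(
      tm = tm, dh = dh, baseline_folded = baseline_folded,
      baseline_unfolded = baseline_unfolded, temperatures = temperatures,
      noise_sd = noise_sd, seed = seed
    ),
    class = "qdh_melting_params"
  )
}

# two-state van't Hoff folded fraction; tm, dh set the midpoint/sharpness
.vanthoff_f <- function(temp_c, tm, dh) {
  Tk <- temp_c + 273.15
  Tm <- tm + 273.15
  # K_unfold = exp(-(dH/R)(1/T - 1/Tm)); f = 1 / (1 + K)
  K <- exp(-(dh * 1000 / 1.9872) * (1 / Tk - 1 / Tm))
  1 / (1 + K)
}

#' Simulate a two-state melting curve with sloping baselines
#'
#' The observed ellipticity is the two-state mixture
#' `theta(T) = f(T) (a_f + b_f T) + (1 - f(T)) (a_u + b_u T) + noise`,
#' with `f(T)` the van't Hoff folded fraction (exactly 0.5 at `tm`).
#'
#' @param params A [melting_params()] list.
#' @return A tibble of class `qdh_melting_curve` with columns
#'   `temperature`, `ellipticity`.
#' @export
simulate_melting_curve <- function(params = melting_params()) {
  stopifnot(inherits(params, "qdh_melting_params"))
  Tg <- params$temperatures
  f <- .vanthoff_f(Tg, params$tm, params$dh)
  th_f <- params$baseline_folded[1] + params$baseline_folded[2] * Tg
  th_u <- params$baseline_unfolded[1] + params$baseline_unfolded[2] * Tg
  y <- f * th_f + (1 - f) * th_u
  if (params$noise_sd > 0) {
    y <- y + .with_seed(params$seed, rnorm(length(Tg), sd = params$noise_sd))
  }
  out <- tibble(temperature = Tg, ellipticity = y)
  class(out) <- c("qdh_melting_curve", class(out))
  attr(out, "params") <- params
  out
}
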