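## Contrast profiles and the analytic flat-bilayer form factor.
##
## For q > 0.05 1/A, scattering from ~100 nm unilamellar vesicles is
## insensitive to overall vesicle size and morphology, so the measured
## intensity is modelled as I(q) = scale * |F(q)|^2 / q^2 + background with
## F(q) the flat-bilayer form factor (the 1D Fourier amplitude of the
## contrast profile).

## Scattering densities of every component for one probe/contrast.
## x-ray: e/A^3; neutron: 1e-6 A^-2.
.component_slds <- function(model, probe = c("xray", "neutron"), x_D = 0) {
  probe <- match.arg(probe)
  solv <- sdp_solvent(x_D = x_D, V_W = model$solvent$V_W)
  dens <- function(g) {
    if (probe == "xray") xray_sld(g) else neutron_sld(g, solv)
  }
  rho <- lapply(model$components, function(cp) dens(cp$group))
  rho$CH2 <- dens(model$groups$CH2)
  rho$solvent <- dens(water_group(V_W = solv$V_W))
  rho
}

#' Contrast profile of an SDP model
#'
#' The scattering contrast versus solvent along the bilayer normal:
#' `drho(z) = sum_i P_i(z) (rho_i - rho_solvent)`, in e/A^3 for x-rays and
#' 1e-6 A^-2 for neutrons at D2O fraction `x_D`.
#'
#' @param model An [build_unit_cell()] model.
#' @param probe `"xray"` or `"neutron"`.
#' @param x_D Solvent D2O mole fraction (neutron contrasts).
#' @param z_grid Positions, Angstrom.
#' @return Tibble of class `sdp_contrast` with columns `z`, `drho`.
#' @export
contrast_profile <- function(model, probe = c("xray", "neutron"), x_D = 0,
                             z_grid = seq(-45, 45, by = 0.1)) {
  probe <- match.arg(probe)
  rho <- .component_slds(model, probe, x_D)
  prof <- volume_probability(model, z_grid)
  drho <- prof$CH2 * (rho$CH2 - rho$solvent)
  for (nm in names(model$components)) {
    drho <- drho + prof[[nm]] * (rho[[nm]] - rho$solvent)
  }
  structure(
    tibble::tibble(z = as.numeric(z_grid), drho = drho),
    class = c("sdp_contrast", class(tibble::tibble())),
    probe = probe, x_D = x_D, model = model
  )
}

## Amplitude terms of the analytic form factor for one probe/contrast.
## Gaussian terms carry V*mult*drho with drho vs. solvent for headgroups and
## the peptide, and vs. CH2 for the CH and CH3 groups (the subtraction
## construction); the envelope term carries drho_CH2 alone.
.ff_terms <- function(model, probe, x_D) {
  rho <- .component_slds(model, probe, x_D)
  nm <- names(model$components)
  amp <- numeric(length(nm))
  z <- numeric(length(nm))
  sg <- numeric(length(nm))
  for (i in seq_along(nm)) {
    cp <- model$components[[nm[i]]]
    Vm <- cp$group$volume * cp$group$multiplicity
    ref <- if (cp$role == "chain") rho$CH2 else rho$solvent
    amp[i] <- Vm * (rho[[nm[i]]] - ref)
    z[i] <- cp$z
    sg[i] <- cp$sigma
  }
  list(amp = amp, z = z, sigma = sg,
       drho_CH2 = rho$CH2 - rho$solvent,
       D_C = model$hc$D_C, sigma_HC = model$hc$sigma_HC, A_U = model$A_U)
}

## F(q) from precomputed terms; q strictly positive.
.ff_eval <- function(terms, q) {
  q2 <- q^2
  F <- rep(0, length(q))
  for (i in seq_along(terms$amp)) {
    F <- F + terms$amp[i] * cos(q * terms$z[i]) *
      exp(-q2 * terms$sigma[i]^2 / 2)
  }
  F <- 2 * F / terms$A_U +
    2 * terms$drho_CH2 * sin(q * terms$D_C) / q *
      exp(-q2 * terms$sigma_HC^2 / 2)
  F
}

#' Analytic flat-bilayer form factor
#'
#' Closed-form 1D Fourier amplitude of the contrast profile: each
#' mirror-symmetric Gaussian contributes
#' `2 (V mult / A_U) drho cos(q z) exp(-q^2 sigma^2 / 2)` and the smeared
#' hydrocarbon slab contributes
#' `2 drho_CH2 sin(q D_C) / q exp(-q^2 sigma_HC^2 / 2)`; the CH and CH3
#' Gaussians carry their contrast relative to CH2 so that the three chain
#' groups together reproduce the subtraction construction of the methylene
#' profile.
#'
#' @inheritParams contrast_profile
#' @param q_grid Scattering vectors, 1/Angstrom; strictly positive.
#' @return Tibble of class `sdp_form_factor` with columns `q`, `F` (signed
#'   amplitude per unit area).
#' @export
form_factor_analytic <- function(model, probe = c("xray", "neutron"),
                                 x_D = 0, q_grid) {
  probe <- match.arg(probe)
  q <- as.numeric(q_grid)
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  terms <- .ff_terms(model, probe, x_D)
  structure(
    tibble::tibble(q = q, F = .ff_eval(terms, q)),
    class = c("sdp_form_factor", class(tibble::tibble())),
    probe = probe, x_D = x_D
  )
}

#' Model intensity from a form factor
#'
#' `I(q) = scale |F(q)|^2 / q^2 + background`, the dilute-vesicle
#' (Lorentz-factor) intensity model.  Optionally applies Gaussian
#' q-resolution smearing of fractional width `resolution` (e.g. 0.1 for a
#' 10% wavelength spread), off by default.
#'
#' @param ff An [form_factor_analytic()] result.
#' @param scale Positive intensity scale.
#' @param background Flat background added to every point.
#' @param resolution `NULL` (no smearing) or fractional FWHM `dq/q`.
#' @return Tibble with columns `q`, `I`.
#' @export
intensity <- function(ff, scale = 1, background = 0, resolution = NULL) {
  stopifnot(inherits(ff, "sdp_form_factor") || all(c("q", "F") %in% names(ff)))
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  I <- scale * ff$F^2 / ff$q^2
  if (!is.null(resolution) && resolution > 0) {
    I <- .smear_gaussian(ff$q, I, resolution)
  }
  tibble::tibble(q = ff$q, I = I + background)
}

## Gaussian resolution convolution on an arbitrary grid (trapezoid weights).
.smear_gaussian <- function(q, I, frac_fwhm) {
  sig <- frac_fwhm * q / (2 * sqrt(2 * log(2)))
  w <- diff(q)
  w <- c(w[1], (w[-1] + w[-length(w)]) / 2, w[length(w) - 1]) # grid weights
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    k <- exp(-(q - q[i])^2 / (2 * sig[i]^2)) * w
    out[i] <- sum(k * I) / sum(k)
  }
  out
}

#' Pointwise weighted average of form factors
#'
#' Averaging the form factors of two single-peptide systems emulates the
#' scattering expected if the two peptides did not interact; comparing the
#' average against the fitted mixture form factor (via
#' [form_factor_discrepancy()]) tests that non-interaction hypothesis.
#'
#' @param ff_A,ff_B Form factors on identical q grids.
#' @param weights Two nonnegative weights (normalised internally).
#' @return Tibble of class `sdp_form_factor`.
#' @export
average_form_factors <- function(ff_A, ff_B, weights = c(0.5, 0.5)) {
  if (length(ff_A$q) != length(ff_B$q) ||
      max(abs(ff_A$q - ff_B$q)) > 1e-12) {
    stop("form factors are on different q grids", call. = FALSE)
  }
  stopifnot(length(weights) == 2, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  structure(
    tibble::tibble(q = ff_A$q, F = w[1] * ff_A$F + w[2] * ff_B$F),
    class = c("sdp_form_factor", class(tibble::tibble()))
  )
}

#' Reduced chi-square discrepancy between two form factors
#'
#' With per-point uncertainties the usual reduced chi-square is returned;
#' without, the uncertainty defaults to the RMS amplitude of `ff_ref`, giving
#' a scale-free relative discrepancy (0 for identical curves).
#'
#' @param ff,ff_ref Form factors on identical q grids.
#' @param sigma Optional per-point uncertainties of `ff_ref$F`.
#' @return Scalar discrepancy.
#' @export
form_factor_discrepancy <- function(ff, ff_ref, sigma = NULL) {
  if (length(ff$q) != length(ff_ref$q) ||
      max(abs(ff$q - ff_ref$q)) > 1e-12) {
    stop("form factors are on different q grids", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- sqrt(mean(ff_ref$F^2))
  mean(((ff$F - ff_ref$F) / sigma)^2)
}
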