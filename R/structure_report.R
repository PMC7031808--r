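## Derived structural parameters: Luzzati thickness, hydrocarbon
## half-thickness, headgroup distance, peptide position; comparisons against
## a reference system and the thermal expansion of the area per unit cell.

#' Luzzati bilayer thickness
#'
#' `D_B = 2 V_LP / A_U`, with `V_LP` the total lipid + peptide volume of the
#' unit cell.  Identically equal to the water-deficit integral
#' `int (1 - P_W(z)) dz` of the same model.
#'
#' @param model An `sdp_model`.
#' @return Thickness in Angstrom.
#' @export
luzzati_thickness <- function(model) {
  stopifnot(inherits(model, "sdp_model"))
  if (model$A_U <= 0) stop("invalid model: A_U must be positive",
                           call. = FALSE)
  2 * model$V_LP / model$A_U
}

#' Hydrocarbon chain length (core half-thickness)
#'
#' The outer terminal position of the methylene region; by volume closure
#' equal to `V_HC / A_U`.
#'
#' @param model An `sdp_model`.
#' @return Half-thickness in Angstrom.
#' @export
chain_length <- function(model) {
  stopifnot(inherits(model, "sdp_model"))
  model$hc$D_C
}

#' Headgroup distance
#'
#' Signed projected distance from the carbonyl-glycerol to the phosphate
#' group, `D_HD = z_PO4 - z_CG`, a proxy for average headgroup tilt.
#'
#' @param model An `sdp_model`.
#' @return Distance in Angstrom.
#' @export
headgroup_distance <- function(model) {
  stopifnot(inherits(model, "sdp_model"))
  cp <- model$components
  if (is.null(cp$PO4) || is.null(cp$CG)) {
    stop("model lacks PO4 or CG group", call. = FALSE)
  }
  cp$PO4$z - cp$CG$z
}

#' Structural parameter report
#'
#' One-row tibble of the derived structural parameters.  For an ensemble
#' fit, every quantity is computed per run and then aggregated with the same
#' center-of-mass / second-moment convention as the raw parameters, so the
#' uncertainties reflect the statistical spread of all solutions.
#'
#' @param x An `sdp_model` or `sdp_fit`.
#' @param ... Unused.
#' @return Tibble of class `sdp_structure_report` with columns `A_U`, `D_B`,
#'   `D_C`, `z_p`, `D_HD` (and `*_u` uncertainties for fits).
#' @export
structure_report <- function(x, ...) UseMethod("structure_report")

#' @rdname structure_report
#' @export
structure_report.sdp_model <- function(x, ...) {
  out <- tibble::tibble(
    A_U = x$A_U,
    D_B = luzzati_thickness(x),
    D_C = chain_length(x),
    z_p = if (x$PL_ratio > 0) x$components$peptide$z else NA_real_,
    D_HD = headgroup_distance(x)
  )
  class(out) <- c("sdp_structure_report", class(out))
  out
}

#' @rdname structure_report
#' @export
structure_report.sdp_fit <- function(x, ...) {
  pre <- attr(x$cost, "precomp")
  runs <- x$runs[x$runs$converged, , drop = FALSE]
  V_LP <- pre$template$V_LP
  V_HC <- pre$V_HC
  per_run <- tibble::tibble(
    A_U = runs$A_U,
    D_B = 2 * V_LP / runs$A_U,
    D_C = V_HC / runs$A_U,
    z_p = if ("z_pep" %in% names(runs)) runs$z_pep else NA_real_,
    D_HD = runs$z_PO4 - runs$z_CG
  )
  est <- vapply(per_run, mean, 0)
  unc <- vapply(per_run, function(v) sqrt(mean((v - mean(v))^2)), 0)
  out <- tibble::as_tibble(as.list(est))
  for (nm in names(unc)) out[[paste0(nm, "_u")]] <- unc[[nm]]
  class(out) <- c("sdp_structure_report", class(out))
  out
}

#' Assemble a structure report from known values
#'
#' Convenience constructor for reports quoted from published tables (so they
#' can be compared with [compare_to_reference()]).
#'
#' @param A_U,D_B,D_C,z_p,D_HD Values in Angstrom (squared for `A_U`).
#' @param A_U_u,D_B_u,D_C_u,z_p_u,D_HD_u Optional uncertainties.
#' @return An `sdp_structure_report` tibble.
#' @export
structure_report_values <- function(A_U, D_B = NA, D_C = NA, z_p = NA,
                                    D_HD = NA, A_U_u = NA, D_B_u = NA,
                                    D_C_u = NA, z_p_u = NA, D_HD_u = NA) {
  out <- tibble::tibble(A_U = A_U, D_B = D_B, D_C = D_C, z_p = z_p,
                        D_HD = D_HD, A_U_u = A_U_u, D_B_u = D_B_u,
                        D_C_u = D_C_u, z_p_u = z_p_u, D_HD_u = D_HD_u)
  class(out) <- c("sdp_structure_report", class(out))
  out
}

#' Published reference structures for POPE/POPG (3:1) with magainins
#'
#' Joint SAXS/SANS structural parameters of POPE/POPG (3:1 mol/mol)
#' bilayers at 35 C, pure and with L18W-PGLa, MG2a, or their equimolar
#' mixture at P:L = 1:200, as determined by scattering-density-profile
#' analysis (center of mass over 400 optimisation runs, second-moment
#' uncertainties).
#'
#' @return Tibble with one row per system.
#' @export
magainin_reference_structures <- function() {
  tibble::tribble(
    ~system,      ~A_U,  ~A_U_u, ~D_B,  ~D_B_u, ~D_C,  ~D_C_u, ~z_p,  ~z_p_u, ~D_HD, ~D_HD_u,
    "pure",       60.56, 0.10,   39.15, 0.06,   15.34, 0.02,   NA,    NA,     4.19,  0.05,
    "L18W-PGLa",  61.26, 0.13,   39.49, 0.08,   15.16, 0.03,   15.75, 0.44,   4.07,  0.06,
    "MG2a",       62.00, 0.09,   39.17, 0.06,   14.98, 0.02,   16.29, 0.50,   3.80,  0.06,
    "mixture",    63.29, 0.06,   38.31, 0.03,   14.68, 0.01,   15.98, 0.43,   4.45,  0.04
  )
}

#' Differences between a report and a reference system
#'
#' Computes `dA_U = A_U - A_U(ref)`, `dD_B`, `2 dD_C` (twice the change of
#' the hydrocarbon half-thickness, the membrane-thinning measure that is
#' free of peptide-volume contributions), `dz_p` and `dD_HD`.  Uncertainties
#' are added in quadrature; `rounded` reports the delta at the 1-decimal
#' precision used in prose.
#'
#' @param report,reference `sdp_structure_report` rows (or tibbles with the
#'   same columns).
#' @return Tibble with columns `term`, `delta`, `uncertainty`, `rounded`.
#' @export
compare_to_reference <- function(report, reference) {
  delta_of <- function(col, factor = 1) {
    d <- factor * (report[[col]][1] - reference[[col]][1])
    ucol <- paste0(col, "_u")
    u <- NA_real_
    if (ucol %in% names(report) && ucol %in% names(reference)) {
      u <- abs(factor) * sqrt(report[[ucol]][1]^2 + reference[[ucol]][1]^2)
    }
    c(d, u)
  }
  vals <- rbind(
    dA_U    = delta_of("A_U"),
    dD_B    = delta_of("D_B"),
    `2dD_C` = delta_of("D_C", factor = 2),
    dz_p    = delta_of("z_p"),
    dD_HD   = delta_of("D_HD")
  )
  tibble::tibble(
    term = rownames(vals),
    delta = unname(vals[, 1]),
    uncertainty = unname(vals[, 2]),
    rounded = round(unname(vals[, 1]), 1)
  )
}

#' Thermal expansion of the area per unit cell
#'
#' Ordinary least-squares slope of `A_U` against temperature, with its
#' standard error.
#'
#' @param series Data frame with columns `temperature` (C) and `A_U` (A^2);
#'   an optional `A_U_u` column is carried through but not used as weights
#'   (plain OLS, matching the reporting convention).
#' @return Tibble with `slope` (A^2/K), `se`, `intercept`, `n`.
#' @export
thermal_expansion <- function(series) {
  stopifnot(all(c("temperature", "A_U") %in% names(series)))
  if (length(unique(series$temperature)) < 2) {
    stop("need at least two distinct temperatures", call. = FALSE)
  }
  fit <- stats::lm(A_U ~ temperature, data = series)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    slope = sm["temperature", "Estimate"],
    se = sm["temperature", "Std. Error"],
    intercept = sm["(Intercept)", "Estimate"],
    n = nrow(series)
  )
}

#' Lipid volume as a function of temperature
#'
#' Linear model `V_L(T) = V_ref + dV_dT (T - T_ref)` used when converting
#' temperature-series fits to areas; the default slope corresponds to a
#' volume expansivity of about 8e-4 per K for the averaged POPE/POPG lipid.
#'
#' @param temperature Temperature(s), C.
#' @param V_ref Reference volume (A^3) at `T_ref`.
#' @param dV_dT Volume slope, A^3/K.
#' @param T_ref Reference temperature, C.
#' @return Volume(s), A^3.
#' @export
lipid_volume_at <- function(temperature, V_ref = 1185.5, dV_dT = 0.92,
                            T_ref = 35) {
  V_ref + dV_dT * (temperature - T_ref)
}

#' Simulate a thermal series of areas per unit cell
#'
#' Generates `A_U(T) = A_0 + slope (T - T_ref)` with additive Gaussian
#' noise, emulating the per-temperature ensemble estimates of a
#' temperature-resolved SAXS series.
#'
#' @param slope True expansion slope, A^2/K.
#' @param A_0 Area at `T_ref`, A^2.
#' @param temperatures Temperatures, C.
#' @param noise Additive noise SD, A^2.
#' @param seed Integer seed.
#' @param T_ref Reference temperature, C.
#' @return Tibble with `temperature`, `A_U`, `A_U_u`.
#' @export
simulate_thermal_series <- function(slope = 0.22, A_0 = 60.56,
                                    temperatures = seq(35, 50, by = 2.5),
                                    noise = 0.1, seed = NULL, T_ref = 35) {
  if (!is.null(seed)) set.seed(seed)
  A <- A_0 + slope * (temperatures - T_ref) +
    stats::rnorm(length(temperatures), 0, noise)
  tibble::tibble(temperature = temperatures, A_U = A, A_U_u = noise)
}
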