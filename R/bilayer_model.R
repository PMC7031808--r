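## Symmetric SDP unit cell: composition-averaged POPE/POPG lipid described by
## Gaussian quasimolecular groups, a smeared hydrocarbon slab, a single
## peptide Gaussian, and water filling the rest.  z = 0 at the bilayer
## midplane; both leaflets are mirror images.

.sigma_min <- 1.0 # A, lower bound on any Gaussian width

#' Geometry parameters of the default POPE/POPG unit cell
#'
#' Positions (z, from the midplane) and widths (sigma) of the headgroup
#' Gaussians, the hydrocarbon interface smearing, and the peptide Gaussian,
#' in Angstrom.  These are the generator ground-truth values for the pure
#' bilayer; fits treat most of them as free parameters.
#'
#' @return Named list of geometry parameters.
#' @export
default_geometry <- function() {
  list(
    A_U = 60.56,
    z_CG = 16.3,  sigma_CG = 2.4,
    z_PO4 = 20.49, sigma_PO4 = 2.2,
    z_ENX = 21.5, sigma_ENX = 2.5,
    z_PG2 = 21.0, sigma_PG2 = 2.7,
    sigma_HC = 2.5,
    z_pep = 16.0, sigma_pep = 4.5
  )
}

#' Build the symmetric SDP unit cell
#'
#' Assembles the composition-averaged lipid (shared chains, CG and PO4; ENX
#' and PG2 carrying the lipid mole fractions as multiplicities), an optional
#' peptide Gaussian, and the hydrocarbon envelope.  The hydrocarbon
#' half-thickness is not a free parameter: volume closure fixes
#' `D_C = V_HC / A_U`, with `V_HC` the summed chain-group volume per averaged
#' lipid.  For more than one peptide (an equimolar mixture) a single combined
#' Gaussian is built with averaged composition and the summed
#' peptide-to-lipid ratio.
#'
#' @param params Geometry parameters, see [default_geometry()]; must contain
#'   `A_U`, `z_*`/`sigma_*` for ENX, PG2, PO4 and CG, and `sigma_HC` (plus
#'   `z_pep`, `sigma_pep` when peptides are present).
#' @param peptides `NULL`, a single `peptide_spec`, or a list of specs
#'   combined equimolarly.
#' @param PL_ratio Total peptide-to-lipid mole ratio (e.g. 1/200).
#' @param lipid_fractions Named vector of POPE/POPG mole fractions summing
#'   to 1.
#' @param groups Group set, see [lipid_groups_pope_popg()].
#' @param solvent An [sdp_solvent()].
#' @param ch_frac Position of the oleoyl CH (double-bond) Gaussian as a
#'   fraction of `D_C`.
#' @param sigma_CH,sigma_CH3 Widths (A) of the CH and terminal CH3 Gaussians
#'   (held fixed in fits).
#' @return An object of class `sdp_model`.
#' @export
#' @examples
#' m <- build_unit_cell(default_geometry())
#' m$D_C # = V_HC / A_U
build_unit_cell <- function(params = default_geometry(),
                            peptides = NULL,
                            PL_ratio = 0,
                            lipid_fractions = c(POPE = 0.75, POPG = 0.25),
                            groups = NULL,
                            solvent = sdp_solvent(x_D = 0),
                            ch_frac = 0.45,
                            sigma_CH = 3.0,
                            sigma_CH3 = 2.9) {
  if (abs(sum(lipid_fractions) - 1) > 1e-9) {
    stop("lipid fractions must sum to 1", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- lipid_groups_pope_popg(pope_frac = unname(lipid_fractions[1]))
  }
  need <- c("A_U", "sigma_HC",
            paste0("z_", c("ENX", "PG2", "PO4", "CG")),
            paste0("sigma_", c("ENX", "PG2", "PO4", "CG")))
  if (PL_ratio > 0) need <- c(need, "z_pep", "sigma_pep")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("missing model parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(params$A_U > 0, PL_ratio >= 0)
  sigmas <- unlist(params[grep("^sigma_", names(params))])
  if (any(sigmas < .sigma_min - 1e-12)) {
    stop("Gaussian widths must be >= ", .sigma_min, " A", call. = FALSE)
  }

  chain_names <- c("CH", "CH2", "CH3")
  V_HC <- sum(vapply(groups[chain_names],
                     function(g) g$volume * g$multiplicity, 0))
  D_C <- V_HC / params$A_U

  pep <- NULL
  if (PL_ratio > 0) {
    if (is.null(peptides)) stop("PL_ratio > 0 but no peptide supplied",
                                call. = FALSE)
    if (inherits(peptides, "peptide_spec")) peptides <- list(peptides)
    pep <- .combine_peptides(peptides)
  }

  ## Gaussian components: headgroups at fitted positions, chain CH/CH3 tied
  ## to the envelope, peptide from the combined spec.
  comp <- list(
    ENX = list(group = groups$ENX, z = params$z_ENX, sigma = params$sigma_ENX,
               role = "head"),
    PG2 = list(group = groups$PG2, z = params$z_PG2, sigma = params$sigma_PG2,
               role = "head"),
    PO4 = list(group = groups$PO4, z = params$z_PO4, sigma = params$sigma_PO4,
               role = "head"),
    CG  = list(group = groups$CG, z = params$z_CG, sigma = params$sigma_CG,
               role = "head"),
    CH  = list(group = groups$CH, z = ch_frac * D_C, sigma = sigma_CH,
               role = "chain"),
    CH3 = list(group = groups$CH3, z = 0, sigma = sigma_CH3, role = "chain")
  )
  if (!is.null(pep)) {
    ## volume per unit cell is V_P * (P:L); multiplicity carries the ratio
    pep$multiplicity <- PL_ratio
    comp$peptide <- list(group = pep, z = params$z_pep,
                         sigma = params$sigma_pep, role = "peptide")
  }
  if (any(vapply(comp, function(x) x$z, 0) < 0)) {
    stop("component centers must be >= 0 (leaflet symmetry is implicit)",
         call. = FALSE)
  }

  V_head <- sum(vapply(groups[c("ENX", "PG2", "PO4", "CG")],
                       function(g) g$volume * g$multiplicity, 0))
  V_L <- V_HC + V_head
  V_P_cell <- if (is.null(pep)) 0 else pep$volume * PL_ratio

  structure(
    list(
      A_U = params$A_U,
      components = comp,
      groups = groups,
      hc = list(V_HC = V_HC, D_C = D_C, sigma_HC = params$sigma_HC),
      D_C = D_C,
      PL_ratio = PL_ratio,
      peptide = pep,
      lipid_fractions = lipid_fractions,
      solvent = solvent,
      V_L = V_L,
      V_LP = V_L + V_P_cell,
      params = params,
      ch_frac = ch_frac,
      sigma_CH = sigma_CH,
      sigma_CH3 = sigma_CH3
    ),
    class = "sdp_model"
  )
}

## Equimolar combination of peptides into one effective spec.
.combine_peptides <- function(peptides) {
  stopifnot(length(peptides) >= 1)
  if (length(peptides) == 1) return(peptides[[1]])
  w <- 1 / length(peptides)
  formula <- Reduce(function(a, b) .add_formula(a, b, mult = w),
                    lapply(peptides, `[[`, "formula"),
                    accumulate = FALSE, init = numeric(0))
  structure(
    list(
      name = paste(vapply(peptides, `[[`, "", "name"), collapse = "+"),
      sequence = NA_character_,
      n_residues = NA_integer_,
      cterm_amidated = NA,
      formula = formula,
      volume = mean(vapply(peptides, `[[`, 0, "volume")),
      n_electrons = mean(vapply(peptides, `[[`, 0, "n_electrons")),
      b_H = mean(vapply(peptides, `[[`, 0, "b_H")),
      n_exchangeable = mean(vapply(peptides, `[[`, 0, "n_exchangeable")),
      multiplicity = 1
    ),
    class = c("peptide_spec", "group_def")
  )
}

#' @export
print.sdp_model <- function(x, ...) {
  cat(sprintf("<sdp_model> A_U = %.2f A^2, D_C = %.2f A, V_L = %.1f A^3",
              x$A_U, x$D_C, x$V_L))
  if (x$PL_ratio > 0) {
    cat(sprintf(", peptide %s at z_p = %.2f A (P:L = 1:%g)",
                x$peptide$name, x$params$z_pep, round(1 / x$PL_ratio)))
  }
  cat("\n")
  invisible(x)
}

## Mirror-symmetric Gaussian volume probability of one component.
.gauss_pair <- function(z, z_c, sigma, V_cell, A_U) {
  amp <- V_cell / (A_U * sigma * sqrt(2 * pi))
  amp * (exp(-(z - z_c)^2 / (2 * sigma^2)) + exp(-(z + z_c)^2 / (2 * sigma^2)))
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## Smeared hydrocarbon slab [-D_C, D_C].
.hc_envelope <- function(z, D_C, sigma_HC) {
  0.5 * (.erf((D_C - z) / (sqrt(2) * sigma_HC)) +
         .erf((D_C + z) / (sqrt(2) * sigma_HC)))
}

#' Volume probability profiles of an SDP model
#'
#' Evaluates every component's volume probability on a grid of distances
#' from the bilayer midplane.  The methylene probability is constructed by
#' subtraction, `P_CH2 = P_HC - P_CH - P_CH3`, so the three chain groups
#' exactly fill the smeared hydrocarbon slab; water fills the remainder of
#' the unit cell.
#'
#' @param model An [build_unit_cell()] model.
#' @param z_grid Positions in Angstrom (symmetric grids or nonnegative
#'   half-grids both work).
#' @return A tibble of class `sdp_profiles` with column `z`, one column per
#'   component, and `water`.  Attribute `min_CH2` records the most negative
#'   methylene probability (diagnostic for inconsistent parameters).
#' @export
volume_probability <- function(model, z_grid = seq(0, 45, by = 0.1)) {
  stopifnot(inherits(model, "sdp_model"))
  z <- as.numeric(z_grid)
  out <- list(z = z)
  P_HC <- .hc_envelope(z, model$hc$D_C, model$hc$sigma_HC)
  for (nm in names(model$components)) {
    cp <- model$components[[nm]]
    V_cell <- cp$group$volume * cp$group$multiplicity
    out[[nm]] <- .gauss_pair(z, cp$z, cp$sigma, V_cell, model$A_U)
  }
  out$CH2 <- P_HC - out$CH - out$CH3
  min_CH2 <- min(out$CH2)
  comp_cols <- setdiff(names(out), "z")
  total <- Reduce(`+`, out[setdiff(comp_cols, c("CH", "CH2", "CH3"))]) + P_HC
  out$water <- 1 - total
  prof <- tibble::as_tibble(out)
  ord <- c("z", "ENX", "PG2", "PO4", "CG", "CH", "CH2", "CH3",
           intersect("peptide", names(prof)), "water")
  prof <- prof[, ord]
  structure(prof,
            class = c("sdp_profiles", class(prof)),
            min_CH2 = min_CH2,
            model = model)
}

#' Water probability of a profile set
#'
#' `P_W(z) = 1 - sum of all component probabilities`; tends to 1 far from
#' the bilayer.  Negative excursions are not clipped — use
#' [check_overfill()] to quantify them.
#'
#' @param profiles An [volume_probability()] result.
#' @return Numeric vector of water probabilities.
#' @export
water_probability <- function(profiles) {
  stopifnot(inherits(profiles, "sdp_profiles"))
  profiles$water
}

#' Maximum volume overfill of a profile set
#'
#' Returns `max(0, max_z(sum_i P_i(z) - 1))`, the worst violation of the
#' packing constraint that the unit cell cannot be more than full.  Used as
#' a penalty during fitting.
#'
#' @param profiles An [volume_probability()] result.
#' @return Scalar nonnegative excess.
#' @export
check_overfill <- function(profiles) {
  stopifnot(inherits(profiles, "sdp_profiles"))
  max(0, max(-profiles$water))
}

#' Write profiles to CSV
#'
#' @param profiles An [volume_probability()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
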