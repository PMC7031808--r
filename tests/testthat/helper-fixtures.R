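# Shared fixtures: numerical quadrature oracles and randomized valid models.

# Trapezoid rule on a half-grid starting at z = 0 for an even function of z:
# integral over the full line is 2 * (trapezoid over [0, zmax]).
trapz_half <- function(z, f) {
  2 * sum((f[-1] + f[-length(f)]) / 2 * diff(z))
}

# Independent cosine-transform oracle for the form factor: F(q) =
# 2 * int_0^inf drho(z) cos(qz) dz, evaluated by trapezoid quadrature on a
# dense half-grid.
ff_numeric_oracle <- function(model, probe, x_D, q, zmax = 70, dz = 0.0025) {
  zg <- seq(0, zmax, by = dz)
  cp <- contrast_profile(model, probe, x_D, zg)
  vapply(q, function(qq) {
    trapz_half(zg, cp$drho * cos(qq * zg))
  }, 0)
}

# Random valid SDP model drawn around the default geometry (seeded by the
# caller); optionally with a peptide.
random_valid_model <- function(with_peptide = FALSE) {
  p <- default_geometry()
  p$A_U <- runif(1, 58, 66)
  p$z_CG <- runif(1, 15.8, 17.0)
  p$sigma_CG <- runif(1, 2.0, 2.8)
  p$z_PO4 <- p$z_CG + runif(1, 3.5, 4.7)
  p$sigma_PO4 <- runif(1, 1.9, 2.6)
  p$z_ENX <- p$z_PO4 + runif(1, 0.5, 1.6)
  p$sigma_ENX <- runif(1, 2.1, 3.0)
  p$z_PG2 <- p$z_PO4 + runif(1, 0.2, 1.2)
  p$sigma_PG2 <- runif(1, 2.2, 3.2)
  p$sigma_HC <- runif(1, 2.0, 3.0)
  if (with_peptide) {
    p$z_pep <- runif(1, 14, 18)
    p$sigma_pep <- runif(1, 3.5, 5.5)
    build_unit_cell(p, peptides = peptide_l18w_pgla(), PL_ratio = 1 / 200)
  } else {
    build_unit_cell(p)
  }
}

# Small marker tibble builder for dimer tests: one frame, explicit positions.
marker_row <- function(frame, id, species, marker, pos) {
  tibble::tibble(frame = frame, peptide_id = id, species = species,
                 marker = marker, x = pos[1], y = pos[2], z = pos[3])
}

make_pair_frame <- function(com_a, n_a, c_a, com_b, n_b, c_b,
                            species = c("A", "B"), frame = 1) {
  dplyr::bind_rows(
    marker_row(frame, "p1", species[1], "COM", com_a),
    marker_row(frame, "p1", species[1], "N", n_a),
    marker_row(frame, "p1", species[1], "C", c_a),
    marker_row(frame, "p2", species[2], "COM", com_b),
    marker_row(frame, "p2", species[2], "N", n_b),
    marker_row(frame, "p2", species[2], "C", c_b)
  )
}
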