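#' @keywords internal
"_PACKAGE"

## Coherent neutron scattering lengths (fm) and electron counts for the
## elements occurring in phospholipids, peptides and water.  b values are the
## standard bound coherent scattering lengths (Sears tables); D is listed as
## its own symbol because H/D substitution is the whole point of contrast
## variation.
.elements <- data.frame(
  symbol    = c("H", "D", "C", "N", "O", "P", "S"),
  electrons = c(1, 1, 6, 7, 8, 15, 16),
  b_coh     = c(-3.7406, 6.671, 6.6460, 9.36, 5.803, 5.13, 2.847)
)

.b_H <- -3.7406 # fm, 1H
.b_D <- 6.671   # fm, 2H

#' Parse a chemical formula string into an element-count vector
#'
#' Formulas are simple element-count strings such as `"C2H7N"` or `"PO4"`.
#' Counts may be fractional (e.g. for composition-averaged groups), in which
#' case they must be given in the named-vector form instead.
#'
#' @param formula A formula string, or an already-parsed named numeric vector
#'   (returned unchanged after validation).
#' @return Named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("C2H7N")
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!names(formula) %in% .elements$symbol)) {
      stop("formula vector must be named with known element symbols",
           call. = FALSE)
    }
    return(formula[formula != 0])
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)",
                                        formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("could not parse formula: ", formula, call. = FALSE)
  }
  sym <- sub("[0-9.]*$", "", parts)
  cnt <- sub("^[A-Z][a-z]?", "", parts)
  cnt <- ifelse(cnt == "", 1, as.numeric(cnt))
  bad <- setdiff(sym, .elements$symbol)
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.numeric(out), names(out))
}

.formula_electrons <- function(formula) {
  idx <- match(names(formula), .elements$symbol)
  sum(formula * .elements$electrons[idx])
}

## Total coherent scattering length (fm) of the all-protiated formula.
.formula_b <- function(formula) {
  idx <- match(names(formula), .elements$symbol)
  sum(formula * .elements$b_coh[idx])
}

.formula_h_count <- function(formula) {
  h <- formula[names(formula) %in% c("H", "D")]
  if (length(h) == 0) 0 else sum(h)
}

#' Define a quasimolecular group
#'
#' A quasimolecular group is a chemically defined fragment of a lipid (or the
#' water molecule) treated as a single scattering unit: phosphate, carbonyl
#' glycerol, methylene, and so on.  Electron number and the all-protiated
#' neutron scattering length are computed from the formula; labile hydrogens
#' exchange with solvent deuterium.
#'
#' @param name Label for the group.
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @param volume Apparent molecular volume in cubic Angstrom (one occurrence).
#' @param n_exchangeable Number of labile (solvent-exchangeable) hydrogens.
#' @param multiplicity Occurrences per averaged-lipid unit cell; may be
#'   fractional for composition-averaged headgroups (e.g. 0.75 for the
#'   ethanolamine group of a 3:1 POPE/POPG bilayer).
#' @return An object of class `group_def`.
#' @export
#' @examples
#' group_def("PO4", "PO4", volume = 53.7)
group_def <- function(name, formula, volume, n_exchangeable = 0,
                      multiplicity = 1) {
  formula <- parse_formula(formula)
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("invalid composition: volume must be a positive number",
         call. = FALSE)
  }
  nH <- .formula_h_count(formula)
  if (n_exchangeable < 0 || n_exchangeable > nH + 1e-9) {
    stop("n_exchangeable must lie in [0, hydrogen count]", call. = FALSE)
  }
  structure(
    list(
      name           = name,
      formula        = formula,
      volume         = volume,
      n_electrons    = .formula_electrons(formula),
      b_H            = .formula_b(formula),
      n_exchangeable = n_exchangeable,
      multiplicity   = multiplicity
    ),
    class = "group_def"
  )
}

#' @export
print.group_def <- function(x, ...) {
  cat(sprintf("<group_def> %s: V = %.1f A^3, %g e-, b_H = %.3f fm, %g exch. H, mult %g\n",
              x$name, x$volume, x$n_electrons, x$b_H, x$n_exchangeable,
              x$multiplicity))
  invisible(x)
}

#' Solvent description for contrast variation
#'
#' @param x_D D2O mole fraction, between 0 and 1.
#' @param V_W Water molecular volume in cubic Angstrom (default 30.0,
#'   appropriate near 35 C).
#' @param temperature Optional temperature in C; if supplied, `V_W` is
#'   adjusted linearly around 30.0 at 35 C with slope `dVW_dT`.
#' @param dVW_dT Thermal expansion of the water volume (A^3/K).
#' @return An object of class `sdp_solvent`.
#' @export
sdp_solvent <- function(x_D = 0, V_W = 30.0, temperature = NULL,
                        dVW_dT = 0.009) {
  if (!is.numeric(x_D) || length(x_D) != 1L || x_D < 0 || x_D > 1) {
    stop("x_D must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(temperature)) V_W <- V_W + dVW_dT * (temperature - 35)
  stopifnot(V_W > 0)
  structure(list(x_D = x_D, V_W = V_W), class = "sdp_solvent")
}

#' Water as a quasimolecular group
#'
#' @param V_W Water molecular volume, cubic Angstrom.
#' @return A `group_def` for H2O with both hydrogens exchangeable.
#' @export
water_group <- function(V_W = 30.0) {
  group_def("W", "H2O", volume = V_W, n_exchangeable = 2)
}

#' X-ray scattering density of a group or peptide
#'
#' Returns the electron density of the fragment, electrons per cubic
#' Angstrom.  The overall intensity scale of a SAXS curve is a free
#' per-dataset parameter, so electron-density units are used throughout
#' rather than absolute scattering-length densities.
#'
#' @param group A [group_def()] or [peptide_from_sequence()] object.
#' @return Electron density, e/A^3.
#' @export
xray_sld <- function(group) {
  stopifnot(inherits(group, c("group_def", "peptide_spec")))
  if (group$volume <= 0) stop("invalid composition: non-positive volume",
                              call. = FALSE)
  group$n_electrons / group$volume
}

#' Neutron scattering length density of a group or peptide
#'
#' Labile hydrogens are assumed to equilibrate fully with the solvent, so the
#' effective deuteration fraction of exchangeable sites equals the solvent
#' D2O mole fraction.
#'
#' @param group A [group_def()] or [peptide_from_sequence()] object.
#' @param solvent An [sdp_solvent()] object (its `x_D` sets the exchange).
#' @return Scattering length density in 1e-6 A^-2.
#' @export
#' @examples
#' neutron_sld(water_group(), sdp_solvent(x_D = 1))
neutron_sld <- function(group, solvent) {
  stopifnot(inherits(group, c("group_def", "peptide_spec")),
            inherits(solvent, "sdp_solvent"))
  b <- group$b_H + group$n_exchangeable * solvent$x_D * (.b_D - .b_H)
  ## fm/A^3 -> 1e-6 A^-2 (1 fm = 1e-5 A)
  10 * b / group$volume
}

## ---- peptides -------------------------------------------------------------

## Residue formulas (residue = amino acid - H2O) and side-chain labile
## hydrogen counts.  Labile counts use the neutral-molecule convention
## matching the formulas (COOH for D/E, NH2 for K, guanidine for R); the
## difference to charged forms is < 1 fm per peptide at any contrast.
.aa_table <- list(
  A = list(f = "C3H5NO",    exch = 0),
  R = list(f = "C6H12N4O",  exch = 4),
  N = list(f = "C4H6N2O2",  exch = 2),
  D = list(f = "C4H5NO3",   exch = 1),
  C = list(f = "C3H5NOS",   exch = 1),
  E = list(f = "C5H7NO3",   exch = 1),
  Q = list(f = "C5H8N2O2",  exch = 2),
  G = list(f = "C2H3NO",    exch = 0),
  H = list(f = "C6H7N3O",   exch = 1),
  I = list(f = "C6H11NO",   exch = 0),
  L = list(f = "C6H11NO",   exch = 0),
  K = list(f = "C6H12N2O",  exch = 2),
  M = list(f = "C5H9NOS",   exch = 0),
  F = list(f = "C9H9NO",    exch = 0),
  P = list(f = "C5H7NO",    exch = 0),
  S = list(f = "C3H5NO2",   exch = 1),
  T = list(f = "C4H7NO2",   exch = 1),
  W = list(f = "C11H10N2O", exch = 1),
  Y = list(f = "C9H9NO2",   exch = 1),
  V = list(f = "C5H9NO",    exch = 0)
)

.add_formula <- function(a, b, mult = 1) {
  sym <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(sym)), sym)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + mult * b
  out[out != 0]
}

#' Build a peptide scattering specification from its sequence
#'
#' Sums residue formulas, adds the terminal H and OH (or NH2 for an amidated
#' C-terminus), and counts labile hydrogens: one backbone NH per non-proline
#' residue, one extra at the free N-terminal amine, side-chain OH/NH/SH
#' hydrogens, and the C-terminal OH or amide NH2.
#'
#' The molecular volume is an input: peptide partial volumes in a membrane
#' are measured quantities and are not reliably reproduced by residue-volume
#' tables.  Defaults are provided by [peptide_l18w_pgla()] and
#' [peptide_mg2a()].
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param volume Molecular volume, cubic Angstrom.
#' @param name Label; defaults to the sequence.
#' @param cterm_amidated Is the C-terminus amidated (CONH2)?
#' @return An object of class `peptide_spec` (also usable wherever a
#'   `group_def` is accepted).
#' @export
#' @examples
#' peptide_from_sequence("GIGK", volume = 1000)
peptide_from_sequence <- function(sequence, volume, name = sequence,
                                  cterm_amidated = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, names(.aa_table))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  formula <- c(H = 2, O = 1) # termini H- and -OH
  exch <- 0
  for (r in res) {
    formula <- .add_formula(formula, parse_formula(.aa_table[[r]]$f))
    exch <- exch + .aa_table[[r]]$exch
    if (r != "P") exch <- exch + 1 # backbone NH
  }
  exch <- exch + 1 # free N-terminal amine: NH2 (second H beyond backbone count)
  if (cterm_amidated) {
    ## -COOH -> -CONH2: swap one O for N + H
    formula <- .add_formula(formula, c(O = -1, N = 1, H = 1))
    exch <- exch + 2 # amide NH2
  } else {
    exch <- exch + 1 # carboxyl OH
  }
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0) {
    stop("invalid composition: peptide volume must be positive", call. = FALSE)
  }
  structure(
    list(
      name           = name,
      sequence       = paste(res, collapse = ""),
      n_residues     = length(res),
      cterm_amidated = cterm_amidated,
      formula        = formula,
      volume         = volume,
      n_electrons    = .formula_electrons(formula),
      b_H            = .formula_b(formula),
      n_exchangeable = exch,
      multiplicity   = 1
    ),
    class = c("peptide_spec", "group_def")
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("<peptide_spec> %s (%d aa%s): V = %.1f A^3, %g e-, b_H = %.1f fm, %g exch. H\n",
              x$name, x$n_residues,
              if (isTRUE(x$cterm_amidated)) ", C-amidated" else "",
              x$volume, x$n_electrons, x$b_H, x$n_exchangeable))
  invisible(x)
}

#' Built-in peptides
#'
#' L18W-PGLa (`GMASKAGAIAGKIAKVAWKAL-NH2`) and magainin 2 amide
#' (`GIGKFLHSAKKFGKAFVGEIMNS-NH2`) with their membrane partial molecular
#' volumes of 4927.8 and 5748.0 cubic Angstrom.
#'
#' @param volume Override the default molecular volume (A^3).
#' @return A `peptide_spec`.
#' @export
peptide_l18w_pgla <- function(volume = 4927.8) {
  peptide_from_sequence("GMASKAGAIAGKIAKVAWKAL", volume = volume,
                        name = "L18W-PGLa", cterm_amidated = TRUE)
}

#' @rdname peptide_l18w_pgla
#' @export
peptide_mg2a <- function(volume = 5748.0) {
  peptide_from_sequence("GIGKFLHSAKKFGKAFVGEIMNS", volume = volume,
                        name = "MG2a", cterm_amidated = TRUE)
}

## ---- built-in lipid group set --------------------------------------------

#' Quasimolecular groups of the averaged POPE/POPG lipid
#'
#' The bilayer is parsed into ethanolamine (ENX, POPE only), headgroup
#' glycerol (PG2, POPG only), phosphate (PO4), carbonyl glycerol (CG), and
#' the hydrocarbon CH, CH2 and CH3 groups.  Chains, CG and PO4 are shared by
#' both lipids (identical chemistry) and carry multiplicity 1 per averaged
#' lipid; ENX and PG2 carry the respective lipid mole fractions.
#'
#' Default volumes follow published SDP work on POPE and POPG near 35 C and
#' close the hydrocarbon core at V_HC = 28 V_CH2 + 2 V_CH + 2 V_CH3 = 928.9
#' A^3; every volume is overridable.
#'
#' @param pope_frac POPE mole fraction (default 0.75).
#' @param volumes Named list overriding default group volumes (A^3 per single
#'   occurrence), names among ENX, PG2, PO4, CG, CH, CH2, CH3.
#' @return Named list of `group_def` objects.
#' @export
lipid_groups_pope_popg <- function(pope_frac = 0.75, volumes = list()) {
  stopifnot(pope_frac >= 0, pope_frac <= 1)
  v <- list(ENX = 51.0, PG2 = 71.0, PO4 = 53.7, CG = 146.8,
            CH = 22.24, CH2 = 27.81, CH3 = 52.83)
  v[names(volumes)] <- volumes
  list(
    ENX = group_def("ENX", "C2H7N",  v$ENX, n_exchangeable = 3,
                    multiplicity = pope_frac),
    PG2 = group_def("PG2", "C3H7O2", v$PG2, n_exchangeable = 2,
                    multiplicity = 1 - pope_frac),
    PO4 = group_def("PO4", "PO4",    v$PO4),
    CG  = group_def("CG",  "C5H5O4", v$CG),
    CH  = group_def("CH",  "CH",     v$CH,  multiplicity = 2),
    CH2 = group_def("CH2", "CH2",    v$CH2, multiplicity = 28),
    CH3 = group_def("CH3", "CH3",    v$CH3, multiplicity = 2)
  )
}

#' Load group and peptide definitions from a YAML config
#'
#' The config file holds one `groups:` block (name, formula, volume,
#' n_exchangeable, multiplicity) and optionally a `peptides:` block
#' (name, sequence, volume, cterm_amidated).
#'
#' @param path Path to a YAML file.
#' @return List with elements `groups` and `peptides`.
#' @export
read_group_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  groups <- lapply(cfg$groups, function(g) {
    group_def(g$name, g$formula, g$volume,
              n_exchangeable = g$n_exchangeable %||% 0,
              multiplicity = g$multiplicity %||% 1)
  })
  names(groups) <- vapply(groups, `[[`, "", "name")
  peptides <- lapply(cfg$peptides, function(p) {
    peptide_from_sequence(p$sequence, volume = p$volume,
                          name = p$name %||% p$sequence,
                          cterm_amidated = isTRUE(p$cterm_amidated))
  })
  if (length(peptides)) {
    names(peptides) <- vapply(peptides, `[[`, "", "name")
  }
  list(groups = groups, peptides = peptides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
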