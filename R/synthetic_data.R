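## Synthetic four-contrast studies with known ground truth.
##
## The generator emulates the experimental design used for POPE/POPG (3:1)
## vesicle studies with magainin-family peptides: one SAXS curve
## (q = 0.0098-0.9 1/A) and three SANS curves at 100/75/50% D2O
## (q = 0.005-0.42 1/A), P:L = 1:200, 35 C, with multiplicative Gaussian
## noise.  Ground-truth parameter sets are available for the pure bilayer
## and the three peptide systems.

#' Ground-truth SDP parameter sets for the four reference systems
#'
#' Geometry and composition used by the synthetic-data generator.  Areas per
#' unit cell, peptide positions and headgroup distances follow the published
#' joint SAXS/SANS values for POPE/POPG (3:1 mol/mol) at 35 C (pure bilayer
#' and P:L = 1:200 peptide systems); Gaussian widths and the remaining
#' positions, which that analysis does not print, are fixed defaults chosen
#' from SDP work on the parent lipids.
#'
#' @param system One of `"pure"`, `"L18W-PGLa"`, `"MG2a"`, `"mixture"`.
#' @return List with elements `params` (see [default_geometry()]),
#'   `peptides`, `PL_ratio`, and `system`.
#' @export
study_truth <- function(system = c("pure", "L18W-PGLa", "MG2a", "mixture")) {
  system <- match.arg(system)
  p <- default_geometry()
  peptides <- NULL
  PL <- 0
  if (system == "L18W-PGLa") {
    p$A_U <- 61.26; p$z_PO4 <- p$z_CG + 4.07; p$z_pep <- 15.75
    peptides <- list(peptide_l18w_pgla()); PL <- 1 / 200
  } else if (system == "MG2a") {
    p$A_U <- 62.00; p$z_PO4 <- p$z_CG + 3.80; p$z_pep <- 16.29
    peptides <- list(peptide_mg2a()); PL <- 1 / 200
  } else if (system == "mixture") {
    p$A_U <- 63.29; p$z_PO4 <- p$z_CG + 4.45; p$z_pep <- 15.98
    peptides <- list(peptide_l18w_pgla(), peptide_mg2a()); PL <- 1 / 200
  }
  list(system = system, params = p, peptides = peptides, PL_ratio = PL)
}

#' Assemble the ground-truth model of a reference system
#'
#' @inheritParams study_truth
#' @param x_D Solvent D2O fraction stored on the model (contrasts are chosen
#'   per dataset at evaluation time).
#' @return An `sdp_model`.
#' @export
truth_model <- function(system = "pure", x_D = 0) {
  tr <- study_truth(system)
  build_unit_cell(tr$params, peptides = tr$peptides, PL_ratio = tr$PL_ratio,
                  solvent = sdp_solvent(x_D = x_D))
}

#' Construct a scattering dataset
#'
#' @param q,I,sigma Numeric vectors: scattering vector (1/A, strictly
#'   increasing), intensity, and uncertainty (positive).
#' @param probe `"xray"` or `"neutron"`.
#' @param x_D Solvent D2O fraction of this contrast.
#' @param q_window Fit window `c(min, max)`; the default keeps
#'   q > 0.05 1/A, where vesicle size and morphology do not contribute.
#' @param name Dataset label.
#' @return Tibble of class `sdp_dataset` with columns `q`, `I`, `sigma`.
#' @export
scattering_dataset <- function(q, I, sigma, probe = c("xray", "neutron"),
                               x_D = 0, q_window = c(0.05, Inf),
                               name = NULL) {
  probe <- match.arg(probe)
  stopifnot(length(q) == length(I), length(q) == length(sigma))
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (is.null(name)) {
    name <- if (probe == "xray") "xray" else sprintf("sans_%g", 100 * x_D)
  }
  structure(
    tibble::tibble(q = as.numeric(q), I = as.numeric(I),
                   sigma = as.numeric(sigma)),
    class = c("sdp_dataset", class(tibble::tibble())),
    probe = probe, x_D = x_D, q_window = q_window, name = name
  )
}

#' Simulate one contrast of a scattering study
#'
#' Evaluates the model intensity on the grid and applies multiplicative
#' Gaussian noise: `I_obs = I_true (1 + noise * eps)` with standard normal
#' `eps`.  The uncertainty column holds the generating standard deviation,
#' `max(noise, floor_frac) * I_true`; with `noise = 0` the curve is exact and
#' the column holds the floor.
#'
#' @param model Ground-truth `sdp_model`.
#' @param probe,x_D Contrast condition.
#' @param q_grid Scattering vectors (1/A).
#' @param noise Relative noise level (default 1%).
#' @param seed Integer seed; required for reproducibility.
#' @param scale,background True intensity scale and flat background.
#' @param floor_frac Relative floor of the uncertainty column.
#' @param q_window Fit window stored on the dataset.
#' @return An [scattering_dataset()].
#' @export
simulate_dataset <- function(model, probe = c("xray", "neutron"), x_D = 0,
                             q_grid, noise = 0.01, seed = NULL,
                             scale = 1, background = 0, floor_frac = 1e-4,
                             q_window = c(0.05, Inf)) {
  probe <- match.arg(probe)
  if (length(q_grid) == 0) stop("empty q grid", call. = FALSE)
  stopifnot(noise >= 0)
  ff <- form_factor_analytic(model, probe, x_D, q_grid)
  I_true <- intensity(ff, scale = scale, background = background)$I
  sig <- pmax(noise, floor_frac) * abs(I_true)
  if (!is.null(seed)) set.seed(seed)
  I_obs <- I_true * (1 + noise * stats::rnorm(length(I_true)))
  scattering_dataset(q_grid, I_obs, sig, probe = probe, x_D = x_D,
                     q_window = q_window)
}

#' Default instrument q grids
#'
#' Log-spaced grids over the SAXS (0.0098-0.9 1/A) and SANS (0.005-0.42 1/A)
#' instrument windows.
#'
#' @param n_saxs,n_sans Number of points.
#' @return List with elements `saxs` and `sans`.
#' @export
instrument_q_grids <- function(n_saxs = 180, n_sans = 120) {
  list(
    saxs = exp(seq(log(0.0098), log(0.9), length.out = n_saxs)),
    sans = exp(seq(log(0.005), log(0.42), length.out = n_sans))
  )
}

#' Recipe for a synthetic four-contrast study
#'
#' @inheritParams study_truth
#' @param noise Relative Gaussian noise (default 1%).
#' @param seed Integer base seed for the study.
#' @param contrasts Data frame with columns `probe` and `x_D`; the default
#'   is one x-ray contrast in light water plus neutron contrasts at 100, 75
#'   and 50% D2O.
#' @param n_saxs,n_sans Points per curve.
#' @return List of class `study_recipe`.
#' @export
study_recipe <- function(system = "pure", noise = 0.01, seed = 1,
                         contrasts = NULL, n_saxs = 180, n_sans = 120) {
  if (is.null(contrasts)) {
    contrasts <- tibble::tibble(
      probe = c("xray", "neutron", "neutron", "neutron"),
      x_D   = c(0, 1.0, 0.75, 0.50)
    )
  }
  stopifnot(nrow(contrasts) >= 1, noise >= 0)
  structure(
    list(system = system, noise = noise, seed = seed, contrasts = contrasts,
         n_saxs = n_saxs, n_sans = n_sans),
    class = "study_recipe"
  )
}

#' Generate a synthetic study (and optionally write it to disk)
#'
#' Simulates every contrast of the recipe from the system's ground-truth
#' model.  With `dir` set, writes one 3-column whitespace ASCII file per
#' contrast (`q I sigma`), a YAML manifest listing probe/x_D/window per
#' file, and the ground-truth parameters as JSON.
#'
#' @param recipe An [study_recipe()].
#' @param dir Optional output directory.
#' @return List of class `sdp_study`: `datasets` (list of
#'   [scattering_dataset()]), `truth`, `model`, `recipe`.
#' @export
make_study <- function(recipe = study_recipe(), dir = NULL) {
  stopifnot(inherits(recipe, "study_recipe"))
  tr <- study_truth(recipe$system)
  model <- build_unit_cell(tr$params, peptides = tr$peptides,
                           PL_ratio = tr$PL_ratio)
  grids <- instrument_q_grids(recipe$n_saxs, recipe$n_sans)
  datasets <- vector("list", nrow(recipe$contrasts))
  for (i in seq_len(nrow(recipe$contrasts))) {
    probe <- recipe$contrasts$probe[i]
    qg <- if (probe == "xray") grids$saxs else grids$sans
    datasets[[i]] <- simulate_dataset(
      model, probe = probe, x_D = recipe$contrasts$x_D[i], q_grid = qg,
      noise = recipe$noise, seed = recipe$seed * 1000L + i
    )
  }
  names(datasets) <- vapply(datasets, attr, "", "name")
  study <- structure(
    list(datasets = datasets, truth = tr, model = model, recipe = recipe),
    class = "sdp_study"
  )
  if (!is.null(dir)) .write_study(study, dir)
  study
}

.write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(system = study$truth$system, datasets = list())
  for (nm in names(study$datasets)) {
    d <- study$datasets[[nm]]
    file <- file.path(dir, paste0(nm, ".dat"))
    utils::write.table(as.data.frame(d), file, row.names = FALSE,
                       col.names = FALSE)
    manifest$datasets[[nm]] <- list(
      file = basename(file), probe = attr(d, "probe"),
      x_D = attr(d, "x_D"), q_window = as.numeric(attr(d, "q_window"))
    )
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  truth <- study$truth
  truth$peptides <- lapply(truth$peptides, function(p) {
    list(sequence = p$sequence, volume = p$volume,
         cterm_amidated = p$cterm_amidated, name = p$name)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a 3-column scattering curve from disk
#'
#' Accepts whitespace- or comma-separated `q I sigma` files, with or without
#' a header line.
#'
#' @param path File path.
#' @inheritParams scattering_dataset
#' @return An [scattering_dataset()].
#' @export
read_scattering <- function(path, probe = c("xray", "neutron"), x_D = 0,
                            q_window = c(0.05, Inf), name = NULL) {
  probe <- match.arg(probe)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- !grepl("^\\s*[-+0-9.eE]", first)
  d <- utils::read.table(path, sep = sep, header = header)
  if (ncol(d) < 3) stop("expected 3 columns (q, I, sigma)", call. = FALSE)
  scattering_dataset(d[[1]], d[[2]], d[[3]], probe = probe, x_D = x_D,
                     q_window = q_window,
                     name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read a study written by [make_study()] back from disk
#'
#' @param dir Directory holding `manifest.yaml` and the curve files.
#' @return List of class `sdp_study` (without the generating model; the
#'   truth parameters are reloaded from `truth.json` when present).
#' @export
read_study <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  datasets <- lapply(names(manifest$datasets), function(nm) {
    m <- manifest$datasets[[nm]]
    read_scattering(file.path(dir, m$file), probe = m$probe, x_D = m$x_D,
                    q_window = as.numeric(m$q_window), name = nm)
  })
  names(datasets) <- names(manifest$datasets)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  structure(list(datasets = datasets, truth = truth, model = NULL,
                 recipe = NULL, system = manifest$system),
            class = "sdp_study")
}
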