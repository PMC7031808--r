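test_that("electron densities follow from formula summation", {
  w <- water_group(30.0)
  expect_equal(w$n_electrons, 10) # 2*Z(H) + Z(O)
  expect_equal(xray_sld(w), 10 / 30.0)

  ch2 <- group_def("CH2", "CH2", volume = 27.81)
  expect_equal(ch2$n_electrons, 8)
  expect_equal(xray_sld(ch2), 8 / 27.81)

  # doubling the volume halves the density
  ch2b <- group_def("CH2", "CH2", volume = 2 * 27.81)
  expect_equal(xray_sld(ch2b), xray_sld(ch2) / 2)

  expect_error(group_def("bad", "CH2", volume = -1), "positive")
})

test_that("built-in lipid groups have consistent electron counts", {
  g <- lipid_groups_pope_popg()
  # recomputed from the formulas by hand: Z(C)=6, Z(H)=1, Z(N)=7, Z(O)=8,
  # Z(P)=15
  expected <- c(ENX = 26, PG2 = 41, PO4 = 47, CG = 67, CH = 7, CH2 = 8,
                CH3 = 9)
  for (nm in names(expected)) {
    expect_equal(g[[nm]]$n_electrons, unname(expected[nm]), info = nm)
  }
  expect_equal(g$ENX$multiplicity, 0.75)
  expect_equal(g$PG2$multiplicity, 0.25)
  # exchangeable count never exceeds the hydrogen count
  for (nm in names(g)) {
    nH <- sum(g[[nm]]$formula[names(g[[nm]]$formula) == "H"])
    expect_lte(g[[nm]]$n_exchangeable, nH)
  }
})

test_that("neutron SLD of water matches the scattering-length arithmetic", {
  # (2*b_D + b_O) / V and (2*b_H + b_O) / V with b_H = -3.7406 fm,
  # b_D = 6.671 fm, b_O = 5.803 fm, V = 30 A^3 (in 1e-6 A^-2)
  w <- water_group(30.0)
  expect_equal(neutron_sld(w, sdp_solvent(1)),
               10 * (2 * 6.671 + 5.803) / 30, tolerance = 1e-12)
  expect_equal(neutron_sld(w, sdp_solvent(0)),
               10 * (2 * (-3.7406) + 5.803) / 30, tolerance = 1e-12)
  expect_error(sdp_solvent(1.2), "x_D")
})

test_that("neutron SLD is affine and monotone in the D2O fraction", {
  groups <- c(lipid_groups_pope_popg(),
              list(pep = peptide_mg2a(), w = water_group()))
  for (g in groups) {
    lo <- neutron_sld(g, sdp_solvent(0))
    hi <- neutron_sld(g, sdp_solvent(1))
    mid <- neutron_sld(g, sdp_solvent(0.5))
    expect_equal(mid, (lo + hi) / 2, tolerance = 1e-12)
    # endpoints bracket every intermediate contrast
    for (x in c(0.25, 0.6, 0.9)) {
      v <- neutron_sld(g, sdp_solvent(x))
      expect_gte(v, min(lo, hi) - 1e-12)
      expect_lte(v, max(lo, hi) + 1e-12)
    }
  }
})

test_that("peptides assemble from residue formulas", {
  # glycyl residue C2H3NO has 30 electrons; free glycine adds H2O (10 e)
  g1 <- peptide_from_sequence("G", volume = 60)
  expect_equal(g1$n_electrons, 40)
  expect_equal(sum(g1$formula * c(C = 0, H = 1, N = 0, O = 0)[
    names(g1$formula)]), 5) # C2H5NO2

  pgla <- peptide_l18w_pgla()
  mg2a <- peptide_mg2a()
  expect_equal(pgla$n_residues, 21)
  expect_equal(mg2a$n_residues, 23)
  expect_equal(pgla$volume, 4927.8)
  expect_equal(mg2a$volume, 5748.0)

  expect_error(peptide_from_sequence("GXZ", volume = 100), "residue")
})

test_that("labile-hydrogen counting follows the backbone + termini rule", {
  # poly-Ala n-mer, free termini: n backbone NH + 1 extra N-terminal amine H
  # + 1 carboxyl OH
  for (n in c(1, 4, 7)) {
    pep <- peptide_from_sequence(strrep("A", n), volume = 100 * n)
    expect_equal(pep$n_exchangeable, n + 2)
  }
  # amidation swaps the carboxyl OH for an amide NH2 (one extra labile H)
  free <- peptide_from_sequence("AAAA", volume = 400)
  amid <- peptide_from_sequence("AAAA", volume = 400, cterm_amidated = TRUE)
  expect_equal(amid$n_exchangeable, free$n_exchangeable + 1)
  # amide formula: one O replaced by N + H
  expect_equal(amid$n_electrons, free$n_electrons - 8 + 7 + 1)
})

test_that("group and peptide definitions load from a YAML config", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "groups:",
    "  - {name: PO4, formula: PO4, volume: 53.7}",
    "  - {name: ENX, formula: C2H7N, volume: 51.0, n_exchangeable: 3,",
    "     multiplicity: 0.75}",
    "peptides:",
    "  - {name: toy, sequence: GIGK, volume: 1000, cterm_amidated: true}"
  ), cfg)
  db <- read_group_config(cfg)
  expect_equal(db$groups$PO4$n_electrons, 47)
  expect_equal(db$groups$ENX$multiplicity, 0.75)
  expect_equal(db$peptides$toy$n_residues, 4)
  expect_true(db$peptides$toy$cterm_amidated)
})
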