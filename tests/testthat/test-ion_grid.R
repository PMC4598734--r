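test_that("composition_from_sequence does peptide-bond bookkeeping", {
  expect_equal(composition_from_sequence("G"),
               c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
  expect_equal(composition_from_sequence("GG"),
               c(C = 4L, H = 8L, N = 2L, O = 3L, S = 0L))
  expect_error(composition_from_sequence("GXG"), "position 2")
  expect_error(composition_from_sequence(""), "non-empty")
})

test_that("peptide masses agree with an independent residue-mass table", {
  for (id in c("Abeta40", "Abeta42")) {
    seqs <- abeta_sequences()
    sp <- peptide_species(id, seqs[[id]])
    # the two residue tables are rounded independently; agreement to ~1e-4 Da
    expect_equal(sp$mono_mass, oracle_peptide_mono(seqs[[id]]), tolerance = 1e-7)
    expect_lt(sp$mono_mass, sp$avg_mass)
    # recomputing from the stored composition reproduces the stored masses
    expect_equal(mass_from_composition(sp$composition, "mono"), sp$mono_mass,
                 tolerance = 1e-9)
    expect_equal(mass_from_composition(sp$composition, "avg"), sp$avg_mass,
                 tolerance = 1e-9)
  }
  expect_equal(ab40_species()$mono_mass, 4327.15, tolerance = 0.01 / 4327)
})

test_that("oligomer m/z follows the charging and cross-link mass rules", {
  ab <- ab40_species()
  k <- ms_constants()
  # explicit formula check across orders and charges
  for (n in 1:4) for (z in c(2L, 5L, 8L)) {
    expect_equal(oligomer_mz(ab, n, z),
                 (n * ab$mono_mass + z * k$proton) / z, tolerance = 1e-12)
  }
  # cross-linked n-mer with one bond is exactly 2 m_H lighter
  d_cl <- oligomer_mz(ab, 2, 5, crosslinked = TRUE, n_bonds = 1)
  d_nc <- oligomer_mz(ab, 2, 5)
  expect_equal(d_nc - d_cl, 2 * k$h_mono / 5, tolerance = 1e-12)
  # m/z strictly decreasing in z at fixed n
  mzs <- sapply(1:9, function(z) oligomer_mz(ab, 3, z))
  expect_true(all(diff(mzs) < 0))
  expect_error(oligomer_mz(ab, 2, 0), "charge_z")
  expect_error(oligomer_mz(ab, 2, 5, crosslinked = FALSE, n_bonds = 1), "n_bonds")
  expect_error(oligomer_mz(ab, 3, 5, crosslinked = TRUE, n_bonds = 1), "n-1 bonds")
})

test_that("n/z-degenerate ions are co-located on the average basis", {
  ab <- ab40_species()
  quad <- sapply(1:4, function(n) oligomer_mz(ab, n, 2L * n, mass_basis = "avg"))
  expect_lt(max(quad) - min(quad), 1)
  # degeneracy property for a cross-linked pair: equal n/z ratio differs by
  # at most n_bonds*2*m_H/z on the average basis
  m2 <- oligomer_mz(ab, 2, 4, crosslinked = TRUE, n_bonds = 1, mass_basis = "avg")
  m1 <- oligomer_mz(ab, 1, 2, mass_basis = "avg")
  expect_lt(abs(m1 - m2), 1 * 2 * ms_constants()$h_avg / 4 + 1e-9)
})

test_that("isotope patterns match a brute-force convolution oracle", {
  # single-carbon sanity: two peaks, second ~1.08% of first
  p1 <- isotope_pattern(c(C = 1), 1)
  expect_equal(nrow(p1), 2)
  expect_equal(diff(p1$mz), 1.003355, tolerance = 1e-6)
  expect_equal(p1$abundance[2] / p1$abundance[1], 0.0107 / 0.9893,
               tolerance = 1e-6)
  ab <- ab40_species()
  pat <- isotope_pattern(ab$composition, 2)
  expect_equal(diff(pat$mz)[1], 0.5016775, tolerance = 1e-4)
  # full envelope against the atom-by-atom convolution oracle
  dimer <- ab$composition * 2L
  pat5 <- isotope_pattern(dimer, 5, abundance_floor = 1e-3)
  oracle <- oracle_neutron_dist(dimer)
  expect_equal(pat5$abundance, oracle[seq_len(nrow(pat5))], tolerance = 1e-6)
  # apex within 1 isotopologue of the carbon Poisson expectation
  apex <- which.max(pat5$abundance) - 1
  expect_lte(abs(apex - round(dimer[["C"]] * 0.0107 / 0.9893)), 1)
  expect_error(isotope_pattern(c(C = 0, H = 0)), "empty")
})

test_that("charge inference round-trips and rejects inconsistent spacings", {
  for (z in 1:20) expect_identical(infer_charge(1.003355 / z), as.integer(z))
  expect_true(is.na(infer_charge(1.003355 / 2.5)))   # >15% off any integer
  expect_true(is.na(infer_charge(NA)))
  expect_true(is.na(infer_charge(1.003355 / 25)))     # beyond max charge
})

test_that("peak assignment uses spacing, then consecutive charge states", {
  ab <- ab40_species()
  grid <- oligomer_grid(ab, orders = 1:6, charges = 1:9)
  # D+5 by isotope spacing at its monoisotopic position
  pk <- data.frame(mz = 1731.9, intensity = 10, spacing = 0.2007)
  a <- assign_peaks(pk, grid, tol_ppm = 20)
  expect_equal(a$rule_used, "isotope_spacing")
  expect_equal(a$n, 2L)
  expect_equal(a$z, 5L)
  # a single Te+7 match without spacing stays unassigned
  pk2 <- data.frame(mz = oligomer_mz(ab, 4, 7, mass_basis = "avg"),
                    intensity = 5, spacing = NA)
  a2 <- assign_peaks(pk2, grid, tol_ppm = 20)
  expect_equal(a2$rule_used, "unassigned")
  # adding Te+8 evidence flips it to consecutive_charge_states
  pk3 <- rbind(pk2, data.frame(mz = oligomer_mz(ab, 4, 8, mass_basis = "avg"),
                               intensity = 5, spacing = NA))
  a3 <- assign_peaks(pk3, grid, tol_ppm = 20)
  expect_equal(a3$rule_used[1], "consecutive_charge_states")
  expect_equal(a3$n[1], 4L)
  expect_error(assign_peaks(pk, grid, tol_ppm = -1), "tol_ppm")
})

test_that("assignment is deterministic and parsimony tie-breaks degenerate channels", {
  ab <- ab40_species()
  grid <- oligomer_grid(ab, orders = 1:6, charges = 1:9)
  # the 2166 channel without spacing: several species satisfy the
  # consecutive rule once their other charge states are present
  mz2166 <- oligomer_mz(ab, 1, 2, mass_basis = "avg")
  pks <- data.frame(
    mz = c(mz2166, oligomer_mz(ab, 1, 3, mass_basis = "avg")),
    intensity = c(10, 5), spacing = NA)
  a <- assign_peaks(pks, grid, tol_ppm = 20)
  expect_equal(a$n[1], 1L)   # lowest order wins
  b <- assign_peaks(pks, grid, tol_ppm = 20)
  expect_identical(a, b)
})
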