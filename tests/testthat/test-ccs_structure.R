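test_that("PDB structures parse into atom clouds with element radii", {
  # 3-atom fixture with altloc A/B on one atom: altloc A kept
  pdb <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.50 10.00           N",
    "ATOM      2  N  BGLY A   1       9.000   9.000   9.000  0.50 10.00           N",
    "ATOM      3  CA  GLY A   1       1.450   0.000   0.000  1.00 10.00           C",
    "ATOM      4  O   GLY A   1       2.400   1.100   0.000  1.00 10.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  cloud <- read_structure(f)
  expect_s3_class(cloud, "atom_cloud")
  expect_equal(nrow(cloud$xyz), 3)
  tab <- vdw_radii_bondi()
  expect_equal(cloud$radii, unname(tab[c("N", "C", "O")]))
  # one-atom synthetic file
  writeLines(pdb[c(3, 5)], f)
  expect_equal(nrow(read_structure(f)$xyz), 1)
  writeLines("END", f)
  expect_error(suppressWarnings(read_structure(f)))
})

test_that("a single sphere reproduces the analytic disk area", {
  cl <- make_cluster("sphere", scale = 2)
  pa <- ccs_projection(cl, probe_radius = 1, n_orientations = 16,
                       n_rays = 20000, seed = 5)
  eh <- ccs_ehss(cl, probe_radius = 1, n_orientations = 16,
                 n_impact = 20000, seed = 5)
  analytic <- pi * (2 + 1)^2
  expect_lte(abs(pa$ccs - analytic), 3 * max(pa$se, 1e-9))
  expect_lte(abs(eh$ccs - analytic), 3 * max(eh$se, 1e-9))
})

test_that("two well-separated spheres are additive under projection", {
  cl <- atom_cloud(rbind(c(0, 0, 0), c(500, 0, 0)), radii = c(2, 3))
  pa <- ccs_projection(cl, probe_radius = 1, n_orientations = 32,
                       n_rays = 40000, seed = 6)
  analytic <- pi * (3^2 + 4^2)
  expect_lte(abs(pa$ccs - analytic), max(4 * pa$se, 0.01 * analytic))
})

test_that("projection matches an independent raster oracle", {
  cl <- make_cluster("convex", n_atoms = 50, scale = 3, seed = 12)
  pa <- ccs_projection(cl, probe_radius = 1, n_orientations = 64,
                       n_rays = 8000, seed = 13)
  oracle <- oracle_raster_projection(cl, probe_radius = 1, n_orientations = 48,
                                     n_pixels = 160, seed = 14)
  expect_equal(pa$ccs, oracle, tolerance = 0.01)
})

test_that("hard-sphere scattering bounds projection from above", {
  # near-convex body: EHSS - PA >= 0 and small
  cvx <- make_cluster("convex", n_atoms = 30, scale = 2, seed = 21)
  pa <- ccs_projection(cvx, 1, 32, 4000, seed = 22)
  eh <- ccs_ehss(cvx, 1, 32, 4000, seed = 22)
  tol <- 3 * sqrt(pa$se^2 + eh$se^2)
  expect_gte(eh$ccs, pa$ccs - tol)
  expect_lte(eh$ccs - pa$ccs, 0.05 * pa$ccs + tol)
  # concave two-lobe body: EHSS strictly exceeds PA, stable across seeds
  lobe <- make_cluster("two_lobe", n_atoms = 60, scale = 12, seed = 23)
  diffs <- vapply(1:5, function(s) {
    p <- ccs_projection(lobe, 1, 32, 3000, seed = 30 + s)
    e <- ccs_ehss(lobe, 1, 32, 3000, seed = 30 + s)
    e$ccs - p$ccs
  }, 0)
  expect_true(all(diffs > 0))
})

test_that("CCS estimates are rigid-motion invariant and radius-monotone", {
  cl <- make_cluster("two_lobe", n_atoms = 40, scale = 10, seed = 41)
  pa1 <- ccs_projection(cl, 1, 48, 4000, seed = 42)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cl2 <- atom_cloud(sweep(cl$xyz %*% R, 2, c(5, -3, 2), `+`), radii = cl$radii)
  pa2 <- ccs_projection(cl2, 1, 48, 4000, seed = 43)
  expect_lte(abs(pa1$ccs - pa2$ccs), 3 * sqrt(pa1$se^2 + pa2$se^2))
  # inflating radii strictly increases the cross-section
  cl_big <- atom_cloud(cl$xyz, radii = cl$radii + 0.5)
  pa3 <- ccs_projection(cl_big, 1, 48, 4000, seed = 42)
  expect_gt(pa3$ccs, pa1$ccs)
  eh1 <- ccs_ehss(cl, 1, 32, 3000, seed = 44)
  eh2 <- ccs_ehss(cl_big, 1, 32, 3000, seed = 44)
  expect_gt(eh2$ccs, eh1$ccs)
})

test_that("Monte Carlo standard error shrinks as 1/sqrt(n)", {
  cl <- make_cluster("two_lobe", n_atoms = 30, scale = 8, seed = 51)
  se_small <- ccs_projection(cl, 1, 16, 1000, seed = 52)$se
  se_big <- ccs_projection(cl, 1, 160, 1000, seed = 52)$se
  # a decade more orientations: s.e. ratio ~ sqrt(10), allow a loose band
  expect_gt(se_small / se_big, sqrt(10) / 2)
  expect_lt(se_small / se_big, sqrt(10) * 2)
})

test_that("model ranking is deterministic with name-order tie-breaks", {
  res <- compare_models(900, c(A = 1400, B = 950))
  expect_equal(res$model[1], "B")
  tie <- compare_models(900, c(zeta = 1000, alpha = 800))
  expect_equal(tie$model, c("alpha", "zeta"))   # equal |delta|: name order
  # a model generated to match the experiment ranks first
  cl <- make_cluster("convex", n_atoms = 20, scale = 2.5, seed = 61)
  omega <- ccs_ehss(cl, 1, 32, 3000, seed = 62)$ccs
  res2 <- compare_models(omega, c(fibrillar = omega * 1.6,
                                  nuclear = omega * 1.3,
                                  globular = omega * 1.01))
  expect_equal(res2$model[1], "globular")
  expect_error(compare_models(numeric(0), c(a = 1)), "non-empty")
})
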