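# Synthetic-data generators with recorded ground truth: profile spectra with
# isotopologue clusters (including n/z-degenerate channels), mobilograms,
# calibrant tables and toy atom clouds. Every generator is deterministic
# given its seed.

#' Oligomer label <-> order mapping
#'
#' @return Named integer vector: M=1, D=2, Tr=3, Te=4, P=5, Hx=6.
#' @export
oligomer_labels <- function() {
  c(M = 1L, D = 2L, Tr = 3L, Te = 4L, P = 5L, Hx = 6L)
}

# drift-time centre (ms) used by the simulator for an n-mer at charge z:
# larger assemblies drift longer, higher charges shorter (T-wave-like trend)
.drift_center <- function(n, z) 1.0 + 40 * sqrt(n) / z

#' Ground truth for a simulated acquisition
#'
#' The "sample" the synthetic instrument measures: the oligomer population
#' distribution, per-species charge-state weights, mobility-peak geometry,
#' and the drift-time calibration the mobility cell obeys.
#'
#' @param distribution Named fractions over oligomer labels (M..Hx), summing
#'   to 1.
#' @param charge_weights Named list: label -> named weight vector over charge
#'   states (names are the z values); weights within a species sum to 1.
#' @param mob_fwhm Mobility-peak FWHM (ms) used for all simulated peaks.
#' @param calibration List `(A, X, c)` of the drift-time power law.
#' @param seed Seed recorded with (and used by) every generator call.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(distribution, charge_weights, mob_fwhm = 0.9,
                         calibration = list(A = 450, X = 0.55, c = 1.41),
                         seed = 1L) {
  if (abs(sum(distribution) - 1) > 1e-9) stop("distribution must sum to 1")
  if (any(distribution < 0)) stop("fractions must be >= 0")
  if (!setequal(names(distribution), names(charge_weights)))
    stop("distribution and charge_weights must cover the same species")
  for (s in names(charge_weights)) {
    w <- charge_weights[[s]]
    if (any(w < 0)) stop("charge weights must be >= 0")
    if (abs(sum(w) - 1) > 1e-9) stop("charge weights for ", s, " must sum to 1")
  }
  structure(list(distribution = distribution, charge_weights = charge_weights,
                 mob_fwhm = mob_fwhm, calibration = calibration,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default ground truth: a low-molecular-weight-like sample
#'
#' Dimers and trimers dominate among the oligomers, monomers are the most
#' abundant single species, and charge-state weights place the classic
#' n/z-degenerate quadruplet (M+2, D+4, Tr+6, Te+8) on one shared channel.
#'
#' @param seed Seed for the derived datasets.
#' @return A [ground_truth()].
#' @export
default_ground_truth <- function(seed = 1L) {
  ground_truth(
    distribution = c(M = 0.45, D = 0.30, Tr = 0.15, Te = 0.07, P = 0.02, Hx = 0.01),
    charge_weights = list(
      M  = c(`2` = 0.7, `3` = 0.3),
      D  = c(`4` = 0.3, `5` = 0.7),
      Tr = c(`5` = 0.2, `6` = 0.5, `7` = 0.3),
      Te = c(`7` = 0.6, `8` = 0.4),
      P  = c(`7` = 0.6, `8` = 0.4),
      Hx = c(`7` = 0.5, `8` = 0.5)
    ),
    seed = seed
  )
}

# theoretical channel table implied by a ground truth for a given peptide
.truth_channels <- function(truth, species) {
  labs <- oligomer_labels()
  rows <- list()
  for (s in names(truth$distribution)) {
    pop <- truth$distribution[[s]]
    if (pop <= 0) next
    w <- truth$charge_weights[[s]]
    for (zi in seq_along(w)) {
      if (w[zi] <= 0) next
      z <- as.integer(names(w)[zi])
      n <- labs[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = s, n = n, z = z,
        mz_mono = oligomer_mz(species, n, z, mass_basis = "mono"),
        mz_avg = oligomer_mz(species, n, z, mass_basis = "avg"),
        weight = pop * w[[zi]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a profile mass spectrum
#'
#' Renders, for every (species, charge) pair with positive weight in the
#' ground truth, an isotopologue cluster at instrument resolution (each
#' isotopologue a Gaussian of FWHM m/z / R, cluster integral proportional to
#' the pair's weight), sums the clusters over the acquisition m/z range and
#' adds white noise. Deliberately produces n/z-degenerate channels where the
#' charge-state weights imply them.
#'
#' @param truth A [ground_truth()].
#' @param species A [peptide_species()].
#' @param resolution Resolving power m/dm (FWHM).
#' @param noise_rel Additive Gaussian noise s.d. as a fraction of the maximum
#'   clean intensity.
#' @param mz_range Acquisition window (Th).
#' @param mz_step Profile grid step (Th).
#' @param seed Seed; defaults to the truth's.
#' @return List of class `mass_spectrum`: `mz`, `intensity`, `channels`
#'   (theoretical channel table with weights), `truth`, `seed`.
#' @export
make_spectrum <- function(truth, species, resolution = 10000, noise_rel = 0.001,
                          mz_range = c(500, 5000), mz_step = 0.02,
                          seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(species, "peptide_species"))
  if (resolution <= 0) stop("resolution must be > 0")
  if (all(truth$distribution == 0)) stop("empty distribution")
  channels <- .truth_channels(truth, species)
  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  y <- numeric(length(mz))
  for (i in seq_len(nrow(channels))) {
    comp <- species$composition * channels$n[i]
    pat <- isotope_pattern(comp, channels$z[i], resolution)
    fwhm <- attr(pat, "fwhm")
    areas <- channels$weight[i] * pat$abundance / sum(pat$abundance)
    for (j in seq_len(nrow(pat))) {
      lo <- pat$mz[j] - 5 * fwhm; hi <- pat$mz[j] + 5 * fwhm
      idx <- which(mz >= lo & mz <= hi)
      if (length(idx) == 0L) next
      y[idx] <- y[idx] + gaussian_fwhm(mz[idx], pat$mz[j], fwhm, areas[j])
    }
  }
  if (noise_rel > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_rel * max(y))
  }
  structure(list(mz = mz, intensity = y, channels = channels,
                 resolution = resolution, noise_rel = noise_rel,
                 truth = truth, seed = seed),
            class = "mass_spectrum")
}

#' Simulate a mobilogram
#'
#' Evaluates the baseline-plus-Gaussians model on a drift-time axis and adds
#' white noise.
#'
#' @param components data.frame `(x_c, w, A, label)`.
#' @param k_im Constant baseline (counts).
#' @param noise_sd Additive Gaussian noise s.d. (counts).
#' @param axis Increasing drift-time axis (ms).
#' @param channel Channel label.
#' @param seed RNG seed.
#' @return List: `mobilogram` (a [mobilogram()]), `truth` (components,
#'   k_im, noise_sd, seed), `labels` (component labels in drift order).
#' @export
make_mobilogram <- function(components, k_im = 0, noise_sd = 0,
                            axis = seq(2, 30, by = 0.05), channel = "",
                            seed = 1L) {
  stopifnot(is.data.frame(components), all(c("x_c", "w", "A") %in% names(components)))
  if (any(diff(axis) <= 0)) stop("axis must be increasing")
  y <- rep(k_im, length(axis))
  for (i in seq_len(nrow(components)))
    y <- y + gaussian_fwhm(axis, components$x_c[i], components$w[i], components$A[i])
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  y <- pmax(y, 0)
  ord <- order(components$x_c)
  labels <- if ("label" %in% names(components)) components$label[ord] else NULL
  list(mobilogram = mobilogram(axis, y, channel = channel),
       truth = list(components = components, k_im = k_im,
                    noise_sd = noise_sd, seed = seed),
       labels = labels)
}

#' Simulate the mobilograms of ambiguous channels
#'
#' Every channel whose m/z is shared, within tolerance, by ions of more than
#' one oligomer species in the theoretical grid needs mobility evidence: the
#' mobility dimension separates the co-located ions and each mobility peak's
#' own m/z spectrum labels it. This generator emits, for each such channel,
#' a mobilogram whose components are the channel's true contributors (with
#' areas proportional to their weights) and the species labels in drift-time
#' order, mirroring per-peak isotope evidence collected upstream.
#'
#' @param truth A [ground_truth()].
#' @param species A [peptide_species()].
#' @param grid Ion grid the downstream assignment will use.
#' @param tol_mz Co-location tolerance (Th).
#' @param noise_rel Noise s.d. as a fraction of the channel's maximum clean
#'   intensity.
#' @param axis Drift-time axis (ms).
#' @param seed Base seed; each channel uses `seed + channel index`.
#' @return Named list (by rounded channel m/z) of [make_mobilogram()]
#'   results, each with an `mz` element added.
#' @export
make_channel_mobilograms <- function(truth, species, grid, tol_mz = 1.0,
                                     noise_rel = 0.01,
                                     axis = seq(2, 30, by = 0.05),
                                     seed = truth$seed) {
  channels <- .truth_channels(truth, species)
  # group truth channels co-located within tol_mz (average basis)
  grp <- cutree_simple(channels$mz_avg, tol_mz)
  out <- list()
  for (g in unique(grp)) {
    members <- channels[grp == g, , drop = FALSE]
    mz0 <- stats::weighted.mean(members$mz_avg, members$weight)
    near <- grid[abs(grid$mz_avg - mz0) <= tol_mz | abs(grid$mz_mono - mz0) <= tol_mz, , drop = FALSE]
    ambiguous <- length(unique(near$n)) > 1L || nrow(members) > 1L
    if (!ambiguous) next
    comp <- data.frame(
      x_c = .drift_center(members$n, members$z),
      w = truth$mob_fwhm,
      A = members$weight * 1000,
      label = members$label,
      stringsAsFactors = FALSE
    )
    hmax <- max(gaussian_fwhm(comp$x_c, comp$x_c, comp$w, comp$A))
    sim <- make_mobilogram(comp, k_im = 0.02 * hmax, noise_sd = noise_rel * hmax,
                           axis = axis, channel = sprintf("m/z %.1f", mz0),
                           seed = seed + g)
    sim$mz <- mz0
    out[[sprintf("%.0f", mz0)]] <- sim
  }
  out
}

# single-linkage grouping of sorted 1-d values with a gap threshold
cutree_simple <- function(x, gap) {
  ord <- order(x)
  g <- integer(length(x))
  gi <- 1L
  g[ord[1]] <- gi
  for (i in seq_along(ord)[-1]) {
    if (x[ord[i]] - x[ord[i - 1]] > gap) gi <- gi + 1L
    g[ord[i]] <- gi
  }
  g
}

#' Simulate a calibrant acquisition
#'
#' Inverts the drift-time power law for each calibrant ion's reference CCS,
#' adds back the mass-dependent transit delay and applies multiplicative
#' noise: a table ready for [fit_calibration()], with the generating
#' parameters recorded.
#'
#' @param A,X,c Power-law scale, exponent and EDC delay coefficient.
#' @param table Calibrant reference table `(protein, z, mass, ccs_ref)`;
#'   default the shipped 19-ion table.
#' @param gas_mass Drift-gas mass (Da).
#' @param noise_rel Multiplicative drift-time noise s.d. (relative).
#' @param seed RNG seed.
#' @return List: `calibrants` (table with `t_d` column), `truth`.
#' @export
make_calibration_set <- function(A = 450, X = 0.55, c = 1.41,
                                 table = default_calibrants(),
                                 gas_mass = 28.0134, noise_rel = 0,
                                 seed = 1L) {
  if (nrow(table) == 0L) stop("calibrant table is empty")
  k <- ms_constants()
  mu <- .reduced_mass(table$mass, gas_mass)
  omega_prime <- table$ccs_ref / (table$z * sqrt(1 / mu))
  tdp <- (omega_prime / A)^(1 / X)
  mz <- (table$mass + table$z * k$proton) / table$z
  t_d <- tdp + c * sqrt(mz) / 1000
  if (noise_rel > 0) {
    set.seed(seed)
    t_d <- t_d * (1 + stats::rnorm(length(t_d), sd = noise_rel))
  }
  table$t_d <- t_d
  list(calibrants = table,
       truth = list(A = A, X = X, c = c, gas_mass = gas_mass,
                    noise_rel = noise_rel, seed = seed))
}

#' Toy atom clouds for cross-section estimators
#'
#' `sphere`: a single atom (analytic CCS `pi (r + r_probe)^2`); `convex`:
#' atoms on a small spherical shell whose inflated spheres overlap into a
#' near-convex body; `two_lobe`: two dense lobes joined by a thin neck, a
#' concave body on which hard-sphere scattering exceeds the projection
#' approximation.
#'
#' @param kind One of `"sphere"`, `"two_lobe"`, `"convex"`.
#' @param n_atoms Number of atoms.
#' @param scale Characteristic size (A): atom radius for `sphere`, lobe
#'   separation for `two_lobe`, shell radius for `convex`.
#' @param seed RNG seed.
#' @param atom_radius Hard-sphere radius of the generated atoms (A).
#' @return An [atom_cloud()] with attribute `kind` (and `atom_radius`).
#' @export
make_cluster <- function(kind = c("sphere", "two_lobe", "convex"),
                         n_atoms = 1L, scale = 2.0, seed = 1L,
                         atom_radius = 1.7) {
  kind <- match.arg(kind)
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  set.seed(seed)
  if (kind == "sphere") {
    cloud <- atom_cloud(matrix(0, 1, 3), radii = scale, model = "sphere")
  } else if (kind == "convex") {
    u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    cloud <- atom_cloud(u * scale, radii = atom_radius, model = "convex")
  } else {
    half <- ceiling(n_atoms / 2)
    lobe <- function(cx, m) cbind(stats::rnorm(m, cx, scale / 10),
                                  stats::rnorm(m, 0, scale / 10),
                                  stats::rnorm(m, 0, scale / 10))
    xyz <- rbind(lobe(-scale / 2, half), lobe(scale / 2, n_atoms - half))
    cloud <- atom_cloud(xyz, radii = atom_radius, model = "two_lobe")
  }
  attr(cloud, "kind") <- kind
  attr(cloud, "atom_radius") <- if (kind == "sphere") scale else atom_radius
  attr(cloud, "seed") <- seed
  cloud
}
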