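# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route than the package code it checks.

# Residue monoisotopic masses from a published residue-mass table (ExPASy),
# independent of the package's elemental-composition route.
residue_mono_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
water_mono <- 18.010565

oracle_peptide_mono <- function(sequence) {
  sum(residue_mono_masses[strsplit(sequence, "")[[1]]]) + water_mono
}

# Brute-force isotope distribution: convolve one atom at a time (no
# exponentiation by squaring).
oracle_neutron_dist <- function(composition) {
  iso <- list(
    C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  conv1 <- function(a, b) {
    out <- rep(0, length(a) + length(b) - 1)
    for (i in seq_along(a)) out[i + seq_along(b) - 1] <-
        out[i + seq_along(b) - 1] + a[i] * b
    out
  }
  d <- 1
  for (el in names(composition))
    for (k in seq_len(composition[[el]])) {
      d <- conv1(d, iso[[el]])
      d <- d[seq_len(min(length(d), 60))]   # keep the head; tails negligible
    }
  d / max(d)
}

# Dense grid-search least squares for a single Gaussian + baseline.
oracle_grid_fit_1g <- function(x, y, xc_grid, w_grid, A_grid, k_grid) {
  best <- NULL; best_rss <- Inf
  for (xc in xc_grid) for (w in w_grid) for (A in A_grid) for (k in k_grid) {
    r <- y - (k + gaussian_fwhm(x, xc, w, A))
    rss <- sum(r^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(xc = xc, w = w, A = A, k = k) }
  }
  list(par = best, rss = best_rss)
}

# Unpaired two-tailed Student's t (pooled variance), from the formulas.
oracle_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Orientation-averaged projected area by pixel rasterisation (independent of
# the package's Monte Carlo disk sampling).
oracle_raster_projection <- function(cloud, probe_radius, n_orientations,
                                     n_pixels = 150, seed = 99) {
  set.seed(seed)
  r <- cloud$radii + probe_radius
  areas <- numeric(n_orientations)
  for (o in seq_len(n_orientations)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    xy <- (cloud$xyz %*% t(R))[, 1:2, drop = FALSE]
    lo <- apply(xy, 2, min) - max(r); hi <- apply(xy, 2, max) + max(r)
    gx <- seq(lo[1], hi[1], length.out = n_pixels)
    gy <- seq(lo[2], hi[2], length.out = n_pixels)
    px <- diff(gx[1:2]); py <- diff(gy[1:2])
    covered <- matrix(FALSE, n_pixels, n_pixels)
    for (j in seq_len(nrow(xy)))
      covered <- covered | (outer((gx - xy[j, 1])^2, (gy - xy[j, 2])^2, `+`) <= r[j]^2)
    areas[o] <- sum(covered) * px * py
  }
  mean(areas)
}

ab40_species <- function() peptide_species("Abeta40", abeta_sequences()[["Abeta40"]])
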