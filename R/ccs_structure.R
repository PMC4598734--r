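# Theoretical collision cross-sections from atomic coordinates:
# projection approximation (orientation-averaged shadow area) and exact
# hard-sphere scattering (specular-reflection trajectories with
# momentum-transfer weighting).

#' Bondi van der Waals radii
#'
#' Element -> radius (A) table used to build hard spheres around atoms.
#'
#' @return Named numeric vector.
#' @export
vdw_radii_bondi <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
    MG = 1.73, ZN = 1.39, FE = 1.60, CA = 2.31, SE = 1.90)
}

#' Construct an atom cloud
#'
#' @param xyz n x 3 matrix of coordinates (A).
#' @param elements Character vector of element symbols (used to look up
#'   radii), or NULL when `radii` given directly.
#' @param radii Per-atom hard-sphere radii (A); defaults to Bondi radii by
#'   element, with 1.7 A and a warning for unknown elements.
#' @param model Model name (e.g. "nuclear", "fibrillar", "compact",
#'   "globular").
#' @return Object of class `atom_cloud`.
#' @export
atom_cloud <- function(xyz, elements = NULL, radii = NULL, model = "model") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) < 1L) stop("xyz must be an n x 3 matrix, n >= 1")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(radii)) {
    if (is.null(elements)) stop("give either elements or radii")
    tab <- vdw_radii_bondi()
    radii <- tab[toupper(elements)]
    if (any(is.na(radii))) {
      warning("unknown element(s) ", paste(unique(elements[is.na(radii)]), collapse = ", "),
              "; using default radius 1.7 A")
      radii[is.na(radii)] <- 1.70
    }
  }
  if (length(radii) == 1L) radii <- rep(radii, nrow(xyz))
  if (length(radii) != nrow(xyz)) stop("one radius per atom required")
  if (any(radii <= 0)) stop("radii must be > 0")
  structure(list(xyz = unname(xyz), elements = elements,
                 radii = unname(as.numeric(radii)), model = model),
            class = "atom_cloud")
}

#' Read an atom cloud from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the first alternate
#' location (altloc "" or "A"), and assigns Bondi radii by element.
#'
#' @param path Path to a PDB file.
#' @param model Model name stored with the cloud; defaults to the file name.
#' @param keep_hetatm Include HETATM records?
#' @return An [atom_cloud()].
#' @export
read_structure <- function(path, model = NULL, keep_hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(el)))
    el <- substr(gsub("[0-9 ]", "", at$elety), 1, 1)
  el[is.na(el) | !nzchar(el)] <- substr(gsub("[0-9 ]", "", at$elety[is.na(el) | !nzchar(el)]), 1, 1)
  atom_cloud(cbind(at$x, at$y, at$z), elements = el,
             model = if (is.null(model)) basename(path) else model)
}

# uniform random rotation matrix (Shoemake quaternion method)
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# bounding circle in the xy-plane covering all inflated spheres
.bounding_disk <- function(xy, r) {
  ctr <- c(mean(range(xy[, 1])), mean(range(xy[, 2])))
  R <- max(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) + r)
  list(center = ctr, radius = R)
}

#' Collision cross-section by the projection approximation
#'
#' Monte Carlo estimate of the orientation-averaged shadow area of the
#' atom spheres inflated by the probe (drift-gas) radius. A strict lower
#' bound on the hard-sphere scattering cross-section; equal to it for
#' convex bodies.
#'
#' @param cloud An [atom_cloud()].
#' @param probe_radius Drift-gas hard-sphere radius (A).
#' @param n_orientations Number of random orientations.
#' @param n_rays Sample points per orientation.
#' @param seed RNG seed (mandatory for a reproducible record).
#' @return List `ccs` (A^2), `se` (Monte Carlo s.e.), `n_orientations`,
#'   `n_rays`, `seed`.
#' @export
ccs_projection <- function(cloud, probe_radius = 1.0, n_orientations = 64L,
                           n_rays = 512L, seed = 1L) {
  stopifnot(inherits(cloud, "atom_cloud"))
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (n_orientations < 1L || n_rays < 1L) stop("need >= 1 orientation and ray")
  set.seed(seed)
  r <- cloud$radii + probe_radius
  est <- numeric(n_orientations)
  for (o in seq_len(n_orientations)) {
    Rm <- .random_rotation()
    xyz <- cloud$xyz %*% t(Rm)
    bd <- .bounding_disk(xyz[, 1:2, drop = FALSE], r)
    # uniform points in the bounding disk
    u <- stats::runif(n_rays); th <- stats::runif(n_rays, 0, 2 * pi)
    rad <- bd$radius * sqrt(u)
    px <- bd$center[1] + rad * cos(th); py <- bd$center[2] + rad * sin(th)
    hit <- rep(FALSE, n_rays)
    for (j in seq_len(nrow(xyz))) {
      hit <- hit | ((px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 <= r[j]^2)
      if (all(hit)) break
    }
    est[o] <- mean(hit) * pi * bd$radius^2
  }
  se <- if (n_orientations > 1L) stats::sd(est) / sqrt(n_orientations) else
    sqrt(mean(est) * (pi * bd$radius^2 - mean(est)) / n_rays)
  list(ccs = mean(est), se = se,
       n_orientations = n_orientations, n_rays = n_rays, seed = seed)
}

# trace a batch of rays (rows of P, unit directions D) through inflated
# spheres with specular reflections; returns final directions
.trace_rays <- function(P, D, centers, r, max_bounces) {
  n_atoms <- nrow(centers)
  active <- rep(TRUE, nrow(P))
  overflow <- 0L
  for (b in seq_len(max_bounces)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    p <- P[idx, , drop = FALSE]; d <- D[idx, , drop = FALSE]
    tmin <- rep(Inf, length(idx)); jmin <- rep(NA_integer_, length(idx))
    for (j in seq_len(n_atoms)) {
      mx <- p[, 1] - centers[j, 1]; my <- p[, 2] - centers[j, 2]; mz <- p[, 3] - centers[j, 3]
      bq <- d[, 1] * mx + d[, 2] * my + d[, 3] * mz
      cq <- mx^2 + my^2 + mz^2 - r[j]^2
      disc <- bq^2 - cq
      tt <- ifelse(disc >= 0, -bq - sqrt(pmax(disc, 0)), Inf)
      sel <- tt > 1e-9 & tt < tmin
      tmin[sel] <- tt[sel]; jmin[sel] <- j
    }
    hit <- is.finite(tmin)
    active[idx[!hit]] <- FALSE
    hidx <- idx[hit]
    if (length(hidx) == 0L) break
    th <- tmin[hit]; cj <- jmin[hit]
    p2 <- P[hidx, , drop = FALSE] + D[hidx, , drop = FALSE] * th
    nrm <- (p2 - centers[cj, , drop = FALSE]) / r[cj]
    dh <- D[hidx, , drop = FALSE]
    dot <- rowSums(dh * nrm)
    D[hidx, ] <- dh - 2 * dot * nrm
    P[hidx, ] <- p2 + D[hidx, , drop = FALSE] * 1e-7
    if (b == max_bounces) overflow <- length(which(active))
  }
  list(D = D, overflow = overflow)
}

#' Collision cross-section by exact hard-sphere scattering
#'
#' Momentum-transfer cross-section from hard-sphere trajectories: for each
#' orientation, probe trajectories enter on a bounding disk, reflect
#' specularly off the atom spheres inflated by the probe radius, and each
#' trajectory contributes `1 - cos(chi)` with `chi` its total deflection.
#' Averaged over impact points and orientations. Always >= the projection
#' approximation for the same cloud; equal for convex bodies.
#'
#' @inheritParams ccs_projection
#' @param n_impact Impact points per orientation.
#' @param max_bounces Reflection cap per trajectory; trajectories exceeding
#'   it are counted with their accumulated deflection (and tallied in
#'   `n_overflow`).
#' @return List `ccs`, `se`, `n_orientations`, `n_impact`, `seed`,
#'   `n_overflow`.
#' @export
ccs_ehss <- function(cloud, probe_radius = 1.0, n_orientations = 64L,
                     n_impact = 512L, seed = 1L, max_bounces = 30L) {
  stopifnot(inherits(cloud, "atom_cloud"))
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (max_bounces < 1L) stop("max_bounces must be >= 1")
  set.seed(seed)
  r <- cloud$radii + probe_radius
  est <- numeric(n_orientations)
  overflow <- 0L
  for (o in seq_len(n_orientations)) {
    Rm <- .random_rotation()
    xyz <- cloud$xyz %*% t(Rm)
    bd <- .bounding_disk(xyz[, 1:2, drop = FALSE], r)
    u <- stats::runif(n_impact); th <- stats::runif(n_impact, 0, 2 * pi)
    rad <- bd$radius * sqrt(u)
    px <- bd$center[1] + rad * cos(th); py <- bd$center[2] + rad * sin(th)
    z0 <- max(xyz[, 3] + r) + 1
    P <- cbind(px, py, z0)
    D <- matrix(rep(c(0, 0, -1), each = n_impact), ncol = 3)
    tr <- .trace_rays(P, D, xyz, r, max_bounces)
    overflow <- overflow + tr$overflow
    cos_chi <- -tr$D[, 3]  # initial direction (0,0,-1) . final
    est[o] <- mean(1 - pmin(pmax(cos_chi, -1), 1)) * pi * bd$radius^2
  }
  if (overflow > 0L)
    message(overflow, " trajectories hit the bounce cap; counted with accumulated deflection")
  se <- if (n_orientations > 1L) stats::sd(est) / sqrt(n_orientations) else NA_real_
  list(ccs = mean(est), se = se, n_orientations = n_orientations,
       n_impact = n_impact, seed = seed, n_overflow = overflow)
}

#' Rank structural models against an experimental CCS
#'
#' Compares each model's theoretical CCS with the mean experimental value
#' and ranks by absolute deviation; ties are broken by model name order.
#'
#' @param experimental Numeric vector of experimental CCS values (A^2);
#'   replicates are averaged.
#' @param models Named numeric vector of model CCS values.
#' @return data.frame `(model, ccs_model, ccs_exp, delta, abs_delta, rank)`
#'   sorted best-first.
#' @export
compare_models <- function(experimental, models) {
  if (length(experimental) == 0L || length(models) == 0L)
    stop("experimental and model CCS lists must be non-empty")
  if (is.null(names(models))) stop("models must be named")
  exp_mean <- mean(experimental)
  out <- data.frame(
    model = names(models), ccs_model = as.numeric(models),
    ccs_exp = exp_mean, delta = as.numeric(models) - exp_mean,
    stringsAsFactors = FALSE
  )
  out$abs_delta <- abs(out$delta)
  out <- out[order(out$abs_delta, out$model), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
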