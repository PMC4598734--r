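# Theoretical ion grid for covalent and non-covalent peptide oligomers:
# elemental compositions, masses, isotope patterns, m/z values, and
# isotope/charge-state based peak assignment.

#' Elemental composition of a peptide from its sequence
#'
#' Sums residue compositions over the canonical one-letter sequence and adds
#' one water for the free N/C termini.
#'
#' @param sequence One-letter amino-acid string (canonical codes only).
#' @return Named integer vector over elements C, H, N, O, S.
#' @export
#' @examples
#' composition_from_sequence("G")   # glycine free amino acid: C2 H5 N O2
composition_from_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("`sequence` must be a single non-empty string")
  codes <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!codes %in% names(.residue_formulas))
  if (length(bad) > 0L)
    stop(sprintf("unknown residue code '%s' at position %d", codes[bad[1]], bad[1]))
  comp <- Reduce(`+`, .residue_formulas[codes])
  comp[["H"]] <- comp[["H"]] + 2L   # + H2O
  comp[["O"]] <- comp[["O"]] + 1L
  storage.mode(comp) <- "integer"
  comp
}

#' Neutral mass from an elemental composition
#'
#' @param composition Named counts over C, H, N, O, S.
#' @param basis `"mono"` (monoisotopic) or `"avg"` (average).
#' @return Mass in Da.
#' @export
mass_from_composition <- function(composition, basis = c("mono", "avg")) {
  basis <- match.arg(basis)
  composition <- .check_composition(composition)
  m <- .element_masses[[basis]][match(names(composition), .element_masses$element)]
  sum(composition * m)
}

.check_composition <- function(composition) {
  if (is.null(names(composition)) || length(composition) == 0L)
    stop("composition must be a named element->count vector")
  unknown <- setdiff(names(composition), .element_masses$element)
  if (length(unknown) > 0L)
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0)) stop("element counts must be >= 0")
  if (sum(composition) == 0) stop("composition is empty")
  composition
}

#' Define a peptide species
#'
#' Builds the per-peptide record the rest of the pipeline refers to: id,
#' sequence, elemental composition, monoisotopic and average masses.
#'
#' @param id Short name (e.g. `"Abeta40"`).
#' @param sequence One-letter amino-acid string.
#' @return Object of class `peptide_species`.
#' @export
#' @examples
#' ab40 <- peptide_species("Abeta40", abeta_sequences()[["Abeta40"]])
#' ab40$mono_mass
peptide_species <- function(id, sequence) {
  comp <- composition_from_sequence(sequence)
  out <- list(
    id = as.character(id),
    sequence = toupper(sequence),
    composition = comp,
    mono_mass = mass_from_composition(comp, "mono"),
    avg_mass = mass_from_composition(comp, "avg")
  )
  class(out) <- "peptide_species"
  out
}

#' @export
print.peptide_species <- function(x, ...) {
  cat(sprintf("<peptide_species> %s: %d residues, M_mono = %.4f Da, M_avg = %.4f Da\n",
              x$id, nchar(x$sequence), x$mono_mass, x$avg_mass))
  invisible(x)
}

#' Theoretical m/z of an oligomer ion
#'
#' Computes (n M - 2 b m_H + z m_H+)/z for an n-mer at charge z, where b is
#' the number of covalent cross-links (each bond formed in the PICUP reaction
#' removes two hydrogen atoms from the assembly).
#'
#' @param species A [peptide_species()].
#' @param order_n Oligomer order (>= 1).
#' @param charge_z Charge state (>= 1).
#' @param crosslinked Covalent oligomer?
#' @param n_bonds Number of covalent bonds; defaults to `order_n - 1`
#'   (minimally connected topology) when cross-linked, must be 0 otherwise.
#' @param mass_basis `"mono"` or `"avg"`.
#' @return m/z in Th.
#' @export
#' @examples
#' ab40 <- peptide_species("Abeta40", abeta_sequences()[["Abeta40"]])
#' oligomer_mz(ab40, order_n = 2, charge_z = 5)       # the D+5 channel
oligomer_mz <- function(species, order_n, charge_z, crosslinked = FALSE,
                        n_bonds = if (crosslinked) order_n - 1L else 0L,
                        mass_basis = c("mono", "avg")) {
  mass_basis <- match.arg(mass_basis)
  stopifnot(inherits(species, "peptide_species"))
  if (order_n < 1) stop("order_n must be >= 1")
  if (charge_z < 1) stop("charge_z must be >= 1")
  if (!crosslinked && n_bonds != 0) stop("n_bonds must be 0 for non-cross-linked ions")
  if (crosslinked && n_bonds < order_n - 1)
    stop("a connected cross-linked n-mer needs at least n-1 bonds")
  k <- ms_constants()
  m_h <- if (mass_basis == "mono") k$h_mono else k$h_avg
  M <- if (mass_basis == "mono") species$mono_mass else species$avg_mass
  (order_n * M - (crosslinked) * n_bonds * 2 * m_h + charge_z * k$proton) / charge_z
}

#' Build the theoretical ion grid
#'
#' Enumerates oligomer ions over orders and charges for one or more peptide
#' species, covalent and/or non-covalent, with monoisotopic and average m/z
#' and the 13C isotopologue spacing of each ion.
#'
#' @param species_list A [peptide_species()] or list of them.
#' @param orders Integer vector of oligomer orders.
#' @param charges Integer vector of charge states.
#' @param crosslinked Logical vector; grid rows are generated for each value
#'   (e.g. `c(FALSE, TRUE)` to cover LMW and LMW_CL ions).
#' @param bond_policy Function `order_n -> n_bonds` for cross-linked ions;
#'   default minimally connected `n - 1`.
#' @return data.frame with columns `species, n, z, crosslinked, n_bonds,
#'   mz_mono, mz_avg, spacing`.
#' @export
oligomer_grid <- function(species_list, orders = 1:6, charges = 1:10,
                          crosslinked = FALSE,
                          bond_policy = function(n) n - 1L) {
  if (inherits(species_list, "peptide_species")) species_list <- list(species_list)
  k <- ms_constants()
  rows <- list()
  for (sp in species_list) {
    for (cl in crosslinked) {
      for (n in orders) {
        if (cl && n == 1L) next  # no cross-linked monomer
        nb <- if (cl) as.integer(bond_policy(n)) else 0L
        for (z in charges) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp$id, n = n, z = z, crosslinked = cl, n_bonds = nb,
            mz_mono = oligomer_mz(sp, n, z, cl, nb, "mono"),
            mz_avg  = oligomer_mz(sp, n, z, cl, nb, "avg"),
            spacing = k$c13_c12 / z,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# n-fold convolution power of a probability vector (index 1 = 0 neutrons),
# by squaring; trailing mass below `trim` of the maximum is dropped.
.conv <- function(a, b, trim = 1e-12) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  keep <- max(which(out > trim * max(out)))
  out[seq_len(keep)]
}

.conv_pow <- function(p, n) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- .conv(result, base)
    base <- .conv(base, base)
    n <- n %/% 2
  }
  result
}

#' Isotopologue pattern of an ion
#'
#' Computes the aggregated isotope distribution of a composition by exact
#' convolution of the per-element isotope distributions on the extra-neutron
#' grid, and places the isotopologues at the monoisotopic m/z plus multiples
#' of the 13C-12C mass difference divided by the charge.
#'
#' @param composition Named element counts.
#' @param charge_z Charge state (protonation assumed).
#' @param resolution Instrument resolving power m/dm (FWHM); attached as the
#'   per-peak FWHM attribute used when rendering profile spectra.
#' @param abundance_floor Isotopologues below this fraction of the most
#'   abundant one are dropped.
#' @return data.frame `(mz, abundance)`, abundances normalised to max = 1,
#'   with attributes `fwhm` (Th) and `spacing` (Th).
#' @export
isotope_pattern <- function(composition, charge_z = 1L, resolution = 10000,
                            abundance_floor = 1e-4) {
  composition <- .check_composition(composition)
  if (charge_z < 1) stop("charge_z must be >= 1")
  if (resolution <= 0) stop("resolution must be > 0")
  dist <- 1
  for (el in names(composition)) {
    cnt <- composition[[el]]
    if (cnt > 0) dist <- .conv(dist, .conv_pow(.element_isotopes[[el]], cnt))
  }
  dist <- dist / max(dist)
  k <- ms_constants()
  mono_mz <- (mass_from_composition(composition, "mono") + charge_z * k$proton) / charge_z
  mz <- mono_mz + (seq_along(dist) - 1L) * k$c13_c12 / charge_z
  keep <- dist >= abundance_floor
  out <- data.frame(mz = mz[keep], abundance = dist[keep])
  attr(out, "fwhm") <- mono_mz / resolution
  attr(out, "spacing") <- k$c13_c12 / charge_z
  out
}

#' Infer charge state from isotopologue spacing
#'
#' Charge is `round(1.003355 / spacing)`; a spacing implying a non-integer
#' charge beyond 15% relative deviation is treated as unmeasurable (NA).
#'
#' @param spacing Observed isotopologue spacing (Th).
#' @param max_charge Largest admissible charge.
#' @param tol_rel Maximum relative deviation of the implied charge from an
#'   integer.
#' @return Integer charge, or NA.
#' @export
infer_charge <- function(spacing, max_charge = 20L, tol_rel = 0.15) {
  if (is.na(spacing) || spacing <= 0) return(NA_integer_)
  zf <- ms_constants()$c13_c12 / spacing
  z <- as.integer(round(zf))
  if (z < 1L || z > max_charge) return(NA_integer_)
  if (abs(zf - z) / z > tol_rel) return(NA_integer_)
  z
}

# ppm distance of an observed m/z from a grid ion, taking the nearer of the
# monoisotopic and average (envelope-centroid) positions: observed values may
# be either depending on whether the cluster was resolved.
.ppm_dist <- function(mz_obs, mz_mono, mz_avg) {
  pmin(abs(mz_obs - mz_mono), abs(mz_obs - mz_avg)) / mz_obs * 1e6
}

#' Assign observed peaks to oligomer ions
#'
#' Implements the two assignment rules used for amyloid-beta oligomer
#' spectra: (1) when the 13C isotopologue spacing of a peak is measurable,
#' the charge is inferred from it and the grid ion with that charge matching
#' in m/z is accepted; (2) when it is not, a species is accepted only if ions
#' of at least two consecutive charge states of that species are matched
#' within tolerance across the peak list. Peaks satisfying neither rule stay
#' unassigned. When several candidates remain, the lowest oligomer order wins
#' (parsimony).
#'
#' @param peaks data.frame with columns `mz`, `intensity`, and optionally
#'   `spacing` (NA when unmeasurable).
#' @param grid Ion grid from [oligomer_grid()].
#' @param tol_ppm Match tolerance in ppm.
#' @return data.frame, one row per peak: observed values, the accepted
#'   (species, n, z, crosslinked), `rule_used` in
#'   `{isotope_spacing, consecutive_charge_states, unassigned}`, and
#'   `n_candidates`; full candidate tables in the `candidates` attribute.
#' @export
assign_peaks <- function(peaks, grid, tol_ppm = 20) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (nrow(grid) == 0L) stop("ion grid is empty")
  if (!all(c("mz", "intensity") %in% names(peaks)))
    stop("peaks must have columns mz, intensity")
  if (!"spacing" %in% names(peaks)) peaks$spacing <- NA_real_

  key <- function(g) paste(g$species, g$n, g$crosslinked, sep = "|")
  cand_list <- lapply(peaks$mz, function(mz) {
    d <- .ppm_dist(mz, grid$mz_mono, grid$mz_avg)
    grid[d <= tol_ppm, , drop = FALSE]
  })
  # charge states matched per species identity, across the whole peak list
  matched <- do.call(rbind, cand_list)
  zset <- if (is.null(matched) || nrow(matched) == 0L) list() else
    split(matched$z, key(matched))

  n <- nrow(peaks)
  out <- data.frame(
    observed_mz = peaks$mz, intensity = peaks$intensity,
    observed_spacing = peaks$spacing,
    species = NA_character_, n = NA_integer_, z = NA_integer_,
    crosslinked = NA, rule_used = "unassigned",
    n_candidates = vapply(cand_list, nrow, 0L),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    cand <- cand_list[[i]]
    if (nrow(cand) == 0L) next
    z_inf <- infer_charge(peaks$spacing[i])
    if (!is.na(z_inf)) {
      hit <- cand[cand$z == z_inf, , drop = FALSE]
      if (nrow(hit) > 0L) {
        hit <- hit[order(hit$n, hit$species), , drop = FALSE][1, ]
        out$species[i] <- hit$species; out$n[i] <- hit$n; out$z[i] <- hit$z
        out$crosslinked[i] <- hit$crosslinked
        out$rule_used[i] <- "isotope_spacing"
        next
      }
    }
    # consecutive-charge-state rule
    ok <- vapply(seq_len(nrow(cand)), function(j) {
      zs <- zset[[key(cand[j, ])]]
      any(c(cand$z[j] - 1L, cand$z[j] + 1L) %in% zs)
    }, logical(1))
    hit <- cand[ok, , drop = FALSE]
    if (nrow(hit) > 0L) {
      hit <- hit[order(hit$n, hit$species), , drop = FALSE][1, ]
      out$species[i] <- hit$species; out$n[i] <- hit$n; out$z[i] <- hit$z
      out$crosslinked[i] <- hit$crosslinked
      out$rule_used[i] <- "consecutive_charge_states"
    }
  }
  attr(out, "candidates") <- cand_list
  out
}
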