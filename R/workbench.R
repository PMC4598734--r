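# Workbench: delimited-text readers/writers, profile-spectrum centroiding,
# pipeline configuration and the end-to-end run.

#' Read / write a peak list
#'
#' Peak lists are CSV with a header and columns `mz`, `intensity`, and
#' optionally `spacing` (Th; NA when the isotopologue spacing was not
#' measurable).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak list needs columns mz, intensity: ", path)
  bad <- which(!is.finite(df$mz))
  if (length(bad) > 0L)
    stop(sprintf("malformed m/z in %s at data row %d", path, bad[1]))
  df
}

#' @rdname read_peaks
#' @param peaks data.frame to write.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a mobilogram
#'
#' Tab-separated columns `drift_ms`, `intensity` preceded by comment
#' headers `# channel:` and optionally `# labels:` (comma-separated species
#' labels of the mobility peaks in drift-time order, as established from
#' their per-peak m/z spectra).
#'
#' @param path File path.
#' @return List: `mobilogram`, `labels` (or NULL).
#' @export
read_mobilogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  channel <- sub("^#\\s*channel:\\s*", "", grep("^#\\s*channel:", hdr, value = TRUE))
  labline <- grep("^#\\s*labels:", hdr, value = TRUE)
  labels <- if (length(labline) > 0L)
    trimws(strsplit(sub("^#\\s*labels:\\s*", "", labline[1]), ",")[[1]]) else NULL
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  if (!all(c("drift_ms", "intensity") %in% names(df)))
    stop("mobilogram needs columns drift_ms, intensity: ", path)
  list(mobilogram = mobilogram(df$drift_ms, df$intensity,
                               channel = if (length(channel)) channel[1] else ""),
       labels = labels)
}

#' @rdname read_mobilogram
#' @param mob A [mobilogram()].
#' @param labels Optional species labels in drift-time order.
#' @export
write_mobilogram <- function(mob, path, labels = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel: %s", mob$channel), con)
  if (!is.null(labels))
    writeLines(sprintf("# labels: %s", paste(labels, collapse = ",")), con)
  utils::write.table(data.frame(drift_ms = mob$drift_time, intensity = mob$intensity),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a profile spectrum
#'
#' CSV with header and columns `mz`, `intensity`.
#'
#' @param path File path.
#' @return List `(mz, intensity)`.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("spectrum needs columns mz, intensity: ", path)
  list(mz = df$mz, intensity = df$intensity)
}

#' @rdname read_spectrum
#' @param spectrum List with `mz` and `intensity`.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(mz = spectrum$mz, intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a calibrant table
#'
#' CSV with columns `protein, z, mass, ccs_ref, t_d`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_calibrants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "z", "mass", "ccs_ref")
  if (!all(need %in% names(df)))
    stop("calibrant table needs columns ", paste(need, collapse = ", "), ": ", path)
  df
}

#' Centroid a profile spectrum into isotope-cluster channels
#'
#' Detects local maxima of a lightly smoothed trace above a noise-aware
#' threshold, groups them into clusters separated by more than `cluster_gap`
#' Th, integrates each cluster's profile down to the noise floor, and
#' estimates the isotopologue spacing from the maxima separations when they
#' are consistent (relative spread < 15%); otherwise the spacing is
#' reported NA (unresolved).
#'
#' @param spectrum List with `mz`, `intensity` (uniform grid).
#' @param min_rel_height Maxima threshold as a fraction of the base peak.
#' @param noise_k Threshold in units of the median absolute deviation of the
#'   smoothed trace (robust noise estimate).
#' @param cluster_gap Gap (Th) separating clusters of maxima; must exceed
#'   the spread of one isotopologue envelope (a few Th) and stay below the
#'   spacing of adjacent oligomer channels (tens of Th).
#' @param pad Integration half-pad (Th) added beyond the outermost maxima of
#'   a cluster; covers the undetected envelope tails while noise integrates
#'   to zero mean.
#' @return data.frame `(mz, intensity, spacing, n_maxima)`: intensity is the
#'   integrated cluster area, mz the intensity-weighted centroid of the
#'   above-floor envelope.
#' @export
centroid_spectrum <- function(spectrum, min_rel_height = 0.002, noise_k = 5,
                              cluster_gap = 10, pad = 3) {
  mz <- spectrum$mz; y <- spectrum$intensity
  step <- stats::median(diff(mz))
  ys <- as.numeric(stats::runmed(y, 5))
  thr <- max(min_rel_height * max(ys), noise_k * stats::mad(ys))
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n], FALSE) &
    ys > thr
  idx <- which(is_max)
  if (length(idx) == 0L)
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      spacing = numeric(0), n_maxima = integer(0)))
  grp <- cutree_simple(mz[idx], cluster_gap)
  rows <- lapply(unique(grp), function(g) {
    gi <- idx[grp == g]
    win <- which(mz >= mz[min(gi)] - pad & mz <= mz[max(gi)] + pad)
    area <- sum(y[win]) * step
    # centroid from the above-floor envelope only, so that window noise does
    # not drag it; floor relative to the cluster's own apex
    floor_c <- max(thr / 3, 0.02 * max(ys[win]))
    wb <- win[ys[win] > floor_c]
    centroid <- sum(mz[wb] * pmax(y[wb], 0)) / sum(pmax(y[wb], 0))
    spac <- NA_real_
    if (length(gi) >= 3L) {
      d <- diff(mz[gi])
      med <- stats::median(d)
      consistent <- abs(d - med) / med < 0.25
      if (mean(consistent) >= 0.6 && length(d[consistent]) >= 2L)
        spac <- stats::median(d[consistent])
    }
    data.frame(mz = centroid, intensity = area, spacing = spac,
               n_maxima = length(gi))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Validated bundle of every setting the end-to-end run uses; a serialized
#' copy is written into each output bundle for provenance.
#'
#' @param species_id,sequence Peptide identity.
#' @param tol_ppm Assignment m/z tolerance (ppm). The pipeline default (40)
#'   is wider than the stick-level default of [assign_peaks()] (20) because
#'   envelope centroids integrated from profile data carry window bias that
#'   exact peak positions do not.
#' @param mass_basis `"mono"` or `"avg"` for reported theoretical m/z.
#' @param orders,charges Grid enumeration ranges.
#' @param crosslinked Build the covalent (cross-linked) grid?
#' @param bond_policy `"minimal"`: n-1 bonds per cross-linked n-mer.
#' @param mob_tol_mz m/z tolerance (Th) for matching a mobilogram to its
#'   channel.
#' @param mz_range Acquisition window (Th).
#' @param seed Seed recorded in the bundle.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(species_id = "Abeta40",
                            sequence = abeta_sequences()[["Abeta40"]],
                            tol_ppm = 40, mass_basis = "mono",
                            orders = 1:6, charges = 1:9,
                            crosslinked = FALSE, bond_policy = "minimal",
                            mob_tol_mz = 1.5, mz_range = c(500, 5000),
                            seed = 1L) {
  stopifnot(tol_ppm > 0, mass_basis %in% c("mono", "avg"),
            all(orders >= 1), all(charges >= 1), mz_range[1] < mz_range[2])
  structure(list(species_id = species_id, sequence = sequence,
                 tol_ppm = tol_ppm, mass_basis = mass_basis,
                 orders = orders, charges = charges,
                 crosslinked = crosslinked, bond_policy = bond_policy,
                 mob_tol_mz = mob_tol_mz, mz_range = mz_range,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis on one acquisition
#'
#' Chains the stages: ion grid -> centroiding -> peak assignment ->
#' mobilogram deconvolution of ambiguous channels -> oligomer population
#' distribution. A channel whose m/z is compatible with ions of more than
#' one oligomer species requires mobility evidence (a mobilogram with
#' per-peak species labels); ambiguous channels without it are excluded
#' from the population statistic and their summed intensity is reported.
#'
#' @param config A [pipeline_config()].
#' @param spectrum Profile spectrum (list with `mz`, `intensity`), or NULL
#'   when `peaks` given directly.
#' @param mobilograms List as from [make_channel_mobilograms()] (or built
#'   from [read_mobilogram()] plus an `mz` element): each entry
#'   `list(mobilogram, labels, mz)`.
#' @param peaks Optional centroided peak list (bypasses `spectrum`).
#' @param sample_id Sample label in the report.
#' @return Object of class `ims_report`: `config`, `grid`, `peaks`,
#'   `assignments`, `channel_table`, `fits`, `distribution`,
#'   `excluded_intensity`.
#' @export
run_pipeline <- function(config, spectrum = NULL, mobilograms = list(),
                         peaks = NULL, sample_id = "sample") {
  stopifnot(inherits(config, "pipeline_config"))
  sp <- peptide_species(config$species_id, config$sequence)
  grid <- oligomer_grid(sp, orders = config$orders, charges = config$charges,
                        crosslinked = config$crosslinked)
  if (is.null(peaks)) {
    if (is.null(spectrum)) stop("give a spectrum or a peak list")
    peaks <- centroid_spectrum(spectrum)
  }
  if (nrow(peaks) == 0L) stop("assignment stage: empty peak list")
  assignments <- assign_peaks(peaks, grid, tol_ppm = config$tol_ppm)
  cand_list <- attr(assignments, "candidates")
  labs <- oligomer_labels()
  lab_of <- function(n) names(labs)[match(n, labs)]

  observations <- list()
  fits <- list()
  excluded <- 0
  channel_rows <- list()
  for (i in seq_len(nrow(assignments))) {
    cand <- cand_list[[i]]
    mzi <- assignments$observed_mz[i]
    inti <- assignments$intensity[i]
    n_species <- length(unique(cand$n))
    status <- NULL
    if (nrow(cand) == 0L || assignments$rule_used[i] == "unassigned") {
      excluded <- excluded + inti
      status <- "unassigned"
    } else if (n_species == 1L) {
      observations[[length(observations) + 1L]] <-
        charge_state_observation(mzi, inti,
                                 stats::setNames(1, lab_of(cand$n[1])))
      status <- "unique"
    } else {
      # ambiguous channel: mobility evidence required
      j <- which(vapply(mobilograms, function(m) abs(m$mz - mzi) <= config$mob_tol_mz, TRUE))
      if (length(j) >= 1L) {
        m <- mobilograms[[j[1]]]
        fit <- fit_mobilogram(m$mobilogram, n_components = length(m$labels),
                              labels = m$labels)
        fits[[sprintf("%.0f", mzi)]] <- fit
        if (!fit$converged) stop(sprintf(
          "deconvolution stage: fit for channel m/z %.1f did not converge", mzi))
        fr <- relative_contributions(fit)
        fr <- tapply(fr, names(fr), sum)  # merge conformers of one species
        observations[[length(observations) + 1L]] <-
          charge_state_observation(mzi, inti, fr / sum(fr))
        status <- "deconvolved"
      } else {
        excluded <- excluded + inti
        status <- "ambiguous_excluded"
      }
    }
    channel_rows[[i]] <- data.frame(mz = mzi, intensity = inti, status = status)
  }
  if (length(observations) == 0L)
    stop("assignment stage: no channel could be attributed to a species")
  dist <- species_population(observations, sample_id = sample_id,
                             excluded_intensity = excluded)
  structure(list(config = config, grid = grid, peaks = peaks,
                 assignments = assignments,
                 channel_table = do.call(rbind, channel_rows),
                 fits = fits, distribution = dist,
                 excluded_intensity = excluded),
            class = "ims_report")
}

#' @export
print.ims_report <- function(x, ...) {
  cat(sprintf("<ims_report> %s: %d channels (%d deconvolved, excluded intensity %.3g)\n",
              x$distribution$sample_id, nrow(x$channel_table), length(x$fits),
              x$excluded_intensity))
  print(x$distribution)
  invisible(x)
}

#' Write a report bundle
#'
#' CSV tables (assignments, channel table, distribution) and a JSON
#' provenance record (config, seed, package version, excluded intensity).
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$assignments, file.path(dir, "assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(report$channel_table, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  pop <- report$distribution$population
  utils::write.csv(data.frame(species = names(pop), population = as.numeric(pop)),
                   file.path(dir, "distribution.csv"), row.names = FALSE)
  prov <- list(
    config = unclass(report$config),
    excluded_intensity = report$excluded_intensity,
    package_version = as.character(utils::packageVersion("oligoIMS"))
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
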