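#!/usr/bin/env Rscript
# Stage 1: simulate the acquisitions the downstream analyses consume.
#
# Three replicate ESI-IM-MS acquisitions for an Abeta40-like and an
# Abeta42-like low-molecular-weight sample (same underlying oligomer
# distribution: the two peptides do not differ detectably at this stage),
# the mobilograms of every m/z channel that needs mobility evidence, and a
# calibrant acquisition at three wave heights.
#
# Bulky profile spectra go to scratch/data/ (regenerable); the ground-truth
# records and the calibrant tables go to results/data/.

suppressPackageStartupMessages(library(oligoIMS))

base_seed <- 20260922L
samples <- list(Abeta40 = 1L, Abeta42 = 2L)
seqs <- abeta_sequences()

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)

for (sample in names(samples)) {
  sp <- peptide_species(sample, seqs[[sample]])
  grid <- oligomer_grid(sp, orders = 1:6, charges = 1:9)
  for (rep in 1:3) {
    seed <- base_seed + 100L * samples[[sample]] + rep
    truth <- default_ground_truth(seed)
    spec <- make_spectrum(truth, sp, seed = seed)
    mobs <- make_channel_mobilograms(truth, sp, grid, seed = seed)
    dir <- sprintf("scratch/data/%s_rep%d", sample, rep)
    dir.create(dir, showWarnings = FALSE)
    write_spectrum(spec, file.path(dir, "spectrum.csv"))
    for (nm in names(mobs))
      write_mobilogram(mobs[[nm]]$mobilogram,
                       file.path(dir, sprintf("mob_%s.tsv", nm)),
                       labels = mobs[[nm]]$labels)
    jsonlite::write_json(
      list(sample = sample, replicate = rep, seed = seed,
           distribution = as.list(truth$distribution),
           charge_weights = truth$charge_weights,
           mobilogram_channels = names(mobs)),
      sprintf("results/data/truth_%s_rep%d.json", sample, rep),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cat(sprintf("%s rep %d: %d profile points, %d mobility channels (seed %d)\n",
                sample, rep, length(spec$mz), length(mobs), seed))
  }
}

# calibrant acquisitions at wave heights 7, 7.5, 8 (one per wave height)
for (i in 1:3) {
  cs <- make_calibration_set(A = 450, X = 0.55, c = 1.41, noise_rel = 0.005,
                             seed = base_seed + 900L + i)
  write.csv(cs$calibrants, sprintf("results/data/calibrants_wh%d.csv", i),
            row.names = FALSE)
}
cat("calibrant tables written for 3 wave heights (19 ions each)\n")
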