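#!/usr/bin/env Rscript
# Stage 3: deconvolve the mobilograms of the ambiguous channels into a
# constant baseline plus Gaussian components (centre, width at half-height,
# area) and tabulate per-channel species fractions and line widths.

suppressPackageStartupMessages(library(oligoIMS))

rows <- list()
for (sample in c("Abeta40", "Abeta42")) {
  for (rep in 1:3) {
    dir <- sprintf("scratch/data/%s_rep%d", sample, rep)
    for (f in list.files(dir, pattern = "^mob_.*\\.tsv$", full.names = TRUE)) {
      mob <- read_mobilogram(f)
      fit <- fit_mobilogram(mob$mobilogram, n_components = length(mob$labels),
                            labels = mob$labels)
      fr <- relative_contributions(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, replicate = rep,
        channel = mob$mobilogram$channel,
        label = fit$components$label,
        x_c = fit$components$x_c, w = fit$components$w,
        A = fit$components$A, fraction = as.numeric(fr),
        k_im = fit$k_im, rss = fit$rss, converged = fit$converged
      )
    }
  }
}
fits <- do.call(rbind, rows)
write.csv(fits, "results/mobilogram_fits.csv", row.names = FALSE)
cat(sprintf("%d mobility components fitted across %d channels; all converged: %s\n",
            nrow(fits), length(unique(paste(fits$sample, fits$replicate, fits$channel))),
            all(fits$converged)))

# line-width contrast between the two samples for the shared-channel dimer
wstats <- with(fits[fits$label == "D", ],
               tapply(w, sample, function(v) c(mean = mean(v), sd = sd(v))))
cat("dimer mobility-peak FWHM (ms):\n")
print(wstats)
cat("fits -> results/mobilogram_fits.csv\n")
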