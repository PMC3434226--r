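#!/usr/bin/env Rscript
## Step 1 -- simulate the study scenes.
##
## Generates the calibrated cell phantoms (rod-shaped cell with
## interfibrillar center + subsarcolemmal periphery; round cell; the
## two-cell scene) and the H2O2 single-spot time course, and writes the
## instrument-style long-format exports plus the ground-truth tables under
## results/sim/. Everything downstream starts from these files.

suppressMessages(library(ramanredox))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
seed <- 1

phantoms <- list(rod = phantom_spec("rod"), round = phantom_spec("round"),
                 two_cell = phantom_spec("two_cell"))
truth_rows <- list()
for (nm in names(phantoms)) {
  ph <- make_cell_phantom(phantoms[[nm]], seed = seed + match(nm, names(phantoms)) - 1)
  write_longform_map(ph$map, sprintf("results/sim/%s_map.tsv", nm))
  utils::write.table(ph$truth$regions, sprintf("results/sim/%s_regions.tsv", nm),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  for (reg in names(ph$truth$true_ratios))
    truth_rows[[paste(nm, reg)]] <- data.frame(
      phantom = nm, region = reg, t(ph$truth$true_ratios[[reg]]))
  cat(sprintf("%s phantom: %d x %d px, %d cell pixels\n", nm,
              nrow(ph$truth$regions), ncol(ph$truth$regions),
              sum(ph$truth$footprint)))
}
truth <- do.call(rbind, truth_rows)
utils::write.table(truth, "results/sim/true_ratios.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("\nNoiseless calibrated region ratios (the generator ground truth):\n")
print(truth, row.names = FALSE)

## H2O2 course: 10 treated + 10 control cells, written one file per cell
sim <- simulate_h2o2_course(h2o2_spec(), seed = seed + 10)
for (cond in c("treated", "control")) {
  recs <- sim[[cond]]
  for (i in seq_along(recs)) {
    dt <- data.table::rbindlist(lapply(seq_along(recs[[i]]$times), function(k)
      data.table::data.table(time = recs[[i]]$times[k],
                             wavenumber = as.numeric(recs[[i]]$spectra[[k]]$axis),
                             intensity = recs[[i]]$spectra[[k]]$intensities)))
    data.table::fwrite(dt, sprintf("results/sim/h2o2_%s_%02d.tsv", cond, i),
                       sep = "\t")
  }
}
cat(sprintf("\nH2O2 course: %d treated / %d control cells, %d time points, lag %g min\n",
            length(sim$treated), length(sim$control),
            length(sim$truth$times), sim$truth$lag))
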