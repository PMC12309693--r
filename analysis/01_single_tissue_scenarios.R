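#!/usr/bin/env Rscript
# Single-tissue migration phenotypes: graded vs uniform vs posterior-only
# activity at m = 32 cells, t_end = 100.  Writes per-scenario reports and a
# division-position table to results/.

suppressPackageStartupMessages(library(midlinesim))
dir.create("results", showWarnings = FALSE)

presets <- c("graded", "uniform", "posterior_only")
seeds <- 1:5

rows <- list()
events <- list()
for (nm in presets) for (s in seeds) {
  sc <- scenario(nm, seed = s)
  r <- sc$report
  rows[[paste(nm, s)]] <- data.frame(
    preset = nm, seed = s, n_divisions = r$n_divisions,
    uniformity_ks = r$uniformity,
    posterior_quartile_fraction = r$posterior_quartile_fraction,
    final_length = r$final_length,
    n_gap_flags_final = length(r$gap_flags))
  ev <- sc$trace$events
  if (nrow(ev)) events[[paste(nm, s)]] <-
      cbind(preset = nm, seed = s, ev)
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/single_tissue_scenarios.csv", row.names = FALSE)
write.csv(do.call(rbind, events), "results/division_events.csv",
          row.names = FALSE)

message("Scenario summary (means over ", length(seeds), " seeds):")
for (nm in presets) {
  sub <- tab[tab$preset == nm, ]
  message(sprintf(
    "  %-18s divisions %5.1f  KS %5.3f  posterior-quartile %4.2f  length %6.1f",
    nm, mean(sub$n_divisions), mean(sub$uniformity_ks),
    mean(sub$posterior_quartile_fraction), mean(sub$final_length)))
}
message("Graded migration distributes divisions along the axis (low KS); ",
        "posterior-only confines them to the posterior quartile; uniform ",
        "migration piles strain onto the anchored anterior end.")

# a simulated kymograph of the graded run, as CSV (rows = frames)
tr <- scenario("graded", seed = 1)$trace
ky <- export_kymograph(tr, "floorplate")
write.csv(ky, "results/kymograph_graded.csv", row.names = FALSE)
message("Wrote results/single_tissue_scenarios.csv, division_events.csv, ",
        "kymograph_graded.csv")
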