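#!/usr/bin/env Rscript
# Stage 1: synthesize the study inputs for the bundled three-city scenario —
# pixel-level column observations (NO2, AOD, and HCHO with an ocean
# background), city/ocean geometries, annual burned-fraction fields, and
# demographic tables — all with known ground truth.

suppressPackageStartupMessages(library(tropicair))

cfg <- demo_config(out_dir = "results/run", seed = 1)
man <- run_pipeline(cfg, stages = "synth")
stopifnot(man$complete)

outs <- unlist(man$stages$synth$outputs)
cat("Synthesized inputs for", length(cfg$cities), "cities ->", cfg$out_dir, "\n")
for (p in outs[grepl("pixels_", outs)]) {
  n <- nrow(read_pixels_csv(p))
  cat(sprintf("  %-42s %5d pixels\n", basename(p), n))
}
demo <- read.csv(file.path(cfg$out_dir, "demographics.csv"), comment.char = "#")
cat(sprintf("Demographics: %d city-years; populations %.1fM to %.1fM\n",
            nrow(demo), min(demo$population) / 1e6, max(demo$population) / 1e6))
cat("Ground truth (alpha): NO2 +4.5%/yr with a Dec-Mar burning season;",
    "bravo: NO2 -2%/yr; charlie: 75% of months are cloud gaps.\n")
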