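#!/usr/bin/env Rscript
# Stage 4: partition each burning-influenced city's series into biomass
# burning and anthropogenic activity with the per-year 75th-percentile rule,
# trend both with Theil-Sen, and check trend directions against burned
# fraction.

suppressPackageStartupMessages(library(tropicair))

cfg <- demo_config(out_dir = "results/run", seed = 1)
man <- run_pipeline(cfg, stages = "partition")
stopifnot(man$complete)

pt <- read.csv(file.path(cfg$out_dir, "partitions.csv"), comment.char = "#")
cat("Source partitions (results/run/partitions.csv):\n")
print(pt[c("region_id", "species", "bb_influenced", "bb_rel_pct",
           "anth_rel_pct", "burned_fraction_consistency")], digits = 3)
cat("\nReading: anthropogenic (below-percentile) trends dominate when",
    "anth_rel_pct tracks the all-data trend; the burning excess is checked",
    "against the burned-fraction trend direction.\n")
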