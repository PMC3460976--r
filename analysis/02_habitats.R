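#!/usr/bin/env Rscript

# Recompute quadrat topography and the six-habitat classification from the
# elevation lattice written by 01_simulate_community.R, and summarise the
# terrain.

suppressPackageStartupMessages(library(forestspat))

grid <- read_elevation_grid("results/elevation.tsv", spacing = 20)
metrics <- compute_quadrat_metrics(grid)
cat(sprintf("elevation %.1f-%.1f m, slope %.1f-%.1f deg, convexity %+.2f-%+.2f m\n",
            min(grid$z), max(grid$z), min(metrics$slope), max(metrics$slope),
            min(metrics$convexity), max(metrics$convexity)))

# gap quadrats carry over from the generated map
gen_map <- read.table("results/habitat_map.tsv", header = TRUE, sep = "\t")
gap <- matrix(FALSE, grid$nx, grid$ny)
gap[cbind(gen_map$ix + 1, gen_map$iy + 1)] <- gen_map$category == "gap"

map <- classify_habitat(metrics, gap_mask = gap)
print(habitat_counts(map))
write_habitat_map(map, "results/habitat_map_recomputed.tsv")

stopifnot(identical(c(map$category), gen_map$category))
cat("recomputed habitat map matches the generated one\n")
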