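#!/usr/bin/env Rscript
# Step 1 — simulate the study system: four decadal environmental stacks on a
# 100 x 100 km grid, a valley-following road network, and per-period
# occurrences (714/561/322/117) drawn from a ground-truth suitability whose
# human-pressure term intensifies over time.
#
# Outputs: small tables under results/scenario/ (GeoJSON roads/polygons,
# CSV occurrences); the raster stacks and the scenario object go to
# scratch/ (large, regenerable).

library(rangerecon)

seed <- 1  # same default seed the acceptance script uses
cfg <- scenario_config(seed = seed)
sc <- simulate_scenario(cfg)

dir.create("results/scenario", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/rasters", recursive = TRUE, showWarnings = FALSE)

for (st in sc$stacks) write_stack_asc(st, "scratch/rasters")
write_geojson_roads(sc$roads, "results/scenario/roads.geojson")
write_geojson_polygons(generate_polygons(cfg, 16, "tile"),
                       "results/scenario/districts.geojson")
write_occurrences_csv(sc$occurrences, "results/scenario/occurrences.csv")
saveRDS(sc, "scratch/scenario.rds")

cat("Simulated", length(sc$stacks), "periods on a",
    cfg$grid$n_rows, "x", cfg$grid$n_cols, "grid (",
    grid_area_km2(cfg$grid), "km^2 ).\n")
cat("True cells with suitability > 0.5 per period:",
    vapply(sc$suitability, function(s) sum(s > 0.5), numeric(1)), "\n")
cat("Occurrences per period:", table(sc$occurrences$period)[cfg$periods], "\n")
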