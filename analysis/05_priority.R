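#!/usr/bin/env Rscript
# Step 5 — conservation prioritization: core-area zonation on the 2000s
# consensus probability, degraded by the 2000s condition layers
# (1 - urban, forest) and divided by the disappearance cost built from the
# four per-period binary ranges; zone reclassification (top 5% Mandatory,
# next 5% Negotiated, next 10% Partial) and district summaries.

library(rangerecon)

sc <- readRDS("scratch/scenario.rds")
pipe <- readRDS("scratch/pipeline.rds")
cfg <- sc$config

st4 <- sc$stacks[[length(sc$stacks)]]
feature <- apply_conditions(pipe$results[["2000s"]]$probability,
                            st4$layers$urban, st4$layers$forest)
cost <- build_cost(lapply(pipe$results, `[[`, "binary"))
rk <- core_area_rank(feature, cost)
zones <- reclassify(rk)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/rasters", recursive = TRUE, showWarnings = FALSE)
write_asc(rk$rank, cfg$grid, "scratch/rasters/priority_rank.asc",
          mask = !is.na(rk$rank))
zt <- table(zones)
write.csv(as.data.frame(zt), "results/zone_cells.csv", row.names = FALSE)

districts <- read_geojson_polygons("results/scenario/districts.geojson")
ps <- polygon_summary(rk, districts, cfg$grid)
write.csv(ps, "results/district_summary.csv", row.names = FALSE)

cell_km2 <- cfg$grid$cell_size^2
cat("Zone areas (km^2):\n")
print(zt * cell_km2)
cat(sprintf("Districts by level: %d priority, %d important, %d normal\n",
            sum(ps$level == "priority"), sum(ps$level == "important"),
            sum(ps$level == "normal")))
cat("Top-10% priority area:",
    sum(rk$rank > 0.9, na.rm = TRUE) * cell_km2, "km^2 of",
    grid_area_km2(cfg$grid), "\n")
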