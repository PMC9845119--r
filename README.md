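# crowncarbon

Tree-level carbon mapping from crown segmentation masks.

Deep-learning crown mappers applied to very-high-resolution aerial imagery
produce binary rasters of overstory tree crowns. Getting from those rasters
to an actionable inventory — how many trees, how much canopy, how much
carbon, and how sure are we — takes a chain of post-processing steps that
this package implements for R users working at 0.1–1 m pixel sizes:
ecologists, foresters and remote-sensing scientists building wall-to-wall
tree inventories in landscapes dominated by trees *outside* forests.

The chain:

1. **Crown separation (DCR — detect centre and relabel).** A distance
   transform of the binary mask; crown centres as pixels whose distance
   value survives an m × m maximum filter (plateaus merged); every crown
   pixel assigned to the centre minimising
   ‖x − c‖₂ + λ·B(x, c), where B counts background pixels on the Bresenham
   line from c to x and λ defaults to the grid diagonal; single-crown holes
   filled. Deterministic, and tested to be *identical* to a brute-force
   oracle.
2. **Crown geometry.** Per-crown area, crown diameter CD = 2·√(area/π),
   centroid; crowns under 0.25 m² dropped; each crown buffered by
   (√1.27 − 1)·CD/2 (the 27 % shrinkage of boundary-weighted predictions)
   and dissolved into canopy cover.
3. **Allometry by land-cover class.** Major-axis regression CD → DBH
   (linear DBH = −4.665 + 5.102·CD for trees outside natural forest; a
   logarithmic fit DBH = exp(1.154 + 1.248·ln(CD·1.27))·exp(0.3315²/2) with
   Baskerville correction for natural forest), then DBH → AGB via class
   power laws (0.091·DBH^2.472 savanna; 0.202·DBH^2.447 plantations,
   farmland, urban) or the pantropical form
   exp(1.803 − 0.976E + 0.976·ln ρ + 2.673·ln DBH − 0.0299·(ln DBH)²), and
   AGC = 0.47·AGB.
4. **Aggregation.** Tree density, canopy cover (%) and carbon density
   (MgC/ha) on half-open 100 m hectare cells.
5. **Uncertainty.** Relative and summed-total bias, area-weighted class
   bias, and a four-run half-sample ensemble rRMSE of the CD–DBH
   calibration, per land-cover class.

A synthetic-scene generator (clumped crowns with known instance labels,
calibration tables with known generating equations, land-cover layers)
makes the whole chain testable without any imagery.

## Worked example

```r
library(crowncarbon)

cfg   <- scene_config(grid_shape = c(160, 160), pixel_size = 0.25,
                      n_crowns = 25, clump_fraction = 0.5, seed = 42)
sc    <- make_scene(cfg)                  # synthetic mask + ground truth
scene <- dcr(sc$mask, m = 3)              # separate clumped crowns
scene
#> <label_scene> 160 x 160 px, 18 instance(s), penalty 226.274

trees <- extract_crowns(scene)            # area, CD, centroid per crown
head(trees, 3)
#>   tree_id n_pixels area_m2     cd_m         x        y
#> 1       1       36  2.2500 1.692569  4.020833 33.37500
#> 2       2      241 15.0625 4.379289 26.375000 32.87500
#> 3       3       48  3.0000 1.954410 24.250000 25.44792

layer <- make_landcover(c(0, 40, 0, 40), n_polygons = 4, seed = 1)
trees <- assign_class(trees, layer, default_class = "savanna_shrubland")
trees <- apply_allometry(trees, default_allometry_table(E = 0.4))
head(trees[, c("tree_id", "cd_m", "landcover", "dbh_cm", "agb_kg", "agc_kg")], 3)
#>   tree_id     cd_m         landcover    dbh_cm       agb_kg      agc_kg
#> 1       1 1.692569 savanna_shrubland  3.970486     2.750318    1.292649
#> 2       2 4.379289    natural_forest 28.513948 12471.137524 5861.434636
#> 3       3 1.954410    natural_forest 10.417734  1003.441997  471.617739

cover <- expand_crowns(scene, trees)      # 27% expansion, dissolved
grid  <- aggregate_hectares(trees, cover, grid_origin = c(0, 0),
                            cell_size = 40)
grid$cells
#>   cell_row cell_col x0 y0 n_trees density_ha cover_pct carbon_mgc_ha
#> 1        1        1  0  0      17     106.25  15.93359      47.55863
```

Reading the output: the 25 generated crowns clump into blobs that DCR
separates into 18 instances (overlapping crowns merge; one falls below the
0.25 m² minimum, leaving 17 records). Tree 1 sits in savanna, so its 1.69 m
crown maps through the linear CD–DBH line to a 4.0 cm stem and 2.75 kg of
biomass (1.3 kg carbon); tree 2 lands in natural forest and maps through
the logarithmic model and the pantropical biomass form instead. The single
40 m cell then holds 17 trees (106 trees/ha), 15.9 % expanded canopy cover,
and 47.6 MgC/ha.

The same chain is scriptable from a shell via the bundled CLI
(`inst/cli/crowncarbon.R`): `simulate`, `separate`, `crowns`, `carbon`,
`aggregate`, `uncertainty`; run any subcommand with `--help` for options.

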