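# contactq

Quantification of ER–mitochondria membrane contact sites in 2-D
electron-microscopy segmentations.

## The problem and who this is for

Electron microscopists measuring organelle contact sites trace two sets of
membranes in a cross-section: the closed mitochondrial outer membrane
(MOM) of each mitochondrion and the nearby ER membrane profiles. The
question is how much ER runs close to each mitochondrion, and how close.
`contactq` turns those traces (or label masks) into per-mitochondrion
contact metrics and cohort-level statistics.

The core computation bins ER membrane length into concentric dilation
bands of width Δ (default 1 nm) around the MOM out to NΔ (default 30 nm).
With L_i the ER length within distance iΔ and l_i = L_i − L_{i−1}:

    L      = Σ_{i=1..N} l_i                        total contact length (nm)
    D      = Δ · Σ i·l_i / Σ l_i                   band-weighted average distance (nm)
    ERMICC = L / (P × D)                           contact coefficient (1/nm)

where P is the mitochondrial perimeter. ERMICC grows with the apposed
fraction of the perimeter and shrinks with the apposition distance.

Also included: a sub-pixel marching-squares contour extractor for label
masks, an independent raster distance-transform cross-check, normalized
fluorescence line-profile analysis (per-channel peaks and a
"query-between-flanks" verdict), two-sample t-tests over pooled
per-mitochondrion tables, and a seeded synthetic-scene generator with
exact ground truth.

## Worked example

```r
library(contactq)

# synthetic two-group cohort with known ground truth
wt <- generate_scene(scene_spec(seed = 1, n_mitochondria = 43), group = "WT")
ko <- generate_scene(scene_spec(seed = 2, n_mitochondria = 62), group = "KO")
tab <- rbind(measure_scene(wt$scene)$metrics,
             measure_scene(ko$scene)$metrics)

head(tab[, c("mito_id", "P_nm", "L_nm", "D_nm", "ermicc_per_nm")], 3)
#>   mito_id     P_nm     L_nm     D_nm ermicc_per_nm
#> 1  mito_1 3092.448 1183.897 14.64852    0.02613471
#> 2  mito_2 2867.061 1374.092 16.52046    0.02901061
#> 3  mito_3 2609.947 1144.508 16.05635    0.02731116

summarize_groups(tab, "ermicc_per_nm")
#>   group  n n_missing       mean         sem
#> 1    KO 62         0 0.03032509 0.001467029
#> 2    WT 43         0 0.02975864 0.001431051

compare_groups(tab, "ermicc_per_nm", "WT", "KO")
#> Two-tailed unpaired t-test (student) on ermicc_per_nm, unit = mitochondrion
#>   WT: n = 43, mean = 0.029759 +/- 0.00143 (s.e.m.)
#>   KO: n = 62, mean = 0.030325 +/- 0.00147 (s.e.m.)
#>   t = -0.2662, df = 103, p = 0.7906
```

Per-mitochondrion rows carry the perimeter, contact length, average
distance (missing for zero-contact mitochondria, which get ERMICC = 0 and
a `zero_contact` flag) and the coefficient; the `bands` element of
`measure_scene()` holds the underlying l_i / L_i table. The two seeded
groups here come from the same scene distribution, so the test correctly
finds no difference.

Reading real data instead of synthetic scenes:

```r
sc  <- read_polyline_table("scene.csv", pixel_size_nm = 1)   # traced polylines
sc2 <- read_label_masks("mom.tif", "er.tif", pixel_size_nm = 1)  # label masks
measure_scene(sc)$metrics
```

A thin command-line front end over the same functions ships in
`inst/cli/contactq.R` (subcommands `measure`, `profile`, `compare`,
`simulate`).

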