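# kidneyscreen

Smart-microscopy screening and quantification of zebrafish pronephric
cysts, in R.

Glomerular cystogenesis in the zebrafish pronephros — the embryonic kidney,
visualised as a GFP-labelled bilateral structure in dorsally mounted
embryos — is a workhorse readout for kidney-disease compound screens in
96-well plates. The practical obstacles are that the interesting anatomy
occupies a tiny fraction of a whole-well overview, and that thousands of
resulting high-resolution z-stacks need automated triage and scoring.
kidneyscreen implements the complete workflow:

1. **Smart (feedback) acquisition** — detect the pronephros in a 4x
   pre-scan by automatic Li thresholding and intensity-weighted centre of
   mass, convert to stage coordinates, and emit a job script
   (`GOTO` / `AUTOFOCUS` / `SET_CHANNEL` / `STACK`) that drives a 10x,
   two-channel, 30-slice (dZ = 4 µm) re-acquisition centred on the organ.
   A folder-watch loop dispatches new images exactly once; a mock
   microscope executes jobs against synthetic scenes.
2. **Preprocessing** — best-focus detection (variance of Laplacian),
   7-slice sub-stack, 3×3 median denoising, maximum projection, centred
   512×512 crop and a glomerular recrop (height/1.6 → 512×320), then a Li
   mask.
3. **Quality control** — blurred wells by background-subtracted intensity
   variance (published rule: variance < 400), blank wells by
   Laplacian-response variance (published rule: variance > 124), with a
   calibration sweep (`calibrate_qc()`) because absolute variance
   thresholds are instrument-specific.
4. **Phenotype classification** — two independent heuristics must agree:
   a zero-run test on the horizontal intensity profile of the organ ROI
   (a cystic lumen interrupts the GFP signal), confirmed by best-fit
   particle ellipses (major axis > 299 px ⇒ intact wild-type structure);
   disagreement is reported as *ambiguous*.
5. **Quantification** — pronephric area from filtered mask particles;
   cystic area as the background particles enclosed by the convex hull of
   the tissue, kept when particle number ≤ 10 and Feret diameter ≥ 70 px;
   total kidney area = pronephric (wild-type) or pronephric + cystic
   (cystic); per-plate CSV, 8×12 matrix and heatmap.

Every stage is exercised against a bundled **synthetic plate generator**
with exact ground truth (per-well phenotype, centroid, lobe and lumen
pixel masks), so the whole pipeline is testable without any instrument
data.

## Worked example

Simulate, acquire, QC, classify and measure an 8-well plate:

```r
library(kidneyscreen)

cfg <- build_config(list(prescan_camera_px = 512L, rescan_camera_px = 512L,
                         n_z = 7L, qc_calibration_n = 8L, seed = 7L))
res <- run_pipeline("demo", cfg, n_wells = 8L)
str(res$counts)
res$measurements[, c("well", "label", "pronephric_area_um2",
                     "cystic_area_um2", "total_kidney_area_um2")]
```

```
List of 11
 $ wells_simulated    : int 8
 $ wells_detected     : int 6
 $ wells_blank_prescan: int 2
 $ wells_processed    : int 6
 $ qc_ok              : int 6
 $ qc_blurred         : int 0
 $ qc_blank           : int 0
 $ wildtype           : int 5
 $ cystic             : int 1
 $ ambiguous          : int 0
 $ measured           : int 6

 well    label pronephric_area_um2 cystic_area_um2 total_kidney_area_um2
  A02 wildtype            18246.51           0.000              18246.51
  A03 wildtype            20151.14           0.000              20151.14
  A04 wildtype            19545.27           0.000              19545.27
  A05 wildtype            17924.14           0.000              17924.14
  A06   cystic            15826.85        3016.228              18843.08
  A07 wildtype            19305.72           0.000              19305.72
```

Two wells were empty and produced no re-acquisition job; the six embryos
passed QC; well A06 carries a cyst whose dark lumen measures ~3000 µm²,
and its total kidney area is the sum of tissue and lumen. The scene's
ground truth (written to `demo/prescan/truth.csv`) has exactly this
composition. `demo/report/plate_heatmap.png` shows the plate matrix;
every CSV artifact names the hash of the configuration that produced it.

The same stages are available individually (`generate_plate()`,
`smart_acquire_plate()`, `process_plate()`, `qc_plate()`,
`classify_plate()`, `measure_well()`, `plate_summary()`) and as a command
line:

```sh
Rscript inst/cli/kidneyscreen.R pipeline --out demo --seed 7 --wells 8 \
    --set prescan_camera_px=512 --set rescan_camera_px=512 --set n_z=7
```

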