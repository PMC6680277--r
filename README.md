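# xrh — 3D X-ray histology of paraffin-embedded tissue blocks

`xrh` is an R toolkit for *3D X-ray histology*: contrast-agent-free
micro-computed tomography (μCT) of standard formalin-fixed, paraffin-embedded
(FFPE) tissue blocks, integrated with the conventional 2D histology workflow.
A μCT scan of an unstained FFPE block shows three gray-value populations —
air < paraffin wax < tissue — and that is enough to calibrate scans against a
wax standard, quantify the 3D tissue architecture, render it, and coregister
ordinary histology slides with the volume they were cut from.

The package covers the full processing chain downstream of CT reconstruction:

- **volume I/O** — headerless raw volumes with JSON sidecars, multi-page
  16-bit TIFF stacks, voxel-size metadata, a fixed `[z][y][x]` indexing
  convention (the XY plane is the plane parallel to the histology cassette);
- **preprocessing** — 3D median filter, per-slice 2D unsharp mask, linear
  windowing (default gray window (−50, 100)) to unsigned 16-bit;
- **calibration** — phantom-based gray-value normalization. For each scan the
  mean gray values of wax and air give the contrast factor
  `Cf = (I_wax − I_air) / I_wax` and two scans are aligned by the calibration
  factor `f = Cf_phantom / Cf_sample`; the sample is multiplied by `f` and
  linearly offset so the mean gray value of air is 0 (the paraffin analogue of
  the Hounsfield convention — all calibrated grays are positive). A stability
  report summarizes wax/tissue gray-value fluctuation across specimens;
- **morphometry** — absolute-threshold segmentation inside a volume of
  interest, local thickness by maximal inscribed spheres (the
  Hildebrand–Rüegsegger definition: at each point, the diameter of the
  largest sphere containing it that fits in the structure), volume-weighted
  thickness statistics, tissue volume fraction (the soft-tissue analogue of
  BV/TV), and physical/virtual section-count arithmetic;
- **rendering** — maximum intensity projections (axis-aligned, oblique, and
  rotating sequences), orthogonal multiplanar views, and oblique reslicing
  with bicubic interpolation;
- **registration** — plane fitting to ≥3 paired 2D/3D landmarks,
  best-matching virtual slice extraction, and elastic 2D warping of the
  histology slide onto the CT slice with a landmark-interpolating thin-plate
  spline;
- **phantoms** — synthetic generators (calibration cylinder, geometric
  primitives with analytic thickness, foam-like parenchyma with exact volume
  fraction, histology/CT pairs with a known deformation field) so the whole
  pipeline runs and is tested without scanner data.

## Worked example

Two foam phantoms emulate a control lung biopsy (33% tissue, fine parenchyma)
and a fibrotic one (60% tissue, coarse architecture) at the protocol voxel
size of 8.48 μm:

```r
library(xrh)
ph_spec <- phantom_spec(shape = c(48L, 48L, 48L), voxel_size_um = 8.48, seed = 1)
control <- make_foam_phantom(ph_spec, target_vf = 0.33, feature_scale_um = 34)
ipf     <- make_foam_phantom(ph_spec, target_vf = 0.60, feature_scale_um = 85)
for (nm in c("control", "ipf")) {
  f <- get(nm)
  rep <- morphometry_report(segment_tissue(f$volume, threshold = 35000))
  cat(sprintf("%-8s VF %.3f (truth %.3f)  mean thickness %.1f um (SD %.1f)\n",
      nm, rep$volume_fraction, f$ground_truth$true_volume_fraction,
      rep$mean_thickness_um, rep$sd_thickness_um))
}
```

```
control  VF 0.330 (truth 0.330)  mean thickness 34.2 um (SD 14.0)
ipf      VF 0.600 (truth 0.600)  mean thickness 114.0 um (SD 35.5)
```

The segmentation recovers both design volume fractions exactly, and the
fibrotic-like foam is built of markedly thicker elements — the same
separation the method shows between control and IPF specimens. Section-count
arithmetic for a 1 mm deep block:

```r
section_counts(1000, 4, 8.48)
#> $n_physical [1] 250    # 4 um microtome sections to exhaustion
#> $n_virtual  [1] 117    # virtual sections, one per 8.48 um voxel layer
```

`run_pipeline(run_config(seed = 1), "run1")` executes the whole chain on a
simulated raw-scale FFPE block (simulate → preprocess → calibrate → quantify
→ render) and writes the volumes, a `report.json`, and an MD5 manifest into
the run directory; with the default configuration the recovered calibration
factor is 1.002 and the air offset 26202 (the windowed air level), against a
ground-truth volume fraction of 0.330.

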