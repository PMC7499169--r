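# plaquant

Automated, repeatable quantification of dental plaque from photographs of
fluorescein-dyed dentition taken under ultraviolet light.

Dental plaque is the bacterial biofilm behind caries and periodontal
disease, and traditional chairside plaque indices are ordinal, subjective
and laborious. After fluorescein disclosure, plaque fluoresces **green**
under UV while clean enamel fluoresces **bright blue**, so the signed
per-pixel channel difference `G − B` carries the whole contrast. plaquant
implements the full planimetric pipeline on top of that observation:

1. **Dental-area segmentation.** The `B + R` channel sum is thresholded at
   its 75% quantile (the darkest three quarters of pixels are background),
   near-white specular artifacts and isolated pixels are removed, and
   8-connected components are kept only if they exceed 2000 pixels and
   solidity 0.5 — which excludes gingiva, lips and background.
2. **Pixel classification.** Each dental pixel is labeled
   - `VISIBLE` plaque if `G − B > 0`;
   - level-1 non-visible plaque `NV1` (risk of becoming plaque within
     hours) if `δ ≤ G − B ≤ 0`;
   - level-2 non-visible plaque `NV2` (risk within days) if
     `l ≤ G − B < δ`;
   - `NONPLAQUE` if `G − B < l` (or if `G = 0` or `B = 0`).

   `δ` defaults to `−|mean(B) − mean(G)|` over the dental area; `l` is the
   first value (scanning from −255 up) where the current moment's
   non-visible-plaque histogram exceeds the reference moment's.
3. **Clinical indices.** Per-class area percentages; the **API index**
   `(visible fraction) × (mean visible G−B / 255) × 100` on a 0–100 scale
   (the product form is a documented reconstruction — simplest formula
   bounded to [0,100] and monotone in both extent and intensity); the
   **area growth index** in % of dental area per hour relative to the
   patient's *reference moment* (baseline after professional cleaning);
   and the **area time index**, the extrapolated days to 100% coverage at
   constant rate, `(100 − area) / rate / 24`.

A synthetic scene generator renders UV-like dentitions (blue teeth, green
plaque patches with controllable `G − B` distributions, reddish gingiva,
specular artifacts) with ground-truth masks and programmable temporal
growth, so the entire pipeline is testable without clinical images.

## Worked example

Simulate a 96-hour plaque-regrowth experiment (moments every 24 h,
programmed visible growth 0.75 %/h) and process it end to end:

```r
library(plaquant)

dir <- tempfile()
cfg <- write_synthetic_experiment(
  dir, scene_spec(seed = 7), rate = 0.75,
  timestamps = as.POSIXct("2020-03-02 09:00:00", tz = "UTC") +
    c(0, 24, 48, 72, 96) * 3600)

run <- run_experiment(cfg, out_dir = file.path(dir, "out"))
summary(run)
```

```
Plaque measurements (5 image(s), 1 patient(s)):

 patient_id moment_label elapsed_hours visible_percent nv1_percent nv2_percent
  synthetic           M0            NA            0.00     52.2754       0.000
  synthetic           M1            24           18.01      0.4759      81.519
  synthetic           M2            48           35.99      0.0000      10.272
  synthetic           M3            72           54.00      0.0000       4.080
  synthetic           M4            96           72.00      0.0000       2.057
 api_index growth_index_visible area_time_visible
     0.000                   NA                NA
     3.704               0.7502             4.554
     7.421               0.7498             3.557
    11.112               0.7499             2.556
    14.829               0.7500             1.555
```

Reading the output: visible plaque climbs 18 → 72% of the dental area,
exactly tracking the programmed 0.75 %/h; the recovered growth index is
0.750 ± 0.0003 at every moment. The API index grows with both plaque
extent and stain intensity. At 96 h the patient would need ~1.56 more
days at this rate to reach full visible coverage (`area_time_visible`).
The reference row (M0) has no relative indices by definition. The output
directory holds, per image, the dental-mask PNG, a labeled PNG (green
visible / red NV1 / orange NV2 / blue non-plaque), the G−B histogram as
CSV and plot, class pie/bar charts, plus a combined `measurements.csv`
and a `manifest.json` recording every auto-resolved δ and l.

A shell front end wraps the same functions:

```sh
inst/cli/plaquant synth /tmp/exp --seed 4
inst/cli/plaquant run /tmp/exp/experiment.yaml --out /tmp/exp/out
inst/cli/plaquant segment /tmp/exp/synthetic_m0.png
```

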