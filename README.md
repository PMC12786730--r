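# evocquant

Quantitative immunohistochemistry (IHC) morphometry and viability scoring
for tumor **ex vivo organ cultures (EVOC)**.

EVOC keeps intact tumor fragments alive at an air–liquid interface, so
drug response and tissue viability can be read out on the native tumor
architecture. The readout is immunohistochemical: serial sections stained
for a tumor marker (e.g. PLAP for seminoma) and the proliferation marker
Ki-67 are digitized, nuclei are detected and classified as DAB-positive,
and counts are followed over culture days (typically 0, 3, 7, 10).
`evocquant` implements that whole analysis as a tested, scriptable R
pipeline, for pathologists and quantitative biologists who want the
numbers — not a GUI session — to be reproducible.

## What it computes

**Stain separation.** Brightfield RGB is converted to optical density
(Beer–Lambert, base 10), `OD_c = log10(I0 / max(I_c, 1))`, and unmixed into
hematoxylin / DAB / residual concentrations by solving `od = M c` per pixel
with the standard Ruifrok–Johnson H-DAB stain matrix (overridable in
config).

**Nucleus detection.** On the hematoxylin channel: Gaussian smoothing
(σ = 1 µm) → h-maxima markers whose OD prominence exceeds the nucleus
splitting threshold (0.15) → marker-based watershed → size gate on the
equivalent circular radius (5–10 µm) → per-nucleus mean ODs. A nucleus is
**positive** when its mean nuclear DAB OD exceeds 0.15 (strictly).
Detection runs at 0.5 µm/pixel by default and is fully deterministic.

**Morphometry.** Detections restricted to the pathologist's tumor ROI
(GeoJSON polygons, even-odd rule, boundary = inside) yield, per sample and
day: OCN (all nuclei), TCN (PLAP-positive), stromal (OCN − TCN) and the
proliferation index `PI = 100 · Ki67⁺/OCN` (%). Cohort summaries report
per-day mean ± SD with t-based 95% CIs and the per-sample percent decrease
`100 · (x₀ − x_d)/x₀` as median [IQR].

**Viability.** The trapezoidal AUC of any time course,
`Σ (d_{i+1} − d_i)(v_i + v_{i+1})/2`, and the **EVOC score** between two
culture arms of one tumor:

```
EVOC score = AUC(control PI curve) / AUC(experimental PI curve)
```

scores > 1 mean lower proliferative viability in the experimental arm.

**Longitudinal statistics.** Per-day Shapiro–Wilk screening; one-way
repeated-measures ANOVA with Mauchly's sphericity test,
Greenhouse–Geisser and Huynh–Feldt epsilons (HF correction applied when
Mauchly p < 0.05) and partial η²; Bonferroni-adjusted paired t or Tukey HSD
post hocs with Cohen's dz; Friedman rank test as the non-parametric
sensitivity analysis.

**Synthetic data.** `simulate_ihc_tile()` renders ground-truthed H-DAB
tiles through the forward Beer–Lambert model; `simulate_cohort()` /
`simulate_quantity_cohort()` generate 12-patient longitudinal cohorts
calibrated to published per-day means/SDs. Every generator is
seed-deterministic, which is what the test suite validates the pipeline
against.

## Worked example

```r
library(evocquant)

## 1. render a ground-truthed synthetic H-DAB tile and quantify it
spec <- image_sim_spec(n_nuclei = 40, positive_fraction = 0.5, seed = 42)
tile <- simulate_ihc_tile(spec)
channels <- unmix(rgb_to_od(tile$rgb, pixel_size_um = tile$pixel_size_um))
nuclei <- detect_nuclei(channels, detection_params(), marker = "Ki67")
ground_truth_compare(nuclei, tile$truth, match_radius_um = 3)
#> detected 40 / 40 nuclei, F1 = 1.000, positivity agreement = 1.000
count_cells(nuclei, "Ki67", sample_id = "S01", day = 0)
#>   ocn positive_count pi_percent
#> 1  40             20         50

## 2. a PI curve -> AUC and EVOC score
days <- c(0, 3, 7, 10)
pi_ctrl <- c(89.47, 88.05, 68.002, 43.886)   # % Ki-67-positive per day
trapezoid_auc(days, pi_ctrl)
#> control PI AUC: 746.216 %*day
evoc_score(trajectory_series("ctrl", "PI", days, pi_ctrl),
           trajectory_series("expt", "PI", days, 0.75 * pi_ctrl))
#> EVOC score: 1.3333 (control AUC 746.22 / experimental AUC 559.66)
#>   score > 1 indicates lower proliferative viability in the experimental arm

## 3. simulated 12-patient cohort -> summary + RM-ANOVA
rec <- simulate_cohort(cohort_sim_spec(seed = 1))$records
m <- quantity_matrix(rec, "OCN")
summarize_cohort(m, "OCN")
#> Percent decrease vs baseline (median [IQR]):
#>  day  n median_pct_decrease iqr_low iqr_high
#>    3 12                12.8     8.4     16.9
#>    7 12                30.2    25.8     35.9
#>   10 12                54.8    53.1     55.8
rm_anova(m)
#> Repeated-measures ANOVA (n = 12, k = 4)
#>   F(3, 33) = 200.8455, p = 2.908e-21 (uncorrected)
#>   Mauchly W = 0.4749 (p = 0.2034); eps_GG = 0.6659, eps_HF = 0.8135
#>   sphericity not rejected; corrected p = uncorrected p
#>   partial eta^2 = 0.9481
```

The PI AUC of 746.216 %·day is three trapezoids summed by hand:
`3·(89.47+88.05)/2 + 4·(88.05+68.002)/2 + 3·(68.002+43.886)/2`. The
interpretation of the cohort block: total cellularity holds near baseline
through day 3, then drops by roughly a third at day 7 and over half by
day 10, with an overwhelming time effect (η² ≈ 0.95).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/evocquant.R", package="evocquant"))')
Rscript $CLI simulate-tiles  --n-tiles 5 --seed 1 --out tiles/
Rscript $CLI quantify        --images tiles/images.csv --out quant/
Rscript $CLI simulate-cohort --seed 1 --out cohort/
Rscript $CLI report          --counts cohort/counts.csv --out report/
Rscript $CLI score           --control a/counts.csv --experimental b/counts.csv --out score/
```

Global flags: `--config cfg.json|cfg.yml` (schema in
`inst/schema/config-schema.json`; unknown keys rejected), `--seed`,
`--out`, `--log-level`. All detection parameters live under `detection:`
with the defaults listed above.

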