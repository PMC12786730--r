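---
title: "Methods: IHC quantification and viability scoring for EVOC experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC quantification and viability scoring for EVOC experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evocquant)
```

## The measurement model

An EVOC (ex vivo organ culture) experiment keeps intact tumor fragments at
an air–liquid interface and asks how viable the tissue stays over culture
days (here the schedule 0, 3, 7, 10). The readout is brightfield IHC with
a brown DAB chromogen over a blue hematoxylin counterstain. Everything
downstream rests on one physical assumption: **stains mix additively in
optical density**. A pixel's OD per channel is

$$\mathrm{OD}_c = \log_{10}\!\frac{I_0}{\max(I_c, 1)},$$

and for stain concentrations $c_H, c_{DAB}, c_{res}$ with unit-norm stain
OD vectors as the columns of $M$, $\mathrm{od} = M\,c$. Unmixing solves
this 3×3 system per pixel. The package uses the Ruifrok–Johnson H-DAB
vectors — hematoxylin $(0.651, 0.701, 0.290)$, DAB $(0.269, 0.568,
0.778)$, each renormalized — because they are the de facto standard
shipped by mainstream digital-pathology software; the true vectors of any
given scanner/stain lot differ in the third decimal, so the matrix is
overridable in the config. The residual vector is the normalized cross
product of the other two: orthogonal by construction, it collects whatever
the two dyes cannot explain.

Two numerical choices here are worth stating. The intensity floor
$\max(I,1)$ caps OD at $\log_{10} 255 \approx 2.41$ for 8-bit input, so
fully opaque pixels stay finite. And unmixed concentrations are **clipped
at zero**: they are physical quantities, and noise that pushes a pixel
outside the stain simplex should not produce negative chromogen.

A consequence the tests make explicit: **8 bits cannot represent high
ODs**. At concentrations $a = b = 3$ the green-channel OD is 3.8, which
renders to intensity 0 and inverts to 2.41 — a concentration error of
order 1. The exact (unquantized) render→unmix round trip is verified to
1e-9 over $[0,3]^2$; the quantized round trip is verified to 0.02 over the
OD range the synthetic tiles actually plant (hematoxylin ≈ 0.8, DAB ≈
0.02–0.4), where 8-bit quantization leaves ample headroom. No tolerance
can rescue the dark corner; it is a property of the medium, not of the
algorithm.

## Nucleus detection

Detection reproduces the semantics of the positive-cell-detection approach
standard in digital pathology, with these parameters (config block
`detection:`):

| parameter | default | unit | meaning |
|---|---|---|---|
| `pixel_size_um` | 0.5 | µm/px | analysis resolution |
| `min_radius_um`, `max_radius_um` | 5, 10 | µm | size gate on the *equivalent circular radius* (area gate ≈ 78.5–314 µm²) |
| `splitting_threshold` | 0.15 | OD | minimum hematoxylin prominence separating two nuclei |
| `cell_expansion_um` | 3 | µm | outward expansion defining the cell territory |
| `dab_od_threshold` | 0.15 | OD | positivity cut on mean nuclear DAB (strict `>`) |
| `smoothing_sigma_um` | 1.0 | µm | Gaussian sigma for marker finding |
| `h_od_threshold` | 0.1 | OD | hematoxylin foreground threshold |

The first six are the published protocol values for seminoma H-DAB slides;
the last two are unstated in any protocol we know of and had to be chosen
to make detection runnable — they are exposed in config so users can match
their staining intensity.

The pipeline: smooth the hematoxylin map; take as markers the **h-maxima**
with prominence above the splitting threshold (computed by grayscale
reconstruction — this is the operational meaning we give "nucleus
splitting threshold 0.15", which no protocol defines algorithmically);
run a marker-based watershed on the negated smoothed map; measure each
region on the **raw** (unsmoothed) foreground mask; gate by equivalent
radius; order by centroid (y, x).

One deliberate deviation from the naive "smooth → threshold" order: the
foreground support is thresholded on the raw map, while the smoothed map
drives markers and watershed only. Thresholding the *smoothed* map at the
fixed 0.1 OD foreground cut would push the apparent boundary of an OD-0.8
nucleus ~1.1 µm outward (the blurred edge crosses 0.1 far from the true
edge), biasing every radius and area; measured on the raw mask, recovered
radii sit within ±0.03 µm of ground truth on noiseless disks. Positivity
is measured on the nuclear mask only — not the expanded cell — and the
threshold is strict ("exceeding"), so a nucleus at exactly 0.15 is
negative. Cell territories come from nearest-nucleus expansion capped at 3
µm, which keeps territories disjoint with the boundary equidistant between
neighbors.

Coordinates are micrometres from the tile's top-left corner, 0-based
pixel indices, pixel-centre convention (`um = index × pixel_size`).

## Morphometry and cohort summaries

Counting is restricted to the pathologist's tumor ROI (GeoJSON polygons;
even-odd rule; a centroid exactly on the boundary counts as inside — a
documented tie-break, not a claim about pathology). Per section: OCN =
all nuclei in the ROI; for PLAP sections TCN = positive nuclei and stromal
= OCN − TCN; for Ki-67 sections PI = 100·positive/OCN (%), left null (not
zero) when OCN = 0. Counting is whole-ROI, not field-based: the digital
analysis this package reproduces counts every tumor nucleus, which is also
why its baseline PI runs higher than field-sampled manual estimates.

Cohort summaries give per-day mean, SD (n−1) and t-based 95% CI, and — per
sample, against that sample's own baseline — the percent decrease
$100(x_0 - x_d)/x_0$, reported as cohort median with IQR. Quartiles use
linear interpolation between order statistics (R type 7); samples with
non-positive baselines are excluded with a warning. Median-of-per-sample
ratios is the only reading of "median decrease with IQR across n = 12"
that is internally consistent, and it is what the acceptance report
recomputes.

## AUC and the EVOC score

Each quantity's time course is summarized by the trapezoidal AUC,
$\sum_i (d_{i+1}-d_i)(v_i+v_{i+1})/2$, in value-units × days (%·day for
PI). The trapezoid rule is exact on piecewise-linear curves and
second-order on smooth ones; both properties are tested against a fine
Riemann oracle. The EVOC score for two arms cultured from the same tumor
is the ratio of control to experimental PI AUC; > 1 means the
experimental condition suppressed proliferation. Day grids must match
exactly — the package refuses to interpolate across missing days, because
silently manufacturing a day-7 value would fabricate exactly the data the
score is supposed to measure. Whether the score should be inverted when a
treatment *increases* PI is genuinely open; we keep the stated orientation
and record it in the output metadata.

## Longitudinal statistics

For each quantity the battery is: Shapiro–Wilk per day (delegated to
`stats::shapiro.test`; a screen, not a contribution — zero-variance
columns are flagged degenerate rather than erroring); one-way
repeated-measures ANOVA from the classical within-subject decomposition
$SS_{total} = SS_{subject} + SS_{time} + SS_{error}$ with
$F = MS_{time}/MS_{error}$ on $(k-1), (n-1)(k-1)$ df; Mauchly's W with the
first-order chi-square approximation; Greenhouse–Geisser ε from the
double-centered covariance; Huynh–Feldt
$\varepsilon_{HF} = \min\{1, [n(k-1)\varepsilon_{GG} - 2] / [(k-1)(n-1-(k-1)\varepsilon_{GG})]\}$,
floored at $\varepsilon_{GG}$ and capped at 1; partial
$\eta_p^2 = SS_{time}/(SS_{time}+SS_{error})$. The HF correction rescales
the F df **only when Mauchly p < 0.05** (threshold configurable),
otherwise the uncorrected p is reported as corrected. For $k = 2$
sphericity is trivial and F equals the squared paired t — an identity the
tests assert to 1e-10. Zero error variance yields an explicitly flagged
infinite F, never a silent NaN.

Post hoc contrasts cover all $k(k-1)/2$ pairs. The default is
Bonferroni-adjusted paired t (p × number of pairs, capped at 1) because it
is exact under the paired design and deterministic to specify; Tukey HSD —
studentized range on the RM error term — is available by flag, since
published protocols name both "as applicable" without a rule. Effect size
is Cohen's $d_z = \bar d / s_d$, flagged undefined when $s_d = 0$. The
Friedman statistic uses within-subject mid-ranks and the classical
no-tie-correction formula $\chi^2 = \frac{12}{nk(k+1)}\sum_j R_j^2 -
3n(k+1)$ on $k-1$ df, so it matches `stats::friedman.test` exactly on
tie-free data and is conservative under heavy ties.

Printed p-values from any particular study are *not* bit-reproduction
targets: the post hoc method behind each published p is unstated, so the
tests assert calibration (type-I error within [0.03, 0.07] uncorrected at
n = 12, k = 4) and power at the published effect sizes, not specific
digits.

## What the synthetic generators emulate — and what they do not

**Tiles.** Disk nuclei with uniform per-nucleus stain ODs, placed by
seeded rejection sampling with a minimum centre separation (default 24
µm), mixed through the forward Beer–Lambert model, perturbed by Gaussian
OD noise (default sd 0.02), rendered to 8-bit. Defaults: 512×512 px at 0.5
µm/px, 40 nuclei, radii uniform in the 5–10 µm detection gate, hematoxylin
OD 0.8 ± 0.05, DAB 0.4 ± 0.05 in positives vs 0.02 in negatives, 50%
positive (count = round-half-even of fraction × n). These are chosen once
to represent a moderately dense, well-stained seminoma field. Not
emulated: stromal texture, necrosis, lymphocytes, elliptical or
overlapping nuclei, uneven illumination, scanner noise correlation. A
green detection test therefore establishes that the detector recovers the
*stated* geometry–stain model (including under OD noise and at the size
gate), not that it matches a human annotator on real tissue.

**Cohorts.** The structural generator draws a truncated-normal baseline
OCN (47,595 ± 3,618 cells), splits it into tumor (fraction 0.853) and
stromal compartments, and declines each by its per-day survival fraction —
the ratios of the published per-day means (tumor: 1, 0.93, 0.72, 0.47;
stromal: 1, 0.70, 0.45, 0.41). PI is drawn per day from a
[0,100]-truncated normal around (89.47, 88.05, 68.0, 43.9)% with the
published per-day SDs; truncation slightly biases means, which is why
calibration checks run at 2%. Two noise layers are deliberate modeling
choices the source data do not determine: a **shared per-sample lognormal
effect** (sdlog 0.05) inducing the within-subject correlation a
repeated-measures design needs, and an independent **per-(sample, day)
lognormal measurement factor** (sdlog 0.08, ~ the published count CVs) —
without the latter, a no-decline cohort would have exactly zero error
variance and every null test would be degenerate. Counts stay real-valued
(expected counts); rounding would break the exact-scaling identities the
tests assert. The published day-0 row is internally inconsistent (OCN ≠
TCN + stromal by ~1,000 cells); the generator keeps the printed OCN and
tumor fraction and lets day-0 stromal follow, while the acceptance report
sidesteps the issue by calibrating each quantity directly to its own
printed per-day means/SDs.

## Determinism and degenerate inputs

Every generator takes a seed and restores the caller's RNG state; same
seed, same bytes — the acceptance suite runs simulate → quantify → report
twice and compares output files byte-for-byte (manifests are excluded:
they record wall-clock timings). Detection has no randomness at all; ties
in the watershed flood and territory expansion resolve by insertion order
and lower label, respectively. Degenerate inputs have defined behavior:
empty tiles give empty tables, OCN = 0 gives null PI with an error flag,
empty ROIs error distinctly from "no nuclei inside", fewer than two time
points skip AUC/statistics with a notice, and zero-variance columns are
flagged rather than propagated as NaN.

## Environment-driven substitutions

The deployment environment has no R readers for TIFF/PNG or YAML, so the
package ships a minimal uncompressed baseline-TIFF reader/writer (pixel
size encoded in the resolution tags) and a small YAML-subset parser next
to first-class JSON config support; the config schema is published as
JSON-Schema in `inst/schema/`. PNG and compressed TIFF are out of scope.

## Known limitations

No blind stain-vector estimation; tiles only (no pyramidal whole-slide
I/O); no machine-learned segmentation and no resolution of heavily
overlapping nuclei beyond watershed; no mixed-effects or between-group
models; no hot-spot/field-based counting. The EVOC score is a summary
ratio — it inherits every caveat of its inputs, is sensitive to baseline
PI differences between arms, and says nothing about the *shape* of the PI
curve, which can differ between arms with equal AUCs.
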