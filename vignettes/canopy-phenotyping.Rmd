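---
title: "Canopy dynamics phenotyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy dynamics phenotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopydyn)
```

# The measurement problem

Plants screened for drought tolerance indoors are usually grown one per
pot, so image analysis can delineate individuals. Populations sown at
field-like density form a closed canopy in which leaves overlap and
single-plant projections cannot be extracted. `canopydyn` implements a
population-level alternative: the **projected canopy height**, read from a
side-view RGB image of a tray holding two containers (a well-watered
variant W and a water-stressed variant D) of densely sown seedlings.
Because canopy height integrates both growth and leaf turgor, its daily
kinetics track the onset of water deficit, the decline under stress, and
the regrowth after rewatering.

# The line-descent height estimate

The green canopy is first segmented from the image. The default
segmentation computes the excess-green index

$$\mathrm{ExG} = 2G - R - B$$

and thresholds it with Otsu's method; a fixed index threshold is
available when illumination is controlled and exact reproducibility
across runs matters more than adaptivity. The index-plus-Otsu default was
chosen because it is the standard parameter-light construction of a
"green mask" and requires no color calibration; whether segmentation is
done in RGB, HSV, or an index space is an open choice, and both exposed
options are defensible — neither is claimed to match any particular
legacy routine bit for bit. Small connected components (8-connectivity,
so thin diagonal grass blades stay whole) below `min_component_px`
(default 12 px) are erased before measuring.

The mask is split into per-container masks at the layout's vertical
line. Column ranges are half-open, `[c0, c1)`, so a pixel exactly on the
right container's first column belongs to the right container
unambiguously. Rows are 1-based with row 1 at the image top.

A horizontal line is then placed one row above the topmost mask pixel of
the container and lowered one pixel per step. At each row the criterion

$$\mathrm{crit} = A/B$$

is evaluated, where $A$ is the number of mask pixels on the line inside
the container ROI and $B$ is the ROI width in pixels — the fraction of
the line intersecting the canopy. The descent stops at the first row with
$\mathrm{crit} > \tau$ (strict inequality; a row exactly at the threshold
continues the descent), and the height is the distance from that row to
the soil reference row. $B$ is the container width, not the full image
width, because the criterion is evaluated per container after the split.
The threshold $\tau$ is user-defined; the package default is 0.2, i.e.
the canopy top is where a fifth of the container width is vegetation. If
no row down to the soil row exceeds $\tau$ the result is a zero height
flagged `threshold_never_exceeded`; a container with no vegetation at all
raises a distinct `no_plant` condition, which the tray-level driver
converts to a flagged row so one empty container never aborts the other.

Heights are reported in pixels relative to a configurable `soil_row`
rather than the image bottom, since pots occupy the lower image region;
no physical (mm) calibration is provided because none is defined for the
setup. Sub-pixel estimation and lens-distortion correction are out of
scope.

# Drought and recovery kinetics

Per-container heights over days form growth curves. The **separation
day** — the first day the W and D curves diverge — is detected by one of
two rules, recorded in the output: with replicated trays, a per-day
Kruskal–Wallis test at $\alpha = 0.05$; without replicates, a relative
gap rule $(W - D)/W > \delta$ with $\delta = 0.10$ by default. Two rules
are provided because curve separation is inherently a judgment call; a
reproducible pipeline must state which rule stood in for it.

From the stressed curve the package extracts: **Max**, the height at
separation (maximum over `[separation_day, decline onset]`); **Min**, the
minimum over the stress window; **Slope**, the OLS decline rate in
px/day over `[decline onset, rewater_day]`; **MaxR**, the maximum after
rewatering; and **SlopeR**, the OLS recovery rate over
`(rewater_day, end_day]`. The decline onset is the first day in the
stress window with a negative first-difference, falling back to the
separation day for non-declining curves — separation can precede the
actual drop by a day or two, and fitting from the onset avoids diluting
the decline slope with the plateau. All fits report $R^2$ (squared
Pearson correlation) and the two-sided slope-test p-value; window bounds
are echoed in the output so every regression is reproducible. Nonlinear
growth models are deliberately out of scope: the traits are defined on
linear model curves.

# Fluorescence quenching yields

From a quenching protocol's fluorescence levels ($F_0$, $F_M$ dark
adapted; $F_t$, $F_M'$ light adapted) the package computes

* $\Phi_{Po} = (F_M - F_0)/F_M$ (dark-adapted maximum PSII yield),
* $\Phi_{PSII} = (F_M' - F_0')/F_M'$,
* $qP = (F_M' - F_t)/(F_M' - F_0')$ (fraction of open PSII centers),
* $\Phi_P = qP\,\Phi_{PSII} = (F_M' - F_t)/F_M'$,
* $\Phi_{f,D} = F_t/F_M$ (constitutive dissipation),
* $\Phi_{NPQ} = F_t/F_M' - F_t/F_M$ (regulatory quenching).

These definitions are the standard quenching-analysis partition and are
adopted precisely because they satisfy
$\Phi_P + \Phi_{NPQ} + \Phi_{f,D} = 1$ exactly, by construction — the
identity every valid trace must obey. When $F_0'$ is not measured it is
estimated by the Oxborough–Baker relation
$F_0' = F_0 / (F_v/F_M + F_0/F_M')$, and the provenance
(measured/estimated) is carried in the output. Per-pixel yields over a
mask are aggregated as the arithmetic mean of pixel yields (which
preserves the partition identity), not as yields of mean fluorescence;
the alternative is exposed as an option because both conventions exist in
imaging-fluorometry practice.

# Scalar physiology

* Relative water content: $\mathrm{RWC}(\%) = 100\,(FW - DW)/(TW - DW)$.
  Out-of-range values are flagged, not rejected — weighing error happens.
* Substrate status: gravimetric water content
  $\theta_g = (\mathrm{current} - \mathrm{dry})/\mathrm{dry}$ (the
  standard per-dry-mass convention, adopted here explicitly) and field
  capacity $\% = 100\,(\mathrm{current} - \mathrm{dry})/(\mathrm{sat} -
  \mathrm{dry})$.
* Enzyme activities via Beer–Lambert: rate
  $= \Delta A_{min} / (\varepsilon \ell)$, scaled by reaction volume and
  divided by the protein mass of the extract aliquot. Default extinction
  coefficients: catalase 38 M⁻¹cm⁻¹, ascorbate peroxidase 2.8 mM⁻¹cm⁻¹,
  guaiacol peroxidase 26.6 mM⁻¹cm⁻¹; the cuvette path defaults to 1 cm
  and is configurable. Because per-minute and per-second conventions
  coexist in the literature for these assays, both figures are emitted
  with explicit unit tags and never converted silently.
* Metabolite normalisation: per-DW concentration
  $= c_{FW}/(1 - \mathrm{awc})$, taking $DW = FW(1-\mathrm{awc})$ as the
  meaning of "absolute water content"; log2 fold changes require strictly
  positive means.

# The synthetic generators

Every analysis module has a closed-loop test against a generator that
emits its own ground truth; all generators are pure functions of a spec
and a seed (bit-reproducible).

**Tray renderer** (`render_tray`). Draws grass-like blades as solid
quadratic strokes with per-pixel green jitter over a wall/soil
background, plus a divider line. Blade tips are spread over a few rows
below the container's canopy-top row with every fifth blade forced to
reach the top, so the recorded truth top is attained and the coverage
fraction rises past $\tau = 0.2$ within ~2 rows of it. Strokes are drawn
solid rather than anti-aliased so the truth mask is exactly the set of
drawn pixels. Noise is salt-and-pepper corruption (default 1% of
pixels), applied after the truth is recorded. What this does *not*
emulate: specular leaf highlights, shadows, perspective, soil texture,
or chlorosis — passing tests show the geometry of the estimator is
right, not that segmentation is robust to every field artifact.

**Kinetics generator** (`simulate_growth_series`). Piecewise-linear W/D
height curves with multiplicative Gaussian noise. The defaults encode the
study conditions the package targets: 19 daily measurements; shared
growth of 130 px/day so the curves separate at day 8 near 1040 px; a
stress decline of −70 px/day until rewatering at day 15; recovery at
+150 px/day; 2% height noise; 3 replicate trays. The W variant saturates
to a quarter of the growth rate after day 15, a stylised account of
late-vegetative slowing. A strictly linear decline over the full stress
window reaches a lower minimum (~550 px) than a real curve whose drop
steepens late; the generator keeps the slopes, which are the traits
under test, rather than the minimum.

**Fluorescence traces** (`simulate_fluor_traces`). Healthy traces center
$\Phi_{Po}$ near 0.81 (s.d. 0.012, the healthy-leaf range); stress lowers
$\Phi_{Po}$ by up to 0.12 and deepens quenching ($F_M'$ falling from
~0.80 to ~0.50 of the variable fluorescence span). $F_t$ is drawn
strictly between the Oxborough–Baker $F_0'$ and $F_M'$, so every trace is
valid by construction.

**Trait table** (`simulate_trait_table`). 47 variables — 15 traits, 19
amino acids, 8 polyamines, 3 enzymes, 2 totals — over the four groups
W/D × stress/recovery. D-group means are shifted by injected log2
effects (defaults pattern proline/hydroxyproline and polyamine
accumulation under stress, citrulline and APX rising after rewatering);
a latent per-sample factor loading positively on metabolites and
negatively on growth traits supplies the correlated structure a PCA
separates. Its standard deviation defaults to 0.10 on the log scale —
about 10% replicate-tray variation, a realistic figure for replicate
trays under one treatment; the multiplicative measurement noise defaults
to 10% CV.

# Reporting layer

Pearson correlations use pairwise-complete observations; constant
variables are flagged with `NA` correlations rather than failing. PCA
runs on the correlation matrix by default (unit-variance scaling),
because traits and metabolites carry incommensurate units; rows with
missing values are dropped, and loading signs follow a fixed convention
(first nonzero element positive) so output is reproducible. Group
comparisons offer Kruskal–Wallis with Holm-adjusted pairwise Wilcoxon
tests, or one-way ANOVA with Tukey HSD; both produce a compact letter
display via an insert–absorb routine over the pairwise p-matrix (groups
sharing a letter do not differ at $\alpha$). The Tukey letters are
cross-checked against `multcomp`'s display in the test suite.

# Numerical and validation choices

* Strict inequality at the stopping threshold; ties descend further.
* Exhaustive oracle equivalence: the descent is compared against a naive
  every-row scan on 1,000 random masks up to 16×16 at nine thresholds.
* Validation problem sizes: the end-to-end image loop uses 12 rendered
  trays (2800 × 540 px, heights to ~2100 px); kinetics recovery uses 200
  seeded replicates; the partition identity is checked on 10,000 traces.
  These sizes give stable estimates of stochastic quantities while
  keeping the default validation run in the minutes range on one core.
* Degenerate inputs have defined behavior throughout: contrast-free
  images give empty masks; constant series give zero slope with
  $R^2 = 0$ by convention; empty containers are flagged; identical
  groups share one letter.

# Known limitations

Heights are population proxies in pixels — no instance segmentation (not
possible in closed canopies), no physical units. The gap-based
separation rule depends on $\delta$; with fewer than two replicates per
day the Kruskal–Wallis rule is unavailable. The renderer's simplified
optics mean segmentation performance on real imagery should be
re-validated per installation, ideally with the fixed-threshold method
and a few hand-labelled frames.
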