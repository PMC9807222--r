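---
title: "Methods: stem bending mechanics, tissue morphometrics, and diameter-class statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stem bending mechanics, tissue morphometrics, and diameter-class statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemflex)
```

`stemflex` analyses how young liana trellis stems trade stiffness for
flexibility as they transition from self-supporting searchers to attached
trellis elements. This vignette documents the models the package implements,
the assumptions behind them, the defaults and why they were chosen, and what
the synthetic-data generator does and does not emulate.

## The mechanical model

A stem segment in three-point bending over span $l$ (mm) deflects at midspan
by $\delta = F l^3 / (48\,EI)$ within the elastic range. The package reduces
a loading sequence to:

$$EI = \frac{l^3 b}{48}, \qquad
  I = \frac{\pi}{4}\,\bar a^3 \bar b, \qquad
  E = \frac{EI}{I},$$

where $b$ is the slope (N/mm) of the force–deflection curve, and $\bar a$,
$\bar b$ are the means of three caliper semi-axis measurements: vertical
(in the load direction) and horizontal, taken at the segment center and 25%
proximally and distally. Units compose to $EI$ in N·mm², $I$ in mm⁴ and $E$
in MPa (MN·m⁻²).

Design choices in the reduction:

- **Slope with intercept.** The OLS fit of force on deflection includes an
  intercept, because pannier settling and seating of the specimen produce a
  constant offset; only the slope carries stiffness information. An
  $R^2 < 0.99$ flags suspected loading beyond the elastic limit
  (`linearity_warning`), and deflections outside a configurable elastic
  window (default 0.2–5 mm, bracketing the typical 1–3 mm working range)
  flag but do not reject a record — hard rejection would discard valid
  extreme specimens.
- **Depth = vertical diameter.** The span-to-depth ratio uses the diameter
  along the load direction ($2\bar a$), the beam-testing convention.

### Span-to-depth screening

Short spans contaminate the measured deflection with shear. The package's
forward model is the midspan Timoshenko form

$$\delta = \frac{F l^3}{48\,EI} + \frac{f_s F l}{4 G A},$$

with shear correction factor $f_s = 10/9$ (solid circular section) and
$G = E/(E/G)$, default $E/G = 20$ — a minimal standard model that reproduces
why a span test is needed without asserting anything about the real shear
behavior of stem tissue. The apparent stiffness recovered from such a test is
$EI_{app} = EI / (1 + 48\,EI\,c/l^2)$ with $c = f_s/(4GA)$: strictly
increasing in span and approaching the true $EI$.
`span_to_depth_analysis()` declares the plateau reached at the smallest
tested ratio whose apparent $E$ is at least 95% of the value at the largest
tested span. The 95% rule is a package choice (the field protocol reports
only its outcome, a working ratio of 40); it is configurable, and a specimen
where only the largest tested span qualifies is flagged rather than assigned
a threshold, since a still-rising curve has not demonstrated convergence.

## Tissue morphometrics

Cross-sections arrive as integer label rasters (0 background, 1 pith,
2 wood TYPE I, 3 wood TYPE II, 4 cortex) with a physical pixel size $p$
(mm). Areas are pixel counts times $p^2$. Second moments of area are taken
about the **horizontal axis through the whole-section centroid** — the
bending axis, since the test load acts vertically — with each pixel
contributing

$$(y_c - \bar y)^2\,p^2 + \frac{p^4}{12}.$$

Two deliberate conventions:

- **One common axis for all tissues.** Per-tissue second moments use the
  global section centroid, not per-tissue centroids, so that contributions
  sum exactly to the whole-section $I$ — the only convention under which
  "percent contribution to $I$" is well defined.
- **The $p^4/12$ self-term.** Including each pixel's own rectangle inertia
  removes the systematic underestimate of pure parallel-axis summation at
  coarse resolution; it is exact for axis-aligned squares.

Coordinates are fixed as row 1 at top, $y$ increasing downward, pixel
centers at half-integer multiples of $p$. Any consistent convention yields
the same physics; fixing one makes outputs bit-stable. Pixel membership is
decided by the pixel center with no anti-aliasing, keeping labels crisp and
counts exact. At pixel sizes of 1/400 of the section diameter, integrated
areas and moments agree with elliptical closed forms
($I = \tfrac{\pi}{4}a^3b$ and its annulus extension
$\tfrac{\pi}{4}(a_o^3 b_o - a_i^3 b_i)$) to well under 0.5% (the acceptance
script reports the realized worst case, typically < 0.2%).

The package does **not** segment photographs: inputs are already-labeled
rasters, mirroring a workflow in which tissue boundaries are traced manually
and digitized.

## The synthetic cohort generator

The generator exists so that every stage — rasterization, pixel integration,
bending reduction, pooling, statistics — can be checked against known ground
truth. It emulates the structure of a field sample of four trellis stem
categories (self-supporting, pendulous, climbing, fixed):

- **Tissue fractions.** Each specimen draws pith/wood-I/wood-II/cortex area
  fractions from a Gaussian around its category profile
  (`category_fraction_profiles()`), normalized to sum to 1. The profiles are
  the narrow-diameter field means and SDs of the study system (only that
  diameter class's profile is used across all diameters — a simplification,
  since the field data's medium/large profiles differ, notably in wood-II
  content of attached stems). Draws below 0.4% of wood TYPE II are set to
  exactly zero, reproducing the near-absence of lianoid wood in unattached
  stems.
- **Geometry.** Fractions are realized as nested elliptical annuli sharing
  the outer aspect ratio (drawn uniformly in 0.85–1). Small wood-II
  fractions (< 5%) become 3–6 discontinuous lobes of 20–40° at a seeded
  random phase — emulating the scattered pockets of early lianoid wood —
  provided the wood-I annulus can absorb the remainder; otherwise, and for
  larger fractions, wood II is a complete ring. In lobes mode the annulus is
  widened so the arcs alone carry the full wood-II target fraction, keeping
  realized fractions exact (to 1e-6 analytically).
- **Diameters.** Uniform on 1.8–10 mm per category. With the developmental
  threshold rule on (default), self-supporting and pendulous stems are
  capped at 5.9 mm, reproducing the observed cutoff above which only
  attached stems keep growing. The uniform shape is a generator choice — the
  field distribution within classes is not documented — and is overridable.
- **Ground truth mechanics.** Per-tissue second moments are computed in
  closed form (lobe arcs reduce to a $\cos^2\theta$ integral in scaled polar
  coordinates), and the stem's stiffness is composed as
  $EI = \sum_t E_t I_t$ with tissue moduli
  pith 50, wood I 6500, wood II 800, cortex 300 MPa
  (`default_tissue_moduli()`). These values were chosen once so that
  composite stem moduli land in the 1500–3000 MPa regime typical of young
  trellis stems with dense TYPE I wood as the stiffness driver; they are
  inputs, not estimates (the package performs no inverse estimation of
  tissue moduli).
- **Bending records.** 1–3 tests per specimen (5–6 loading steps each) at a
  span-to-depth ratio of 40, with step masses chosen to reach a target
  deflection drawn from 1–3 mm. Forces are $F = mg$ with $g$ = 9.81 m/s².
  Optional Gaussian noise applies to deflection readings and caliper radii;
  optional shear follows the Timoshenko model above.

Everything is driven by a single seed; identical configurations produce
byte-identical cohorts.

**What passing tests show — and don't.** Noiseless round trips recover
ground truth to machine precision and noisy ones are unbiased within
Monte-Carlo error, which validates the *chain of computation*. The generator
does not emulate vessel-level anatomy, tissue-modulus variation within a
stem, curved or twisted segments, growth through time, or non-elliptical
outlines; agreement on synthetic cohorts therefore says nothing about those
aspects of real stems.

## Statistics

- **Pooling.** Diameter classes narrow [1.8, 3.9), medium [3.9, 5.9], large
  (5.9, ∞) mm. The printed class edges overlap at 3.9 and 5.9; the package
  fixes the rule as stated ("large" strictly above 5.9, and, made consistent
  with it, 3.9 assigned to medium). Diameters below 1.8 mm get a `below`
  label and are excluded from pooled comparisons.
- **Kruskal–Wallis.** Tie-corrected, via `stats::kruskal.test()`, behind a
  surface that applies the inclusion rule: categories with fewer than 3
  observations in a trait × class cell are excluded with a recorded reason
  (mirroring the field analysis's exclusion of an undersized category; the
  threshold 3 is the package's concrete rule, as none was stated). The fully
  tied case is reported as $H = 0$, $p = 1$.
- **Dunn's post-hoc.** Pairwise
  $z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N{+}1)/12 - \sum T/(12(N{-}1)))\,(1/n_i + 1/n_j)}$
  on pooled mid-ranks with tie term $T = t^3 - t$, two-sided normal
  p-values. The default applies **no** multiplicity adjustment (the source
  analysis states none); Bonferroni/Holm and the other `p.adjust` methods
  are available. Whether letters should derive from raw or adjusted
  p-values is left to the caller for the same reason.
- **Compact letter display.** Insert-and-absorb assignment: groups share a
  letter *iff* their pairwise p-value is at least α. Non-transitive patterns
  yield multi-letter groups; the tests verify the display reconstructs the
  thresholded p-matrix exactly on random patterns.
- **Spearman.** $R_s$ as the Pearson correlation of mid-ranks;
  $t = R_s\sqrt{(n-2)/(1-R_s^2)}$ with $n-2$ df for the two-sided p-value.
  At pooled-cohort scale (hundreds of segments) the t approximation is
  standard and matches published statistics; perfect monotone relations are
  flagged with unbounded $t$ and $p = 0$ rather than erroring.
- **Aggregation unit.** The default record is the stem segment (one row per
  bending test), matching how field samples are counted; per-individual
  averaging is available (`aggregate = "individual"`) since reasonable
  analyses differ here.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of 40–100 specimens,
rasters of 150–400 pixels per diameter, 200 Monte-Carlo replicates for the
noise-bias check, and exact permutation enumeration only at total $n \le 8$.
These sizes make every validated claim — fraction conservation to 1e-6,
geometry to 0.5%, recovery to 1e-6 relative, permutation agreement to
0.02 — checkable in seconds while remaining comfortably inside their
asymptotic regimes. Degenerate inputs are defined, not accidental: empty
sections error, absent tissues report zero area and zero $I$ (not an error),
zero totals error on percent computation, and constant vectors error on
correlation.

## Known limitations

- The ellipse approximation for caliper-based $I$ and the pixel integration
  for image-based $I$ answer slightly different questions on irregular real
  sections; the package reports both paths and never mixes them silently.
- The shear model is a deliberately minimal screening device, not a
  validated constitutive description of stem tissue.
- Category fraction profiles are diameter-independent in the generator
  (narrow-class profiles throughout), so synthetic cohorts understate the
  wood-II enrichment of large attached stems.
- No failure mechanics, torsion, or four-point bending; no automatic
  segmentation of color photographs.
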