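---
title: "Quantifying ecDNA tethering from fluorescence microscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ecDNA tethering from fluorescence microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectether)
```

## The problem

Extrachromosomal DNA (ecDNA) elements are large, circular, acentric,
chromatinized DNA bodies that carry oncogene amplifications (here visualized
with a *MYC* FISH probe). Lacking centromeres, ecDNA are not segregated by the
spindle; they hitchhike through mitosis by physically tethering to
chromosomes. How strongly they tether — and what happens when they do not
(mis-segregation into micronuclei, copy-number loss) — is quantified from
multi-channel fluorescence microscopy. This package implements that
quantification as a tested pipeline over three experimental geometries:

1. **Prometaphase spreads** — chromosomes dispersed on a slide; each ecDNA is
   a small connected component whose *perimeter adjacency* to
   chromosome-class pixels defines its tether state.
2. **Metaphase cells on coverslips** — chromosomes aligned at the metaphase
   plate; tethering is *pixel overlap* of FISH signal with the largest DAPI
   connected component (the genomic mass).
3. **Newly divided daughter-cell pairs** — micronuclei are small DAPI bodies
   outside the two primary nuclei; the micronuclear share of FISH pixels
   measures ecDNA mis-segregation.

Because the source measurements were made on microscopy that is not publicly
deposited, every stage is instead verified by *parameter recovery* against a
seeded synthetic-scene generator that renders each geometry with per-object
ground truth.

## Metric definitions

### Spread tether classes

For an ecDNA connected component (8-neighbourhood throughout, the
"connectivity = 2" convention), boundary pixels are component pixels with at
least one 8-neighbour outside the component; out-of-image sides count as
outside. The adjacency fraction is the share of boundary pixels that have at
least one chromosome-class 8-neighbour:

- fraction < 0.25 → **untethered**
- 0.25 ≤ fraction < 1 → **tethered**
- fraction = 1 → **surrounded** (fully enclosed; excluded from the
  untethering denominator)

$$\text{untethering \%} = 100\cdot\frac{n_\text{untethered}}{n_\text{untethered}+n_\text{tethered}}$$

The number of chromosome-class components is reported as *chromosome
individualization*. The upper tether bound is stated as "99.9%" in the
field's convention; with finite boundary counts a fraction strictly between
0.999 and 1 is realizable, so this package reads the bound as the half-open
interval $[0.25, 1)$ — only components with *every* boundary pixel
chromosome-adjacent are "surrounded". Whether the original script treated
99.9% as exact or as display rounding is unknowable from the text; the choice
here is documented rather than claimed identical.

### Metaphase overlap, micronuclei, foci, intensity metrics

- **Metaphase untethering** = 100 × (FISH-positive pixels not overlapping the
  largest DAPI component) / (all FISH-positive pixels). Ties for largest are
  broken by lowest component id.
- **Micronuclei**: `myc_in_mn_pct` = 100 × FISH px in micronuclei / FISH px
  in primaries + micronuclei; `mn_composition_pct` = 100 × FISH px in
  micronuclei / DAPI px in micronuclei.
- **Focus counting**: three-class Otsu, higher threshold, 8-connected
  components, count those of **more than five pixels** (`min_focus_px = 6`).
- **Integrated density** = sum of IF intensity over a segmented region;
  expression tiers: below a background cutoff → negative (−); at or above
  the 80th percentile (linear-interpolation quantile, ties inclusive) of
  *expressing* cells → high (++); otherwise positive (+). The "top 20% tile"
  denominator is read as expressing cells only, because those are the cells
  being tiered + versus ++; this is flagged as an interpretation.
- **Acetylation ratio**: mean IF / mean DAPI over one pixel class
  (chromosome or ecDNA), normalizing signal to DNA content.
- **Convex hull area** (drug-screen proxy): lattice points inside or on the
  convex hull of all foreground pixel centers of the DAPI ∪ FISH mask, ties
  inclusive. Row-interval rasterization makes this exact for integer centers.

### Statistics layer

One-way ANOVA (classical sums of squares) with Tukey HSD post hoc via the
studentized range distribution, gated on omnibus p < 0.05; two-way ANOVA
with **type-II** sums of squares (the configuration of the reference stack;
type II equals the sequential decomposition for balanced designs but is
well-defined for the unbalanced cell counts real experiments produce);
chi-squared tests of independence with Yates continuity correction on 2×2
tables by default (matching the reference implementation's default); simple
linear regression with Pearson r; two-tailed **pooled-variance** Student's t
tests with Bonferroni adjustment `min(1, m·p)` (the screen fixed m = 44);
weighted clone means; and 2^−ΔΔCt relative quantification (ΔCt = target −
reference Ct; ΔΔCt subtracts the control-group mean ΔCt).

## Image operations

- **Best-focus selection**: population variance of the 3×3 discrete
  Laplacian `[[0,1,0],[1,−4,1],[0,1,0]]`, maximized over planes, ties to the
  lowest z index. Borders are handled by reflect-101 mirroring, the default
  of the reference implementation's Laplacian; under this choice a constant
  image scores exactly 0 and the score is invariant to adding a constant
  offset, neither of which holds under zero padding. Exact numeric parity
  with the original script is not claimed (its kernel size and border flag
  are unstated).
- **Multi-level Otsu**: 256 uniform bins over the observed min–max range;
  exhaustive search over all threshold pairs for the global between-class
  variance maximum (ties broken toward lower thresholds, which lands the
  threshold immediately above the last occupied bin of the lower class).
  Binarization uses `>=`, so a pixel exactly at the threshold is foreground.
  The *higher* threshold segments FISH and metaphase DAPI; the *lower*
  threshold segments interphase DAPI.
- **Chromosome/ecDNA pixel classes**: the published neural segmenter is out
  of scope; a rule-based surrogate stands in, and externally produced label
  masks are the fidelity path (passed through verbatim). The surrogate
  resolves pixels, not whole components: FISH-positive pixels are ecDNA;
  remaining pixels of each DAPI component follow the component's area
  (≤ 200 px → ecDNA, larger → chromosome at the synthetic scale). A
  component-level reading of the area rules would misclassify a tethered
  ecDNA that merges with a chromosome into one DAPI component — the merged
  component is large, so the ecDNA would vanish and the untethering
  percentage would be biased toward 100%. The pixel-level rule keeps every
  stated example and the zero-noise agreement bound while fixing that
  failure mode.

## The synthetic stated world

The generator renders what the metrics assume, not optical reality:

- **Spreads**: 6 chromosomes as capsules (length 55–75 px, half-width
  5.5 px, ≥ 2 px mutual clearance so they stay individual components) and 20
  ecDNA discs (radius 3–7 px) per 256×256 scene. Intended tether classes are
  *constructed*: untethered discs keep a ≥ 2.5 px clearance from everything;
  surrounded discs are carved into a chromosome interior with an intact
  chromosome ring; tethered discs are clipped against a chromosome flank and
  accepted only if the realized adjacency lands in [0.25, 1). Realized
  fractions are re-checked against `classify_tether()` at generation time,
  so truth is exact by construction, and per-scene class counts use
  round-half-up of the requested fractions.
- **Channels** carry three separated intensity populations each (e.g. DAPI:
  background 10, ecDNA 120, chromosome 200; FISH: background 5, chromosomal
  cross-hybridization 30, foci 180), which keeps three-class Otsu well posed
  even at zero noise. Interphase DAPI additionally renders bright
  chromocenters (level 300) inside primary nuclei: without a genuine third
  DAPI population, the optimal two-threshold split spends a threshold
  bisecting the dominant background mode and the "lower threshold" mask
  swallows background — the same failure real interphase images avoid by
  having heterochromatic foci.
- **Noise**: additive Gaussian, clipped at zero, default σ = 10 ("moderate").
  Chosen a priori by a separation argument: the smallest class-mean gap is
  110 units ≈ 11 σ, and the expected maximum of ~6×10⁴ background draws
  stays ≈ 4.3 σ below the inter-mode gap, so no stray background pixels
  become spurious components (the pipeline deliberately has no small-object
  filter, because the stated segmentation rules do not include one).
- **Not modeled**: point-spread-function optics, photobleaching, camera
  gain, 3D structure, uneven illumination. A green recovery test therefore
  establishes that the *rules* are implemented correctly and are robust to
  pixel noise — not that the surrogate segmenter would match a neural
  segmenter on real COLO320DM images. Imported masks exist precisely for
  that gap.

## Numerical and interface choices

- Component ids are assigned in row-major order of each component's first
  pixel; all tie-breaks (focus plane, genomic mass, Otsu) go to the lowest
  index/threshold — determinism is a contract, and byte-identical reruns are
  tested.
- Each generator consumes a single RNG stream derived from its explicit seed
  and restores the caller's RNG state.
- Images travel as plain numeric matrices (intensities ≥ 0, arbitrary
  units); TIFF I/O is a minimal baseline little-endian uncompressed 8/16-bit
  grayscale reader/writer, because no TIFF package is available in the
  target environment — compressed or exotic TIFFs are rejected with a clear
  error, and extraction from proprietary microscope containers is out of
  scope (users pre-export TIFF).
- The run configuration is a single declarative JSON file (no YAML parser in
  the target environment); every parameter in effect is echoed to `run.log`.
  CSV output is comma-separated UTF-8 with a header row and "." decimal.
- Degenerate inputs have defined behaviour: constant images raise a
  degenerate-histogram error (focus counting catches it and returns 0 with a
  warning); a spread with no ecDNA reports a missing untethering percentage
  but still counts chromosomes; zero FISH pixels make the overlap and
  micronuclei percentages missing rather than zero.

## Known limitations

- The surrogate pixel classifier is explicitly not the published neural
  segmenter; its intermediate-area rule (FISH-negative bodies between the
  area cutoffs count as chromosome) is a documented guess.
- The boundary is the set of component border *pixels*, not a traced
  contour; perimeter-adjacency values can differ from contour-based
  implementations on the same mask.
- `partition_daughter_nuclei()` automates what was manual labeling; its
  size-rank rules (2 largest components primary, micronuclei within
  [10 px, 0.5 × smallest primary]) are a reproducible stand-in with an
  annotation-import escape hatch.
- Statistical helpers assume the designs the source experiments used
  (between-cell independence, normal-ish residuals); they are thin,
  oracle-tested wrappers, not a general modeling framework.
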