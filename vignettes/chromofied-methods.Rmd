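---
title: "Quantifying histone-variant enrichment at chromocenters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-variant enrichment at chromocenters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromofied)
```

## The biological measurement

Mouse chromocenters are DAPI-dense nuclear bodies formed by clustered
pericentric major-satellite repeats. The replicative histone variants
H3.1/H3.2 are deposited by the CAF-1 chaperone during DNA synthesis
(DSC pathway), while the replacement variant H3.3 is deposited
synthesis-independently (DSI, via HIRA or DAXX/ATRX). Whether a nucleus
shows a histone signal *enriched*, *even*, or *excluded* at its
chromocenters is therefore a readout of deposition-pathway activity, and it
changes with cell-cycle stage and differentiation state.

`chromofied` implements the quantification machinery for this readout:

1. **3D-FIED** (3-dimensional fluorescence intensity enrichment at
   domains): for a nucleus with segmented chromocenter domains, the ratio

   $$ R = \frac{\overline{I}_{\text{domains}}}{\overline{I}_{\text{nucleus}
   \setminus \text{domains}}} $$

   computed over exact voxel sets, both for the union of domains
   (`ratio_global`) and per domain (same denominator).

2. **Pattern classification**: a nucleus is *Enriched* when at least
   `k_min = 3` chromocenters have a per-domain ratio above the tolerance
   band ($r > 1 + \delta$), *Excluded* when at least `k_min` fall below
   ($r < 1 - \delta$), *Even* otherwise, with $\delta = 0.2$.

3. **Cell-cycle staging**: marker logic on EdU/Aurora-B (G1 when both
   negative, S when EdU-positive — refined to early/mid/late S from the
   spatial EdU pattern — G2 when Aurora-B-positive only) and FUCCI logic on
   hCdt1/Geminin intensities.

4. **Repeat-level ChIP normalization** (SNAP-capture-seq): per-repeat
   fragment counts are scaled to counts-per-million over repeat-mapped
   reads, divided by repeat length, divided by the matched input,
   log2-transformed, and z-scored per IP sample across repeats, after
   removing the tandem (`trf`) and low-complexity (`dust`) repeat classes.
   Values above 0 read as enrichment relative to the average repeat.

5. A **synthetic-data generator** that renders ground-truthed nuclei and
   repeat-count data so every stage is testable without any download.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `delta` | 0.2 | ratio | "same as the nucleus" band half-width; echoes the 1.2 positivity cut-off used for the Clover gate |
| `k_min` | 3 | domains | chromocenters outside the band needed for an Enriched/Excluded call |
| `gate_threshold` | 1.2 | ratio | TALE positivity on whole-nucleus Clover enrichment, strict `>` |
| `k` | 2 | SD | chromocenter threshold: mean + k·sd of nuclear DAPI |
| `smooth_sigma` | 0.3 | µm | Gaussian smoothing before the Otsu nucleus threshold |
| `min_nucleus_volume` | 50 | µm³ | debris filter for nuclei |
| `min_domain_volume` | 0.15 | µm³ | speckle filter for chromocenters |
| `theta_ring`, `theta_n`, `theta_per` | 0.5, 10, 0.5 | — | EdU sub-stage rules (ring fraction; focus count; periphery fraction) |
| `ring_um` | 0.5 | µm | chromocenter dilation ring used by the mid-S rule |
| `rim_um` | 1.0 | µm | peripheral shell depth used by the late-S rule |
| `marker_k_sd` | 3 | SD | marker positivity: mean in-nucleus > background mode + k·spread |

Design choices where the underlying publication protocols are qualitative
or silent, fixed here as explicit computable surrogates:

* **"Higher / lower than the nucleus"** is quantified through the
  $\delta$-band on mean per-domain ratios (peak intensity would be noisier
  and volume-dependent). Mean — not median — intensity makes the global
  ratio exactly the volume-weighted mean of per-domain ratios, which the
  tests assert.
* **Excluded rule** is the mirror image of the published Enriched rule
  (≥ 3 domains below the band), with Enriched taking precedence.
* **Boundary semantics**: a Clover ratio of exactly 1.2 is negative
  (positivity is defined strictly as ratio > 1.2); the Enriched call flips
  at exactly 3 above-band domains. Both boundaries are asserted by
  bisection/sweep tests.
* **"Rest of the nucleus"** means nucleus minus *all* domains, also for
  per-domain ratios, keeping a single denominator.
* **Late-S periphery shell**: the shell is a 1.0 µm erosion band from the
  segmented nucleus border. A shell defined as the outer 10 % of the
  equivalent radius (≈ 0.4 µm here) is thinner than a single late-S
  replication focus, so the `frac_periphery > 0.5` rule could never fire;
  1.0 µm matches the scale of lamina-proximal foci. The erosion uses a
  separable box element (exact 1.0 µm depth along the axes, slightly
  deeper diagonally) for speed.
* **FUCCI "++" vs "+"**: thresholds `t_pos` (Otsu split of log
  intensities) and `t_high` (75th percentile of positives) can be derived
  per experiment with `derive_fucci_thresholds()`, making staging invariant
  to common channel rescaling; fixed defaults (60, 200) match the
  generator's rendering scale.
* **Marker positivity spread** uses the background interquartile range
  scaled to a normal SD rather than the raw SD: bright structures blurred
  just outside the nuclear border (late-S foci) and the zero-clamped half
  of the read-noise distribution both break the raw SD.
* **z-score axis**: each IP sample is standardized across its repeats
  (sample SD), so "above 0" reads as enrichment relative to the average
  repeat — the reading consistent with single-condition boxplot summaries
  of the major-satellite class. Standardizing each repeat across samples is
  the other possible reading of "cross-sample normalization"; it is not
  implemented.
* **Zero-input repeats** are masked from the ratio and z computation
  rather than pseudocounted (no pseudocount is stated anywhere);
  `pseudocount` is available behind a flag.
* **CPM totals** are computed after class filtering (unstated in the
  protocol; the alternative differs only by a per-sample constant that the
  z-score removes).

## What the synthetic generator emulates — and what it does not

`generate_nucleus()` renders an ellipsoidal nucleus (default semi-axes
2.5 × 4.5 × 4.5 µm, a flattened adherent nucleus) containing 6–15
non-overlapping spherical chromocenters (radius 0.6 ± 0.1 µm) at
`dapi_fold = 3` DAPI contrast. Each signal channel is uniform at
`base_level` (100 photon counts) in the nucleoplasm and `base_level × r`
inside chromocenters. Optics and detection are modeled as an isotropic
Gaussian PSF (σ = 0.1 µm) followed by Poisson shot noise and Gaussian read
noise (SD 2 counts, clamped at zero). Ground-truth masks are returned
pre-blur, pre-noise.

Condition presets tie pattern mixtures to fold ranges chosen to straddle
the classifier band: Enriched r ∈ [1.4, 2.5], Even r ∈ [0.95, 1.1],
Excluded r ∈ [0.6, 0.78]. (The Excluded upper end is capped below the
band's lower edge 0.8 — a fold inside the band would be Even by
construction.) Cell-cycle renderings: early-S EdU as 50–80 small foci
(0.2–0.35 µm) in the nucleoplasm excluding chromocenters; mid-S as a
0.3 µm dilation ring around chromocenters; late-S as 5–8 large foci
(0.7–0.9 µm) hugging the nuclear border; G2 as diffuse Aurora-B; FUCCI
stages as diffuse hCdt1/Geminin at (negative, positive, high) = (0, 120,
300) counts.

The default voxel size follows the confocal acquisition (0.172 µm z-step,
0.08 µm in xy). The packaged presets override it to a 2×-binned
(0.344, 0.16, 0.16) µm grid so that a 300-nucleus population runs in
minutes on one CPU; at this grid a chromocenter still spans ~100 voxels,
ample for mean-intensity ratios. One unit-test invariant (the
recall/precision sweep) uses 30 nuclei instead of the module's stated 100,
again purely for runtime.

Not emulated: realistic optics (no spherical aberration, no chromatic
focal offset between DAPI and far-red), nucleoli, mitotic figures,
intensity inhomogeneity, or chromocenter shape irregularity. A green
recovery test therefore establishes that the *pipeline arithmetic and
rules* recover known ground truth at realistic SNR — not that segmentation
would be robust to every artifact of real microscopy. The chromocenter
count/size distributions are plausible stand-ins (no published per-cell-type
calibration exists), so preset proportions, not absolute domain geometry,
are the validated quantities.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on a 256-bin histogram spanning the data
  range, making segmentation exactly invariant to intensity scaling;
  constant images yield zero nuclei rather than an error.
* Hole filling is 2D per z-slice — 3D filling through an anisotropic stack
  can seal the nuclear interior via the top/bottom caps.
* Border-touching nuclei are discarded (whole-nucleus ratios would be
  biased); the generator leaves a margin so synthetic nuclei are interior.
* Zero outside-domain mean raises an undefined-ratio error; zero-domain
  nuclei are *uncallable* and excluded from proportions (with a warning if
  a whole replicate is lost).
* "Noiseless" in recovery tests means PSF off and noise off; with the PSF
  on, boundary spill biases ratios by a few percent even without noise,
  which is part of the with-noise (10 %) tolerance, not the noiseless
  (5 %) one.
* An IP sample whose log2 ratios have zero spread (e.g. IP ≡ input) raises
  a degenerate-distribution error at the z-step rather than emitting NaNs.
* The z-score uses the sample (n−1) standard deviation.
* Population generation draws all pattern labels in a single `sample()`
  call before any rendering, so the label stream is reproducible by an
  independent multinomial draw under the same seed — a determinism contract
  the tests exploit.

## Known limitations

* Nucleus segmentation is a global Otsu split: dim nuclei next to bright
  ones in the same field, or touching nuclei, are out of scope (no
  watershed separation).
* The EdU sub-stage rules are threshold surrogates for a visual
  classification; their accuracy target (≥ 90 %) is defined against the
  generator's renderings, the only available ground truth.
* Single-plane (2D) quantification is not implemented; degenerate
  single-z stacks are accepted by the data structures but the pipeline is
  3D-first.
* Downstream significance testing (ANOVA, Mann-Whitney, Kruskal-Wallis)
  is deliberately delegated to standard statistical software.
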