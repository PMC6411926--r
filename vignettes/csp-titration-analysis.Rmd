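---
title: "CSP titration analysis: model, rules and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSP titration analysis: model, rules and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspfit)
```

## The measurement and its model

A ¹H–¹⁵N HSQC spectrum resolves one peak per backbone amide. When a
ligand binds in fast exchange on the chemical-shift timescale, each peak
sits at the population-weighted average of its free and bound positions,
so its displacement along the titration is proportional to the bound
fraction of protein. The displacement is summarized per residue as the
normalized chemical shift perturbation

$$\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (w_N\,\Delta\delta_N)^2},$$

with $w_N = 0.20$ (`nitrogen_weight`) compressing the ¹⁵N axis onto the
¹H ppm scale — the standard weight for backbone amides. `normalized_csp()`
implements this; it is a norm in the weighted shift plane, symmetric in
reference and observed state.

Weak interactions force the protein concentration (0.05–0.10 mM here)
into the same range as the ligand, so the free-ligand hyperbola is
biased and the bound fraction must come from the exact single-site mass
balance. Solving the quadratic for the complex concentration gives

$$\Delta\delta = \Delta\delta_{max}\,
  \frac{([L]+[P]+K_d) - \sqrt{([L]+[P]+K_d)^2 - 4[P][L]}}{2[P]},$$

implemented in `predict_csp()`. It is increasing in $[L]$ and
$\Delta\delta_{max}$, decreasing in $K_d$, bounded by
$[0, \Delta\delta_{max}]$, and collapses onto
$\Delta\delta_{max}[L]/([L]+K_d)$ as $[P] \to 0$ — properties the test
suite asserts directly.

A ternary titration — titrant added to protein pre-bound to a first
ligand — needs no special machinery: the CSP measures displacement from
whatever state the reference spectrum captures, so setting the series
reference to the complex point and fitting as usual yields the
titrant's affinity for the pre-formed complex.

## Significance classification

Only residues whose endpoint CSP stands out from the profile are fit.
The threshold is the mean plus one standard deviation of the endpoint
CSP distribution computed after trimming the
`ceiling(trim_fraction * n_ok)` observed residues with the largest CSP
(`trim_fraction = 0.10`; for the canonical 49 observed resonances this
trims five). Trimming exists to keep strong genuine binders from
inflating the very threshold meant to detect them; the trimmed residues
therefore remain eligible to be classified significant. Design choices
worth stating explicitly:

* **Ceiling, not rounding**, fixes the trimmed count at small $n$
  (10% of 49 → 5), and ties in the largest-CSP order are broken by
  trimming the higher residue index first, making the rule
  deterministic and order-invariant.
* **Sample (n−1) SD**, the small-sample convention.
* **Strict inequality** $\Delta\delta > \text{threshold}$, with a
  $10^{-9}$ relative guard so floating-point jitter cannot promote a
  residue sitting exactly at the threshold; in the degenerate all-equal
  profile the SD is zero and no residue is significant.
* **Broadened, missing and proline entries never enter the threshold
  statistics**; broadened resonances (lost to intermediate-exchange
  line broadening, themselves evidence of binding) are carried through
  to the outputs with their status rather than a value.

## Per-residue fitting and the global Kd

Each significant residue's trajectory — $\Delta\delta$ at every point
against $([P], [L])$, including the reference $(0, 0)$ — is fit by
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) for
$(K_d, \Delta\delta_{max})$, with $K_d \in [10^{-6}, 10^3]$ mM,
$\Delta\delta_{max} \in (0, 10\,\max\Delta\delta]$, and convergence
tolerances of $10^{-10}$ on objective and parameters for cross-platform
reproducibility. Starting values are
$\Delta\delta_{max,0} = 1.2 \max \Delta\delta$ and $K_{d,0}$ = the
ligand concentration at the half-maximal observed CSP (linear
interpolation), robust for both saturating and non-saturating designs; a
single deterministic restart from $(10\,K_{d,0},\,2\,\Delta\delta_{max,0})$
is attempted if the first fit fails to converge. Trajectories with all
CSPs below machine noise are rejected as non-binders. The tests verify
the fitter against an independent 200×200 log-grid search of the RSS
surface; agreement is required to grid resolution, measured with the
coarser of the two grid spacings because the $(K_d, \Delta\delta_{max})$
likelihood ridge has near-unit log–log slope, which propagates the
$K_d$-grid quantization into the $\Delta\delta_{max}$ argmin.

The global $K_d$ averages the per-residue estimates over converged fits
of significant residues, with one robustness pass: residues whose $K_d$
deviates from the initial mean by more than `outlier_sd` (default 2)
standard deviations of the initial set are removed — in a single pass,
since iterating the rule could cascade — and mean and SD are recomputed
over the retained set. If at least `lower_limit_fraction` (default 50%)
of the set is removed, the result is flagged and rendered as a lower
limit (`"> X mM"`).

One structural property of this rule deserves note: when dispersion is
estimated from the same values being screened, the sum of squared
deviations caps the number of points beyond $2\,\mathrm{SD}$ at
$(n-1)/4$, so the 50% removal branch cannot fire from the screening rule
alone. We keep the flag and renderer in the interface — `format_global_kd()`
renders lower limits, and callers can lower `outlier_sd` or
`lower_limit_fraction` when a different screening convention is wanted —
but in practice an unresolvable affinity manifests first as inflated
per-residue scatter (see the validation below), and the honest report in
that regime is the mean with its large SD.

## The synthetic-data generator

`simulate_titration()` exists so that every stage — parsing,
profiling, classification, fitting, aggregation — can be validated
against known ground truth. It emulates, by construction:

* a ~54-residue domain observed as 49 backbone amides (no prolines in
  the simulated lists, as prolines have no amide and never appear in an
  HSQC);
* reference shifts drawn uniformly in realistic windows (¹H 6.5–10.5,
  ¹⁵N 103–133 ppm);
* per-residue responses along fixed random unit directions in the
  *weighted* (¹H, 0.20·¹⁵N) plane, scaled by
  `predict_csp(P, L, true_kd, dmax_i)` — so the normalized CSP equals
  the scalar isotherm exactly and `dmax` is interpretable in
  normalized-ppm units;
* saturating CSPs `dmax_i` drawn uniformly from 0.05–0.25 ppm, typical
  of peptide/DNA titrations of small reader domains;
* i.i.d. Gaussian shift noise at every observed peak of every point
  (defaults 0.003 ppm ¹H, 0.02 ppm ¹⁵N — typical HSQC peak-position
  precision; real uncertainty depends on linewidth and S/N and is
  configurable);
* a configurable number of responsive residues (default 2) that broaden
  beyond detection wherever their bound fraction lies in [0.3, 0.7],
  mimicking intermediate-exchange loss at mid-titration;
* byte-identical output for identical seeds.

Default geometries mirror the two experimental designs the pipeline
targets: a peptide ladder (protein 0.1 mM, ratios 0, 1, 2, 4, 7, 10)
and a DNA-like ladder for high-affinity ligands (protein 0.05 mM,
ratios 0, 0.25, 0.5, 1, 2, saturating near 1:1).

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: lineshapes and intensity decay,
exchange-regime physics beyond the binary broadened/observed flag,
multi-site or cooperative binding (CSP trajectory curvature), baseline
distortion, peak overlap and mis-assignment, or dilution of the protein
along the titration (the manifest accepts per-point protein
concentrations should dilution correction be wanted).

## Validation design and problem sizes

The acceptance analysis (`scripts/acceptance.R`, mirrored in the test
suite) recovers the global $K_d$ across 20 seeded series per condition —
enough for a stable median at a few seconds per condition:

* **Well-sampled regime** (true $K_d$ 0.7 mM ≤ max $[L]$ 1.0 mM): the
  median recovered global $K_d$ lands within a few percent of truth.
* **Under-sampled regime** (true $K_d$ 2.0 mM > max $[L]$): the
  titration reaches only ~33% saturation, $(K_d, \Delta\delta_{max})$
  become strongly correlated, and the seed-to-seed spread inflates —
  the tests assert this variance inflation rather than hiding it, and
  accept the median within a wider band (35%).
* **Ternary regime** (true $K_d$ 0.2 mM from a pre-bound reference):
  recovered like any binary series.
* **High-affinity regime** (true $K_d$ 5 μM, near-stoichiometric
  titration): individual $K_d$s are barely identifiable beyond "below
  the protein concentration", so the assertion is the scientifically
  meaningful one — the recovered global $K_d$ stays below a 10 μM bound
  in at least 18 of 20 seeds.
* **Type-I control**: across 50 seeds, non-responsive residues are
  essentially never classified significant at default noise.

## The genomic overlap module

Peak proximity between ChIP-seq/DNase peak sets uses a maxgap rule: two
intervals overlap when within `max_gap` (default 150) bp on the same
strand. Coordinates are BED-convention 0-based half-open, under which
the gap between $[a,b)$ and $[c,d)$ with $c \ge b$ is $c - b$ (touching
intervals have gap 0), so "within 150 bp" is exactly $c - b \le 150$.
`GenomicRanges::findOverlaps(maxgap =)` provides the sorted interval
engine; the unit tests pin its semantics to an all-pairs brute-force
oracle, including the gap-150 vs gap-151 boundary. An unstranded `"."`
record matches either strand — ChIP-seq peaks are typically unstranded,
and a strict rule would zero out BED3 input. Three-way Venn counts are
reported per anchor set: interval overlap is not a symmetric partition
(one anchor peak can absorb several subject peaks), so each region's
count depends on which set it is counted from, and fractions are always
anchor-relative. Reproducing published overlap percentages on public
ENCODE/GEO peak sets requires those downloads and is deliberately out
of scope for the test suite; `run_overlap()` applies directly to such
BED files.

## Known limitations

* One-site fast-exchange model only; curved CSP trajectories
  (multi-site or coupled equilibria) are not modeled and will fit
  poorly on purpose.
* The global $K_d$ is an unweighted mean over retained residues;
  per-residue fit uncertainties are not propagated into the reported SD.
* Broadening is recorded, not quantified; no intensity analysis.
* The overlap module counts proximity, not statistical enrichment — no
  permutation or background model.
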