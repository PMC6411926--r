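# cspfit

Quantitative analysis of protein–ligand titrations followed by
¹H–¹⁵N HSQC NMR, for the weak-binding regime where chemical shift
perturbation (CSP) titrations are the method of choice — e.g. reader
domains such as chromodomains binding methylated histone peptides or
short DNA duplexes with millimolar-to-micromolar affinity.

Under fast exchange each backbone amide peak sits at the
population-weighted average of its free and bound positions, so the
normalized CSP of residue *i* between the reference (apo) spectrum and a
titration point reports its bound fraction:

```
Δδ = sqrt( (ΔδH)² + (0.20·ΔδN)² )
```

Because these experiments run protein at 0.05–0.10 mM — comparable to
the ligand — the free-ligand approximation fails, and each residue's
trajectory is fit with the single-site isotherm accounting for ligand
depletion:

```
Δδ = Δδmax · ( ([L]+[P]+Kd) − sqrt(([L]+[P]+Kd)² − 4[P][L]) ) / (2[P])
```

with per-residue parameters (Kd, Δδmax). The package implements the full
pipeline:

* **Peak-list I/O** — Sparky-style assigned peak lists, a YAML series
  manifest (per-point molar ratios or concentrations, broadened peaks,
  prolines), TSV/JSON results.
* **Significance rule** — a resonance is significantly perturbed when its
  Δδ exceeds the mean + 1 SD of the CSP distribution computed after
  trimming the top 10% of observed residues (5 of 49), which keeps large
  genuine CSPs from inflating their own threshold.
* **Per-residue fitting** — bounded Levenberg–Marquardt
  (`minpack.lm`) of (Kd, Δδmax) per significant residue.
* **Global Kd** — the mean over per-residue Kds after a single
  outlier-removal pass (|Kd − mean| > 2 SD of the initial set), reported
  as mean ± SD; results dominated by removals are flagged and rendered
  as lower limits ("> X mM").
* **Synthetic titrations** — a seeded generator of fast-exchange HSQC
  series with known ground truth (responsive/silent residues, Gaussian
  shift noise, resonances that broaden away at mid-saturation), so every
  stage is testable without spectra.
* **Genomic peak overlap** — stranded maxgap overlap of BED peak sets
  (two peaks overlap when within 150 bp on the same strand, "."
  matching any strand), with pairwise fractions and three-way Venn
  counts per anchor set.

## Worked example

Simulate a peptide-style titration (true Kd 0.7 mM, protein 0.1 mM,
ratios 1:0 … 1:10, 30 of 49 residues responsive) and run the pipeline:

```r
library(cspfit)

cfg <- simulation_config(true_kd = 0.7, seed = 42)
sim <- simulate_titration(cfg)
res <- fit_series(sim$series, verbose = TRUE)
#> CSP threshold 0.07007 ppm; 14 of 47 observed residues significant
#> Global Kd 0.71 ± 0.17 mM (13 retained, 1 removed)

res$global
#> Global Kd: 0.71 ± 0.17 mM
#>   retained 13 residue(s), removed 1 outlier(s)

head(subset(res$fits, significant,
            select = c(residue_label, delta_endpoint, kd, dmax, retained)))
#>    residue_label delta_endpoint        kd      dmax retained
#> 1             V1     0.08208572 0.8204155 0.1494974     TRUE
#> 5             E5     0.10033344 0.7687546 0.1824170     TRUE
#> 6             W6     0.14123697 0.7796564 0.2539541     TRUE
#> 22           I22     0.07627391 0.4120703 0.1070546     TRUE
#> 26           M26     0.14193574 0.8500048 0.2669967     TRUE
#> 28           I28     0.11056300 0.7668102 0.2014353     TRUE
```

The threshold (0.070 ppm) is the trimmed mean + 1 SD of the endpoint CSP
profile; 14 residues exceed it, each is fit individually, one Kd is
removed by the 2-SD rule, and the retained 13 average to 0.71 ± 0.17 mM
— recovering the generating 0.7 mM.

The same pipeline runs from files
(`run_simulate()` / `run_fit()` / `run_overlap()`), or from a shell via
the thin wrapper:

```sh
Rscript inst/scripts/cspfit.R simulate --kd-mM 0.7 --seed 1 --out sim/
Rscript inst/scripts/cspfit.R fit --manifest sim/manifest.yaml --out out/
Rscript inst/scripts/cspfit.R overlap --query a.bed --subject b.bed \
    --third c.bed --max-gap 150 --out ov/
```

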