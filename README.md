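# smcreg

Cohesin and condensin II — two structural maintenance of chromosomes
(SMC) complexes — occupy the regulatory elements of active genes during
interphase: enhancers bound by the master transcription factors
OCT4/SOX2/NANOG, promoters bound by TBP and POL II, and above all
*super-enhancers*, the large Mediator-rich enhancer clusters that
control cell-identity genes. Genes driven by super-enhancers are
preferentially sensitive to knockdown of either complex. `smcreg`
implements that entire analysis chain as a tested R package over a
synthetic study, so every step — from aligned reads to the final class
comparison — can be verified against planted truth and independent
oracles.

The package is aimed at computational biologists who want a
reproducible, self-contained reference implementation of the standard
machinery in this area:

- **Quantification** — binned coverage from strand-extended reads,
  region signal in reads per million (`total_rpm`) and RPM per bp
  (`density_rpm_per_bp`), with pro-rata partial bins.
- **Occupancy calling** — per-bin Poisson enrichment versus a
  depth-scaled input control, floored at the genome-average control
  rate.
- **Region classes** — enhancers = OCT4 ∩ SOX2 ∩ NANOG, promoters =
  TBP ∩ POL II, heterochromatin = H3K9me3 ∪ H4K20me3; TSS co-occupancy
  and nearest-TSS gene assignment.
- **Super-enhancer calling** — constituents stitched across ≤ 12.5 kb,
  ranked by background-subtracted MED1 signal; the super/typical cutoff
  sits where a unit-slope line is tangent to the rank-vs-signal curve
  scaled to the unit square, and fold differences are reported both per
  enhancer (mean total RPM, super ÷ typical) and per constituent (mean
  RPM/bp density).
- **Rank normalization** — two conditions mapped onto the averaged
  quantile reference of their shared support, used to show condensin II
  loss at enhancers/promoters after NIPBL knockdown.
- **Knockdown statistics** — CPM fold changes with hairpin pooling,
  log2((kd + 1)/(ctrl + 1)); Spearman agreement between knockdowns;
  Welch t tests (one- and two-tailed); 1.5×IQR box statistics; 2^−ΔΔCt
  qPCR arithmetic.
- **Synthetic data** — a first-class generator planting enhancer
  clusters, typical constituents, promoters, gene bodies and
  heterochromatin on a toy genome, with Poisson ChIP-seq reads and
  negative-binomial knockdown RNA-seq counts.

## Worked example

The five drivers under `analysis/` run the study end to end on the
default conditions (20 Mb genome, 10^6 reads per factor, master seed 1;
set `SMCREG_SEED` to change it):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_occupancy_regions.R
Rscript analysis/04_super_enhancers.R
Rscript analysis/05_expression_sensitivity.R
```

prints, among other things:

```
genome: chr1=10Mb, chr2=10Mb; 20 SE clusters, 300 typical constituents, 380 genes, 10 heterochromatin domains
CAPH2 density at enhancers is 1693x heterochromatin (2.016 vs 0.0012 RPM/bp); SMC1 1814x
20 super-enhancers vs 300 typical; planted recovery 100%, typical misclassified 0.0%
CAPH2: 18.2-fold more signal at super-enhancers, 2.48-fold denser at their constituents
Spearman CAPH2 #1 vs #2: 0.807; CAPH2 avg vs SMC1: 0.676
CAPH2 knockdown: SE-gene median lfc -0.85 vs TE-gene -0.20 (Welch two-tailed p = 1.17e-03)
```

Reading those numbers: condensin II and cohesin coverage concentrates at
active enhancers/promoters and is essentially absent from
heterochromatin; the ranked-signal cutoff recovers every planted
super-enhancer with no typical enhancer misclassified; SMC signal is
~2.5-fold denser at super-enhancer constituents (the planted ratio) and
~18-fold higher in total per super-enhancer, because super-enhancers are
also much wider; the two CAPH2 hairpins agree more with each other than
with the SMC1 knockdown; and super-enhancer-associated genes drop
significantly more on knockdown than typical-enhancer genes. Each
driver writes its tables under `results/`.

The same chain is available in one call:

```r
library(smcreg)
summary <- run_pipeline(default_config(seed = 1), outdir = "results/run")
```

which also writes `summary.json` plus an MD5 manifest that
`verify_manifest()` re-checks.

## Layout

- `R/` — the package: simulator, coverage/occupancy, region classes,
  metagenes, super-enhancers, rank normalization, expression statistics,
  pipeline.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — oracle-backed unit and property tests, plus the
  end-to-end recovery checks in `test-acceptance.R`.
- `vignettes/smc-occupancy-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter defaults and rationale, numerical choices,
  limitations.
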