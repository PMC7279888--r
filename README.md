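# marpipe

Time-resolved differential proteomics of the microglial amyloid response.

`marpipe` is an R package for label-free quantification (LFQ) proteome
time courses from amyloidosis mouse models: microglia sampled at a
pre-deposition age and three post-deposition ages (1, 3, 6, 12 months) in
two models (an overexpression line such as APPPS1 and a knock-in line
such as APP-NL-G-F), three transgenic and three wild-type animals per
age and model. It is written for proteomics/neuroimmunology analysts who
have protein-group intensity tables and want staged, model-independent
"amyloid response protein" (MARP) calls with controlled error rates —
plus a fully synthetic replica of the study design so every stage of the
pipeline can be verified against planted ground truth.

## The statistical core

For each (model, age) contrast, on log2 LFQ intensities:

* consistency filter: only proteins quantified in **all** six samples of
  the age group are tested (no imputation);
* per-age-group median normalization (columns centred to the batch
  median-of-medians over mutually observed proteins);
* log2 fold change `mean(TG) − mean(WT)`, two-sided pooled Student
  t-test, and the s0-moderated statistic

  `d = (mean(TG) − mean(WT)) / (se_pooled + s0)`,  `s0 = 0.1`;

* permutation-based FDR: genotype labels are shuffled (all 18 informative
  assignments of a 3 vs 3 design are enumerated exactly), the estimated
  FDR at cutoff `c` is
  `mean_shuffles #{null |d| ≥ c} / max(1, #{obs |d| ≥ c})`,
  and the smallest cutoff with estimated FDR ≤ 5% defines the
  significance flags;
* regulation call: `|log2 FC| > 0.5` **and** `p < 0.05` **and**
  FDR-significant.

Proteins are then staged in the reference model — **early** (regulated at
3, 6 and 12 months, same direction), **middle** (6 and 12 only),
**advanced** (12 only) — and kept as MARPs when the second model shows
same-direction regulation at any staging age (later onset allowed).
Downstream modules classify proteome–transcriptome concordance
(unidirectional / inverse / protein-only / transcript-only), run
hypergeometric term enrichment against a custom background of
consistently quantified proteins (cluster score `−log10` geometric mean
p, threshold 1.301), and process LCO emission spectra of amyloid plaques
(max-normalization, interpolated 502 nm / 588 nm peak ratio, 20 plaques
per animal, animal-level t-test).

## Worked example

A complete synthetic study (2000 proteins, planted effects of 1–3 log2
units, noise SD 0.3, one-age onset lag in the knock-in model), analyzed
end to end:

```r
library(marpipe)
cfg <- run_config(
  sim = simulation_config(n_proteins = 2000, effect_size_range = c(1, 3)),
  seed = 42
)
report <- run_all(cfg)
report
#> pipeline run report
#>   contrasts:
#>   model age_months n_tested n_up n_down
#>  APPPS1          1     1723    0      0
#>  APPPS1          3     1807   11     11
#>  APPPS1          6     1739   27     36
#>  APPPS1         12     1807   79     87
#>   APPKI          1     1855    0      1
#>   APPKI          3     1796    1      0
#>   APPKI          6     1766   11      7
#>   APPKI         12     1761   77     88
#>   MARPs: 19 early, 27 middle, 75 advanced
#> recovery report
#>   sensitivity: early 0.679, middle 0.510, advanced 0.620
#>   sensitivity (stageable universe): early 0.864, middle 0.867, advanced 0.872
#>   direction accuracy 1.000 | FDP 0.0000 | called 121
```

Reading this: the pre-deposition (1-month) contrasts are null, as they
should be; the reference model responds earlier and more broadly than the
lagged knock-in model at 3–6 months; both converge by 12 months. Of the
planted staged proteins that survive the consistency filter at every
staging age ("stageable universe"), ~86–87% receive their exact planted
stage, every recovered protein has the correct direction, and no true
null protein was called (empirical FDP 0). The lower unrestricted
sensitivities show how much signal left-censored missingness removes
before testing even begins.

Enrichment of a 4-gene query in a 10-gene set against a 2000-protein
background:

```r
coll <- gene_set_collection(list(demo = sprintf("GENE%d", 1:10)),
                            background = sprintf("GENE%d", 1:2000))
term_enrichment(sprintf("GENE%d", 1:4), coll)[, c("term", "k", "m", "n", "N",
                                                  "fold_enrichment", "p_value")]
#>   term k  m n    N fold_enrichment     p_value
#> 1 demo 4 10 4 2000             200 3.15947e-10
```

With `out_dir` set, `run_all()` writes the normalized matrices, one CSV
per contrast, the MARP table, concordance classes and the ground truth as
plain-text artifacts, byte-identical across reruns with the same seed.

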