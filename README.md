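# seqaffinity

Sequence-based classification and estimation of heterodimeric
protein-complex binding affinity.

Binding strength of a protein–protein interaction is summarized by the
dissociation constant Kd; complexes with Kd < 10⁻⁸ M are conventionally
called high-affinity, those with Kd ≥ 10⁻⁸ M low-affinity, and
pKd = −log₁₀(Kd) is the usual working scale. `seqaffinity` predicts the
affinity class, and estimates pKd, of a two-chain complex **from its chain
sequences alone** — no structure required. It is aimed at protein
engineers and interactomics groups who need a fast triage of candidate
complexes, and at methodologists studying which amino-acid properties
carry affinity signal.

## The method

1. **Encoding.** A complex is mapped to a fixed-length vector of *total
   physicochemical properties*: for each per-residue scale *p* (an
   AAindex-style table of 20 numbers),

   TPCP(p) = Σᵢ w(aᵢ) · PCPₚ(aᵢ),

   where w(aᵢ) is the fraction of amino acid aᵢ over both chains
   concatenated. The encoding is independent of residue order and chain
   labelling. Candidate pools of ~580 scales (AAindex plus literature
   descriptors) are supported; features are rescaled to [−1, 1] on
   training data.

2. **Selection.** An inheritable bi-objective combinatorial genetic
   algorithm (IBCGA) selects a small subset of r = 10…20 scales jointly
   with the cost C and RBF width γ of a support vector machine (both
   encoded as 4-bit genes over the grid 2⁻⁷ … 2⁸). Fitness is stratified
   10-fold cross-validation accuracy; recombination is orthogonal-array
   (L8) crossover with main-effect composition; stages inherit solutions
   from r to r + 1.

3. **Evaluation.** Pooled-confusion cross-validation, stratified 75/25
   holdout (162/54 on a balanced 216-complex set), ROC/AUC, and
   leave-one-out (jackknife) support vector regression of pKd with
   Pearson r and mean absolute error.

4. **Interpretation.** Knock-out difference accuracy (drop when one
   selected scale is removed), orthogonal-design main-effect difference
   (MED) ranking, and per-class amino-acid composition and property-mean
   comparisons.

A synthetic-data generator with planted informative scales makes every
claim testable offline; see the methods vignette
(`vignettes/seqaffinity-methods.Rmd`) for the model, parameter and
design details.

## Worked example

```r
library(seqaffinity)

# a synthetic benchmark: 60 complexes, 10 candidate scales, 3 planted
ds <- generate_dataset(n_complexes = 60, n_properties = 10,
                       n_informative = 3, effect_size = 2, seed = 7)
x  <- encode_dataset(ds$records, ds$tables)

# classify on the planted scales
cross_validate(x[, ds$truth$informative], ds$records$label,
               k = 10, cost = 8, gamma = 0.5, seed = 3)
#> <metrics_report> TP=28 TN=28 FP=3 FN=1
#>   accuracy    93.33%
#>   sensitivity 0.966   specificity 0.903
#>   MCC 0.869   AUC 0.970

# estimate pKd by jackknifed SVR
jackknife_regress(x[, ds$truth$informative], ds$records$pkd,
                  cost = 32, gamma = 0.5, epsilon = 0.01)
#> <regression_report> n=60  Pearson r=0.891  MAE=0.882 pKd
```

The classifier separates the two affinity classes well (93% pooled CV
accuracy, AUC 0.97) because three planted scales carry a 2-pooled-SD
class separation; the regression is noisier (r ≈ 0.89, MAE ≈ 0.9 pKd
units) because the generated pKd carries 1 pKd unit of noise. A full-scale run (580 scales, 200 complexes) with
`run_ibcga(fit_scaling(x), labels, search_config(seed = 1))` finishes in
a few minutes on one core and reports the selected scales, decoded C/γ
and the per-stage bests.

The same pipeline is scriptable from a shell via
`inst/scripts/seqaffinity.R` with the commands `simulate`, `encode`,
`select`, `evaluate` and `knockout`; every command writes a JSON manifest
of its resolved parameters, and all randomness flows from `--seed`.

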