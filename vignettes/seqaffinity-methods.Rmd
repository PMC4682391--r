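---
title: "Methods: sequence-based binding-affinity prediction with seqaffinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based binding-affinity prediction with seqaffinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqaffinity)
```

## The problem

The strength of a protein--protein interaction is summarized by the
dissociation constant Kd (molar); smaller Kd means tighter binding, and
pKd = -log10(Kd) is the usual log scale. Measuring Kd is slow and
expensive, and structure-based predictors need a solved complex.
`seqaffinity` addresses the harder, cheaper setting: predict, from the two
chain sequences of a heterodimeric complex alone, whether the complex
binds with high affinity (Kd < 1e-8 M) or low affinity (Kd >= 1e-8 M),
and estimate its pKd.

## Encoding: total physicochemical properties

A complex of two chains of arbitrary length is mapped to a fixed-length
vector. For each per-residue property scale `p` (an AAindex-style table of
20 numbers, one per amino acid), the feature is the composition-weighted
sum

$$\mathrm{TPCP}(p) = \sum_{i=1}^{20} w(a_i)\, \mathrm{PCP}_p(a_i),$$

where `w(a_i)` is the fraction of amino acid `a_i` in the concatenation of
both chains. Three conventions are fixed here:

* the composition is computed over both chains together, yielding one
  vector per complex and making the feature independent of residue order
  and of which chain is called A or B;
* `w` is a fraction summing to 1 (not a percentage) --- the downstream
  [-1, 1] rescaling makes the choice immaterial to the classifier, but a
  convention must be fixed;
* nonstandard letters (X, B, Z, U, `*`) are removed before anything else,
  and a complex is dropped when either sanitized chain is shorter than 50
  residues (chains of exactly 50 are kept). Short-chain fragments behave
  more like peptides than folded domains and would distort the
  composition statistics.

Features are rescaled per column to [-1, 1] by an affine map fit on
training data only (minimum to -1, maximum to +1; constant columns map
to 0). Values of test complexes outside the training range are clipped.
Fitting the scaling on the training part of every fold avoids information
leaking from held-out complexes; whether one fits it once globally or per
fold changes results only marginally, but the per-fold choice is the
defensible one and is what `cross_validate()` does.

The candidate pool in the benchmark setting is 580 scales: 531 AAindex
properties plus 49 physicochemical, energetic and conformational
descriptors from the protein-folding literature. The package parses the
AAindex1 flat-file dialect directly (entries delimited by `//`, values in
the order A R N D C Q E G H I / L K M F P S T W Y V); entries with `NA`
values are skipped rather than imputed, because the encoding needs a
value for every amino acid. Three scales that recur in the affinity
literature are packaged: a buried-hydrophobicity scale (GUYH850105,
apparent partition energies from the Chothia buried-molar-fraction
index), Sneath's principal component IV (SNEP660104, associated with
hydrogen-bonding capacity), and the Chou--Fasman beta-turn propensity
(CHOP780101).

## Feature and parameter selection: the inheritable bi-objective GA

Selecting `m` informative scales out of `n = 580` jointly with the SVM
parameters is a combinatorial problem C(n, m). The chromosome is a
580-bit feature mask plus two 4-bit genes decoding the SVM cost C and RBF
width gamma onto the 16-value grid 2^-7 .. 2^8. Fitness is the stratified
10-fold cross-validation accuracy of the radial-basis SVM on the masked
columns, averaged over two independent fold assignments derived
deterministically from the run seed: wrapper selection over hundreds of
candidate columns will exploit any frozen partition's luck, and
replicate averaging halves that single-partition bias while doubling
the resolution of the score. The bi-objective ordering is lexicographic
(higher accuracy first, then fewer features).

One stage of the search holds the subset size `r` fixed. Each generation
produces a small batch of offspring and merges it back into the
population:

1. **Crossover.** Two parents chosen by binary tournament (the better of
   two uniform draws with replacement) recombine through an orthogonal
   design. Positions where the parents differ (mask bits, and each
   parameter gene as an atomic unit) are grouped in order into at most 7
   contiguous factors; each row of the two-level L8 orthogonal array
   defines a candidate child taking every factor from one parent or the
   other; the per-factor main effects (mean fitness at level 1 minus
   level 2) compose a predicted-best child, and the best of the eight
   rows and the composed child wins. Under an additive fitness this
   returns the exact optimum over all parent-level combinations while
   issuing at most 9 evaluations. Rows whose mask drifts off `r`
   selected features are repaired by random bit clears/sets before
   evaluation.
2. **Mutation.** Each individual spawns, with probability
   `mutation_rate`, a mutant offspring: a swap of one selected with one
   unselected feature (size-preserving) and a +-1 step of one parameter
   gene, reflected at the grid boundary. Parents are retained.
3. **Replacement.** The pooled population and offspring are deduplicated
   and truncated to the best `population_size` chromosomes (incumbents
   win ties); slots freed by duplicates are refilled with random
   immigrants. The best individual can never be displaced, so the best
   fitness is non-decreasing within a stage.

After a fixed number of generations the stage best is recorded;
**inheritance** then switches one random additional feature on in every
individual and the search continues at `r + 1`. The run sweeps
`r = 10 .. 20` and reports every stage best plus the overall winner.

The steady-state structure (offspring compete against the pool rather
than replacing it wholesale) is a deliberate design choice with two
motivations. First, budget: a fitness evaluation costs ten SVM fits, so
crossing over every pair of a mating pool each generation would burn
hundreds of evaluations per generation; one structured OA crossover plus
a handful of mutants per generation concentrates the budget where the
design information is. Second, diversity: wholesale tournament
reproduction collapses the population onto one lineage within about ten
generations, after which crossover has nothing to merge; retaining
parents lets lineages that discovered different informative features
coexist until crossover combines them, which is precisely the regime
where orthogonal-array recombination outperforms random cuts. Fitness
values are cached per distinct chromosome, so re-encountered masks are
free. Defaults of population 50, 60 generations per stage, mutation
0.05 and a crossover every other generation let a full 580-feature,
200-complex run finish in a few minutes on one core (roughly
4,000--6,000 distinct evaluations, each costing twenty SVM fits). Fold
assignments are pure functions of `(labels, folds, seed)`, and every
random decision flows from the single config seed, so runs are
byte-reproducible.

## Models and evaluation

Classification uses a C-SVM with RBF kernel (via `e1071`/libsvm);
regression of pKd uses epsilon-insensitive SVR (epsilon default 0.1 pKd
units). The positive class is high affinity. Metrics follow the standard
definitions of accuracy (reported in percent), sensitivity, specificity
and Matthews correlation; an MCC denominator of zero yields 0 (the
standard fallback), whereas sensitivity or specificity without any
positive or negative complex is an error rather than a silent number.
Cross-validation pools the confusion counts over folds and computes the
metrics once on the pooled counts --- the reproducible interpretation
when a single sensitivity/specificity per protocol is reported. The AUC
is the Mann--Whitney statistic of the pooled out-of-fold decision scores
(ties count one half). Holdout evaluation splits 75/25 within each class,
so a balanced 216-complex set gives exactly 162 training and 54 test
complexes (81/27 per class). The jackknife protocol predicts each
complex's pKd from a model trained on the other n-1 and reports Pearson r
and mean absolute error.

## Feature importance

Two distinct procedures are implemented and reported separately, because
they measure different things and differ in magnitude:

* **Knock-out difference accuracy**: the drop in CV accuracy when one
  selected scale is removed, all folds held fixed. It measures the
  marginal, redundancy-aware contribution --- a duplicated column knocks
  out for free.
* **Main-effect difference (MED)**: a two-level orthogonal array over the
  selected scales (level 1 = keep, level 2 = drop; all-drop rows are
  skipped) is evaluated by CV accuracy, and a scale's MED is the mean
  accuracy of designs keeping it minus designs dropping it. This is a
  group contribution score and typically exceeds the knock-out
  difference. The exact published MED procedure is not recoverable from
  its source, so the orthogonal-design definition above is declared as
  this package's operationalization. The Walsh construction supplies
  arrays up to 31 factors; the factor-to-column assignment is exposed so
  ranking stability under re-assignment can be checked.

Compositional analyses compare per-class mean amino-acid composition
percentages (differences sum to zero since each composition sums to
100%) and per-class means of per-complex property scores, optionally
restricted to a residue subset (e.g. hydrophobic residues) and weighted
as a sum or mean, since published per-class statistics use both
conventions.

## The synthetic benchmark generator

Real PDB-derived benchmarks cannot ship with the package, so every
pipeline claim is validated on generated data with known ground truth.
The generator emulates the published study conditions: a balanced
two-class set (default 216 complexes), two chains of 100--300 residues,
580 candidate scales, pKd spanning roughly 3--15 as in published Kd
compilations, and a small planted informative subset (default 5 scales
at effect size 2).

The construction plants structure in composition space, matching the
order-independent encoding. A signal subset S of ten residues carries
the entire class difference: around the uniform composition `p0`, a
shift `delta` supported on S is solved for exactly (a small linear
system, minimum-norm) so that the class profiles `p0 +- delta` separate
the mean TPCP projection of each informative scale by `effect_size`
pooled standard deviations, the pooled SD being the multinomial
composition noise at the expected total chain length. Chains are
sampled letter by letter from the class profile.
pKd is `8 + 1.2 * (effect_size/2) * s + N(0, pkd_noise_sd)` where `s` is
the standardized sum of the informative projections; labels are the Kd
threshold applied to the realized pKd, so labels, Kd and pKd are
consistent by construction, the slope vanishes on a null dataset
(effect 0), and at the default noise of 1 pKd unit a few percent of
complexes land on the "wrong" side of the threshold --- deliberate label
noise emulating borderline affinities.

Because every TPCP feature is a linear functional of the same
20-dimensional composition, naive noise scales would leak: they would
pick up a class-mean difference through `delta`, and --- more subtly ---
class-conditional variance and covariance differences through the
multinomial sampling noise, letting combinations of "noise" columns
reconstruct the class signal. The coordinate split closes all of these
channels at once: non-informative scales are made constant on S (at
their own off-S mean), so their projections depend on the S residues
only through the total S fraction, whose class-conditional mean and
variance are matched by construction; their off-S part is additionally
decorrelated from the informative projections. Noise projections
therefore match across classes in mean, variance and all covariances,
and the residual class dependence is third-order and negligible at
benchmark sizes. The cost is a structured departure from i.i.d. normal
values in the noise scales (they span a lower-dimensional space), which
is immaterial to what the tests assert. What passing tests on this
generator show is that the pipeline recovers planted,
composition-level signal; they do not show that real interface
biophysics (which is structural and order-dependent) is captured, and
no realism beyond composition statistics is attempted.

## Problem sizes used by the test suite

The packaged checks run the encoding oracle on 1,000 random
(composition, scale) pairs; the metric and AUC oracles on 100 random
confusion matrices and score sets; crossover optimality on 200 random
additive-fitness instances; planted recovery on five full-scale searches
(200 complexes, 580 scales, population 50, 60 generations per stage,
r = 10..20); null calibration on 20 datasets of 200 complexes;
knock-out and regression checks on 200- and 60-complex datasets. These
sizes keep a complete run on one core in the tens of minutes while
leaving each check statistically meaningful.

## Known limitations

* Composition-only features ignore residue order, positional motifs and
  interface geometry; published results with this family of methods show
  good class discrimination but weak absolute pKd estimation across
  heterogeneous function classes, and nothing here changes that.
* The GA is stochastic; different seeds can select different,
  near-equivalent feature subsets when scales are correlated (AAindex
  contains many near-duplicates).
* Because the fitness is a deterministic cross-validation score, wrapper
  selection over hundreds of candidate columns optimistically biases the
  reported CV accuracy (replicate averaging halves but does not remove
  this); the selected feature set should always be re-evaluated on an
  independent protocol (holdout or fresh folds), which is what
  `cmd_evaluate` is for.
* Recovery of planted truth saturates. With five informative scales at
  two pooled SDs each and 200 complexes, the marginal accuracy
  contribution of the fourth and fifth informative scale (roughly 0.5--2
  percentage points) falls below the finite-sample resolution of any
  cross-validation estimate, so the fitness landscape plateaus: subsets
  with three planted scales can tie or even beat the full planted set
  under the model's own objective, and the fewer-features tie-break then
  prefers the smaller mask. In that regime the search typically recovers
  three to five of the five planted scales, and which outcome occurs is
  seed luck rather than algorithm quality --- a caution that applies
  equally to interpreting feature lists selected from real benchmarks of
  this size.
* The packaged reference compositions and three scales support
  compositional comparison and worked examples; reproducing the full
  published 14-feature model would require the complete AAindex release
  and the 49 literature descriptors, which users must supply as AAindex1
  files.
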