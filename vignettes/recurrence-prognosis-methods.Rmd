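---
title: "Methods: differential miRNA-target correlation and neural-network recurrence prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential miRNA-target correlation and neural-network recurrence prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurnet)
```

## The analysis problem

After radical prostatectomy for locally advanced prostate cancer, a
subset of patients relapses (biochemical recurrence, BCR: post-operative
PSA at or above 0.2 ng/mL), while others stay recurrence-free (BRF).
Within the molecularly homogeneous TMPRSS2-ERG fusion subtype, miRNA and
mRNA expression in the primary tumor carries prognostic signal. `recurnet`
implements the full analysis chain used to extract that signal from
two-cohort count data:

1. per-cohort differential expression of miRNA counts (TMM/CPM
   normalization, Mann-Whitney testing, BH correction) with a
   direction-consistent cross-cohort intersection;
2. a differential-correlation interactome: for catalog-defined
   miRNA-target pairs, the difference of group Spearman correlations
   (BCR minus BRF) tested by Fisher's r-to-z;
3. hypergeometric over-representation analysis of the network members;
4. a fully connected neural-network classifier of recurrence from
   expression and clinicopathological predictors;
5. qPCR delta-CT relative quantification with group-comparison
   statistics.

Because the original cohorts are not distributable, every stage is
exercised against a synthetic-cohort generator with recorded ground
truth; the generator is itself a first-class, tested module.

## Count normalization and differential expression

`tmm_factors()` implements trimmed-mean-of-M-values scaling: the
reference sample is the one whose upper quartile of library-size-scaled
counts lies closest to the mean upper quartile; per sample, M-values
(log2 expression ratio vs the reference) and A-values (mean log2
abundance) are computed over features nonzero in both samples, the M and
A distributions are double-sided trimmed by 30% and 5% respectively (the
published trimming constants for this procedure), and the scaling factor
is 2 to the inverse-variance-weighted mean of the surviving M-values,
with delta-method binomial weights. Factors are rescaled to geometric
mean 1. `cpm_matrix()` divides by effective library size
(library size x factor); the log variant uses log2(CPM + 1), so a zero
count maps to exactly 0 — the prior count of 1 is a declared,
configurable choice.

Two numerical caveats are deliberate and tested. First, only the
*unweighted* trimmed mean is exactly invariant to scaling one sample's
column by a constant; the default inverse-variance weights depend on
absolute counts, so scale invariance is approximate (the reference
Bioconductor implementation behaves identically, and the two agree to
at least ten significant digits on shared inputs). Second, a sample
sharing fewer than two nonzero features with the reference receives
factor 1 with a warning rather than an error.

`mw_test()` is two-sided Mann-Whitney: the exact permutation
distribution when the pooled sample size is at most 20 and the data are
tie-free, otherwise midranks with tie-corrected variance and continuity
correction (a log note marks the fallback). Fully tied inputs carry no
ordering information and return p = 1. The published DE rule was a
disjunction of a quasi-likelihood F-test and Mann-Whitney at p <= 0.05;
this package implements Mann-Whitney as the criterion and does not
provide a quasi-likelihood substitute, which satisfies the disjunction
while keeping the implementation self-contained. The DE threshold is
applied to the raw p-value (FDR reported alongside), and the fold change
reported per feature is the ratio of group CPM means — the published
tables do not state which estimator they used; this choice is declared
rather than inferred.

Features DE in both cohorts with the same direction form the shared set.
"High and stable expression" is operationalized as: median log2CPM of at
least 1.0 in every group of every cohort and detection (count > 0) in at
least 80% of samples per group. Both thresholds are configurable and
this rule is an interpretation of a qualitative published criterion.

## Differential correlation and the interactome network

For each catalog pair and group, `pair_correlations()` computes Spearman
(midranks) and Pearson correlations on log2CPM, and the adjusted
coefficient of determination 1 - (1 - r^2)(n - 1)/(n - 2) of the simple
regression of target on source. Correlations are computed on
TMM-normalized log2CPM — the expression scale is not stated in the
source methods and is declared here. Selection is driven exclusively by
the Spearman difference delta = r_s(BCR) - r_s(BRF); Pearson and
adjusted R-squared are annotations.

`fisher_z_diff()` tests delta by the r-to-z transform:
z = (atanh r1 - atanh r2) / sqrt(v/(n1-3) + v/(n2-3)), two-sided normal
p. The default variance numerator is v = 1 (classical Fisher); the
Fieller-Hartley-Pearson value 1.06 sometimes recommended for Spearman
correlations is available as a configuration switch. With v = 1 and
Spearman inputs the test is mildly anticonservative; the calibration
suite verifies the null rejection rate at alpha = 0.05 stays within
[0.035, 0.065] at n = 30 per group. Inputs are clamped to magnitude
1 - 1e-7 so perfect sample correlations stay finite; group sizes below 4
are rejected by name of the 1/(n - 3) variance constraint.

Which threshold defines a "differentially correlated" pair (raw p, FDR,
or a minimum |delta|) is genuinely open. The scan defaults to raw
p <= 0.05 with BH-FDR reported. The bundled demo pipeline instead
selects on FDR <= 0.05: with hundreds of catalog pairs scanned
simultaneously, raw-p selection admits about alpha x (number of null
pairs) false edges — with 200 decoy pairs, roughly ten — which would
swamp a 20-pair planted signal at one-third contamination, whereas BH
keeps the decoy fraction of the selected set near alpha. The BH family
is all scanned pairs in one run, not per edge type.

The network keeps the endpoints of selected miRNA-target edges, typed by
catalog role (miRNA, gene, TF, lncRNA), annotated with per-cohort DE
status; PPI, TF-target and lncRNA-target catalog edges between included
nodes are appended with their own correlation annotations. Exports to
GraphML (via igraph), JSON and TSV round-trip losslessly; the GraphML
check in the test suite is structural (well-formed XML in the GraphML
namespace, re-parseable), since offline validation against the external
XML schema is not possible.

## Over-representation analysis

`ora_test()` is the upper-tail hypergeometric probability
P(X >= k) for an overlap of k between a query of n and a set of K in a
universe of N. The universe defaults to the union of all set members
after miRNA extension — the published analysis does not state its
universe, and this default is the most common convention. miRNAs enter
sets only through an explicit annotation table (a file-based stand-in
for live miRNA-pathway databases, keeping runs reproducible offline).
Significance is raw p < 0.05 by default, matching the published rule;
BH adjustment is available by flag. Enrichment p-values are exact, so
no simulation tolerance applies; the test suite sweeps all universes up
to N = 60 against an enumeration oracle.

## The classifier

`fcnn_spec()` defaults to the published architecture: an input layer of
n predictors, seven hidden layers of 150, 120, 90, 60, 40, 30, 20
neurons (the publication gives only the range 20-150 for widths, so the
descending stack is a declared choice), relu activations with a tanh
variant, and a two-neuron softmax output. Training minimizes softmax
cross-entropy — the two-class form of binary cross-entropy — by
backpropagation with mini-batch Adam (beta1 = 0.9, beta2 = 0.999,
epsilon = 1e-8) at the published learning rate 0.003. Epochs (200) and
batch size (8) are not published; both are configurable. Weights are
Glorot-uniform, biases zero, and the shuffle stream is seeded, so
training is bit-reproducible.

Numerical choices: the softmax is computed in log-sum-exp stabilized
form, so loss and gradients are finite for any finite input; the batch
gradient is the *sum* of per-sample gradients (Adam's normalization
makes the sum/mean distinction a learning-rate rescaling, and the sum
makes gradient additivity over duplicated samples exactly testable);
per-predictor center/scale is fitted on training rows only and stored
inside the model, with zero-variance predictors assigned scale 1 under a
warning. Ordinal clinical covariates are encoded ISUP 1-5,
pT {pT3a: 1, pT3b: 2, pT4: 3}, Gleason as its raw score. Hard
classification uses p(BCR) > 0.5, with an exact tie at the threshold
resolved to the recurrence-free class; a Youden-optimal threshold is
reported alongside for transparency.

Analytic gradients are verified against central finite differences
(step 1e-5) to a relative error below 1e-5 as part of the test suite.

## Evaluation

`confusion_metrics()` reports sensitivity, specificity, precision and
Cohen's kappa (marginal-product chance agreement); undefined ratios
surface as NaN with a warning rather than silent zeros. `roc_auc()`
sweeps the unique score thresholds and integrates by the trapezoid rule,
which makes the AUC identical to the pairwise concordance statistic
(ties counting one half); the identity is property-tested, as are
monotone-transform invariance and the label-swap duality Se <-> Sp,
AUC -> 1 - AUC.

One worked example is reconstructable from the published validation
metrics alone: a test split of 17 samples with sensitivity 0.89 and
specificity 1.00 admits a unique integer confusion matrix
(TP = 8, FN = 1, TN = 8, FP = 0), whose kappa is 0.88 to two decimals.
The package recovers this number exactly; the headline discrimination
(AUC about 0.94) is reproduced in spirit on synthetic cohorts, since the
original expression data are not distributable.

## qPCR relative quantification

Technical triplicates are averaged arithmetically per (sample, assay);
delta-CT is taken against the matched control assay (control gene for
mRNA targets, control miRNA for miRNA targets) and relative expression
is 2^(-dCT), computed per sample before any group summary — the
alternative (exponentiating a group-mean delta-CT) is not used, a choice
the source leaves open. Fold change between groups is the ratio of
group medians (robust at n near 30; mean ratio by flag), tested by
Mann-Whitney, and the Spearman correlation against the binary group
indicator is reported with its p-value. Assays whose Mann-Whitney p
exceeds 0.05 are flagged excluded, mirroring the rule that removed a
non-validating marker from the published model. No replicate outlier
rejection is applied by default.

## The synthetic-cohort generator

The generator defines the study conditions for every test:

* **Counts.** Negative binomial marginals; per-feature baseline means
  lognormal (meanlog 4, sdlog 1.5, i.e. a median of about 55 counts with
  a heavy right tail), per-feature dispersions gamma(2, 20) (mean 0.1,
  typical of bulk RNA-seq), and lognormal per-sample library-size
  factors with CV 30% so TMM normalization is exercised nontrivially.
  No simulation recipe is published; these are declared test conditions,
  chosen for statistical power rather than fidelity to the original
  cohorts.
* **Planted differential expression.** A configurable fraction of
  leading features (default 10%) receives a multiplicative fold change
  (default 3, within the range of the published DE tables), alternating
  up/down, applied to the BCR group mean.
* **Planted correlations.** miRNA-mRNA pairs are drawn per group through
  a Gaussian copula: latent bivariate normal with correlation rho mapped
  through NB quantile functions. The implied population Spearman
  correlation has the closed form (6/pi) asin(rho/2), which is the
  documented, testable target; defaults rho(BCR) = 0.8 vs
  rho(BRF) = -0.2 plant a correlation flip of about 0.98 on the Spearman
  scale. Planted pairs live outside the DE block so the two signals stay
  unconfounded.
* **Clinical covariates.** Group labels are fixed and balanced; ISUP,
  pT, Gleason and log-PSA are drawn from label-shifted latent-normal
  models whose baseline category frequencies follow the published
  cohort tables. Shifting covariates given the label is the
  Bayes-equivalent of drawing labels from a logistic model given
  covariates, and keeps group sizes exact.
* **CT tables.** CT = intercept - slope x log2(expression) + noise,
  three replicates, slope 1 (100% PCR efficiency) and replicate noise
  SD 0.15 cycles by default — the publication states neither; both are
  configurable.

What the generator does **not** emulate: read-level sequencing error,
batch effects, GC/length biases, cohort-specific library-size
distributions, or miRNA-target regulation mechanisms (correlations are
planted directly, not through a kinetic model). Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under
controlled conditions — not that the biological conclusions of any
particular cohort transfer.

## Pipeline and reproducibility

`run_pipeline()` executes simulate, de, diffcor, ora, train, evaluate
and qpcr stages with file-based handoff (TSV/JSON/GMT/CSV) in a single
output directory, and writes a manifest of MD5 content hashes plus the
configuration snapshot and seed; identical configuration and seed
reproduce identical hashes. All stage randomness derives from the one
global seed through a fixed hash of the stage name, so stages can be
rerun independently. The thin command-line front end in
`inst/cli/recurnet.R` exposes the stages as subcommands over a YAML
configuration.

Problem sizes used by the bundled demo configuration — 30 samples per
group, 120 miRNAs x 240 mRNAs, 20 planted pairs among 200 decoys, and a
six-predictor classifier trained on 200 samples — are the package's
declared study conditions for its end-to-end demonstrations; the test
suite verifies planted-signal recovery at >= 80% with <= 10% decoy
contamination and held-out AUC >= 0.95 under them.

## Known limitations

* The quasi-likelihood F-test arm of the published DE rule is out of
  scope; only Mann-Whitney drives DE calls.
* Fisher's r-to-z on Spearman coefficients with v = 1 is approximate;
  its mild anticonservatism is quantified but not corrected by default.
* ORA treats sets as flat (no topology, no redundancy pruning), and the
  universe convention is a declared default.
* The classifier offers no regularization, early stopping or
  hyperparameter search; it reproduces a fixed published recipe.
* qPCR quantification assumes 100% amplification efficiency
  (no efficiency-corrected model) and no plate/batch normalization.
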