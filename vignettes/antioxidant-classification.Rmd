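---
title: "Classifying antioxidant proteins from sequence descriptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying antioxidant proteins from sequence descriptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(antioxrf)
```

## The problem

Experimentally verified antioxidant proteins are rare. A curated benchmark
in this area holds on the order of 250 positives against 1550 negatives —
roughly 1:6 — and that imbalance is the central statistical difficulty: a
classifier that optimizes raw accuracy can ignore the minority class almost
entirely and still score well. Since the positives are the biologically
interesting class, the pipeline in this package is organized around
recovering *sensitivity* without giving up specificity, using only the
primary sequence (no predicted secondary structure, whose errors and cost
this approach deliberately avoids).

## The model

### Sequence descriptors

**CKSAAP** (composition of k-spaced amino-acid pairs). For gap $k$, every
position $j$ pairs residue $A_j$ with residue $A_{j+k+1}$; a sequence of
length $N$ contributes $N-k-1$ such windows ($N-4$ at the default $k=3$).
With the 20-letter alphabet in the fixed order `ACDEFGHIKLMNPQRSTVWY`,
the descriptor is

$$ f_i = \frac{n_i}{N-k-1}, \qquad i = 1,\dots,400 $$

where $n_i$ counts windows showing the $i$-th ordered pair (pair index
$20\,\mathrm{rank}(a) + \mathrm{rank}(b)$; the alphabet order and index
formula are conventions this package fixes and documents, since only the
dimensionality is canonical). The 400 frequencies are non-negative and sum
to exactly 1 — a conservation property the test suite asserts on random
sequences. One gap value is used by default (400 columns); multiple gaps
concatenate.

**Conjoint triad (CT).** Residues are first collapsed to 7 classes by
side-chain dipole and volume — 1:{A,G,V}, 2:{I,L,F,P}, 3:{Y,M,T,S},
4:{H,N,Q,W}, 5:{R,K}, 6:{D,E}, 7:{C} — and the $7^3 = 343$ class triads
are counted over the $N-2$ consecutive windows, giving counts $v_i$
normalized as

$$ d_i = \frac{v_i - \min_j v_j}{\max_j v_j}. $$

The denominator is $\max v$, not $\max v - \min v$: that is the printed
form of the descriptor's normalization, and the package implements it
literally (`ct_norm = "max"`), with `"range"` available as a switch. Both
keep $d_i \in [0,1]$. The triad index is lexicographic,
$(c_1-1)\cdot 49 + (c_2-1)\cdot 7 + c_3$ — again a convention fixed here
because only the 343-dimensional layout is canonical.

Combined, CKSAAP-then-CT gives 743 named columns. Sequences shorter than
$\max(k+2, 3)$ are rejected with the offending record named, never
zero-padded; records containing non-standard letters (B, X, Z, and equally
J, O, U, gaps, stops — the exclusion list is exemplary, and the
descriptors are undefined for all of them) are dropped with a log message
during dataset loading, or abort with an error in strict mode.

### Imbalance correction

Only the training split is ever resampled; the driver keeps the test set
out of this stage by construction. Two methods are implemented from their
standard definitions:

- **SMOTE**: each synthetic minority point is
  $x_{new} = x_i + u\,(x_{nn} - x_i)$ with $u \sim U(0,1)$ and $x_{nn}$
  one of the $k=5$ nearest minority neighbors of $x_i$ (Euclidean distance
  on raw feature values, which are already frequency-scaled in $[0,1]$;
  $k=5$ is the descriptor's de facto default). Originals pass through
  byte-identical; synthetic rows are flagged in their sample ids.
- **Random undersampling**: seeded uniform subsampling of the majority
  class without replacement.

At the default 1:1 target a 200/1500 training matrix becomes 1500/1500
(SMOTE) or 200/200 (undersampling). The fancier resamplers of the
imbalanced-learning family (ADASYN, Borderline/SVM-SMOTE, ClusterCentroids,
NearMiss, SMOTEENN, SMOTETomek) are out of scope here.

### MRMD feature ranking and incremental selection

Each feature $F_i$ gets a score $\mathrm{MRMD}_i = MR_i + MD_i$:
$MR_i = |\mathrm{PCC}(F_i, C)|$ is relevance to the class vector $C$, and
$MD_i = \frac{1}{M-1}\sum_{k \ne i} \mathrm{ED}(F_i, F_k)$ is the mean
Euclidean distance (across samples) to the other feature columns —
distance as an independence proxy: the larger, the less redundant.

Two numerical choices deserve note:

- *Scaling.* $MR$ is bounded by 1 while raw $MD$ grows with sample count,
  so the sum is only commensurate if columns are first min–max scaled to
  $[0,1]$; that is the default (`scale = "minmax"`), with `"none"`
  reproducing the literal unscaled formula. Zero-variance columns get
  $MR = 0$ (the correlation is undefined there) and scale to a constant
  zero column, so they remain rankable by distance alone.
- *Distance computation.* Column distances are computed by direct summation
  of squared differences rather than the faster
  $\|a\|^2+\|b\|^2-2\langle a,b\rangle$ identity, which loses enough
  precision to cancellation ($\sim 10^{-8}$ relative) to perturb score
  ties; the test suite pins the implementation to a naive double-loop
  oracle at $10^{-12}$.

Ranking sorts by score descending with stable tie-breaking in original
column order. Selection then walks the ranking in prefixes of `step`
features, evaluating each prefix by stratified cross-validated
random-forest accuracy on folds fixed once per call, and returns the
*smallest* prefix attaining the maximal accuracy. The full set is always
evaluated, so the chosen accuracy can never undercut it. `step = 1`
reproduces the one-feature-at-a-time search; the package's end-to-end runs
use `step = 10` and 3 inner folds, which trades resolution of the accuracy
curve for an order-of-magnitude fewer forest fits — the selection plateau
on planted-signal data is broad, so the chosen subsets barely differ.

### Classifier and evaluation

The forest (ranger backend, single-threaded, seeded, 100 trees, unlimited
depth, $\sqrt{M}$ features per split — all configurable) scores a sample
as the *fraction of trees voting positive*, matching a vote-based
classifier; hard calls use a 0.5 vote threshold while ROC/AUC sweep all
thresholds. Metrics are implemented from their definitions:
$Sn = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Acc$, $F = 2TP/(2TP+FN+FP)$ and
MCC, with the standard convention that a zero denominator factor yields 0.
AUC is the trapezoidal area under the (1−Sp, Sn) curve with tied scores
crossing simultaneously — provably equal to the normalized Mann–Whitney
$U$ with half-weight ties, which the tests verify exhaustively on random
cases and against pROC. Every `evaluate()` call also asserts the identity
$Acc = (Sn\cdot P + Sp\cdot N)/(P+N)$ internally. Model evaluation uses
10-fold stratified cross-validation by default (folds preserve the class
ratio to within one sample) plus an independent test set.

## The synthetic generator

`generate_sequences()` draws residues i.i.d.: negatives from a uniform
background over the 20 residues, positives with the hydrophobic residues
A,G,V,I,L,F,P (CT classes 1–2) upweighted by a multiplicative
`enrichment` factor, default 3, lengths uniform on 50–300. This mirrors
the empirical signature that hydrophobic-residue triads are
over-represented in antioxidant proteins, and creates signal in both
descriptor families at once. Per-residue i.i.d. generation is a deliberate
simplification: real proteins have Markovian local structure, motifs,
families and homology, none of which the generator emulates. Passing tests
therefore demonstrate that the pipeline recovers a planted compositional
signal under realistic class imbalance — not that it matches any published
performance on curated data. `benchmark_shape_dataset()` presets the
benchmark shape: 253/1552 generated, split 200/1500 train and 53/52 test
with disjoint ids; with enrichment 1 the two classes are identically
distributed and end-to-end accuracy sits at chance, which the tests also
check.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains simulate/load → validate → extract → rebalance →
rank/select → train → evaluate from one YAML config. A single global seed
fans out as `seed + stage_index` so each stage is independently
reproducible; every artifact (`ranked.csv`, `subset.txt`, `model.rds`,
`report.json`, `roc.csv`, `run.log`) carries the config MD5 and seed, and
identical configs produce identical reports. Configuration errors are
aggregated and reported together before any work starts.

The shipped end-to-end checks run the benchmark shape (1805 sequences,
743 features, SMOTE to 3000 training rows) with selection at `step = 10`,
3 inner folds and 100 trees, five seeds for the SMOTE-versus-baseline
sensitivity comparison — sizes chosen so a full verification pass
completes in minutes on a single core while leaving the selection plateau
clearly resolved.

## Known limitations

- The generator's i.i.d. residues make the planted signal easier than real
  homology-structured data; absolute metric values on synthetic data do
  not transfer to curated benchmarks.
- SMOTE interpolates in the raw 743-dimensional descriptor space; in very
  high dimensions interpolated points concentrate near their parents,
  which weakens (but does not remove) the oversampling effect.
- Only Euclidean distance is offered for the MRMD distance term, and only
  the F1 form of the F-score is implemented.
- The incremental search evaluates prefixes of one fixed ranking; it does
  not revisit earlier features (no floating selection).
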