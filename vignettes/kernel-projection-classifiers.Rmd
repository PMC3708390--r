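---
title: "Three-dimensional kernel projection classifiers: models, choices and limits"
author: "kernelField"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-dimensional kernel projection classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelField)
```

## The method in one paragraph

`kernelField` classifies samples described by numeric feature vectors —
canonically the 20-dimensional amino-acid composition of a protein domain —
by first projecting them into a low-dimensional kernel feature space
(three dimensions by default) and then deciding the class *in that space*,
either by a K-nearest-neighbour vote or by a Coulomb-style *class intensity*
model: every projected training sample is treated as a point charge of
magnitude $\mathrm{EQPC}_C = 1/n_C$ (so each class carries unit total
charge), the field intensity of class $C$ at a query point $x$ is

$$\mathrm{IEFP}_C(x) \;=\; \sum_{i \in C} \frac{\mathrm{EQPC}_C}{r_i^2},
\qquad r_i = \lVert x - z_i \rVert,$$

and the class with the largest intensity wins. Two projections are
available: kernel principal component analysis (KPCA), which is
unsupervised, and kernel generalized discriminant analysis (GDA), a
kernelised Fisher discriminant. The package adds the scaffolding a real
analysis needs: range scaling, a leave-one-out cross-validation (LOOCV)
harness, a two-stage hierarchical pipeline for membrane-protein typing,
seeded synthetic generators, and a command-line interface.

## Kernels

Four kernels are supported, evaluated by `kernelEval()` /
`kernelMatrix()`:

| name | form |
|------|------|
| linear | $\langle x, y\rangle + \theta$ |
| polynomial | $(\langle x, y\rangle + \theta)^d$ |
| rbf | $\exp(-\lVert x-y\rVert^2 / \sigma^2)$ |
| sigmoid | $\tanh(v\langle x, y\rangle + r)$ |

Note the rbf denominator: it is $\sigma^2$, **not** the $2\sigma^2$ used by
several other libraries. A width quoted here as $\sigma = 0.5$ therefore
corresponds to `gamma` $= 1/\sigma^2 = 4$ in the $\exp(-\gamma d^2)$
parameterisation. The sigmoid kernel does not satisfy Mercer's condition
for all $(v, r)$; `kernelMatrix()` warns when a sigmoid self-kernel is
indefinite but lets it through, since the downstream eigendecompositions
simply discard non-positive directions.

## Kernel PCA

With kernel matrix $K$ of the $n$ training samples, KPCA solves the dual
eigenproblem $\lambda\,\alpha = \tfrac{1}{n} K \alpha$ and keeps the top
$k$ eigenpairs. Dual coefficient vectors are rescaled to give each
feature-space direction unit norm, $\alpha^\top K \alpha = 1$; with a
linear kernel ($\theta = 0$) and centering this makes the training scores
*equal* classical PCA scores up to per-component sign, a property the test
suite asserts against an independent covariance-eigendecomposition oracle.

**Centering.** The PCA derivation assumes the mapped data have zero mean in
feature space, which for a kernel matrix means double centering,
$K \mapsto K - \mathbf{1}K - K\mathbf{1} + \mathbf{1}K\mathbf{1}$ with
$\mathbf{1} = \tfrac1n 11^\top$. `fitKPCA()` centers by default and applies
the matching rectangular formula to test kernels; `center = FALSE` is
provided for the literal uncentered variant, because published
kernel-projection analyses do not always state which was used. Both
behaviours are tested.

**Determinism.** Eigenvector signs are arbitrary in exact arithmetic, so
each component's sign is fixed by requiring its largest-magnitude dual
coefficient to be positive (first index wins ties). Together with LAPACK's
deterministic symmetric solver this makes every fit bit-reproducible.

## Kernel GDA

GDA maximises the Fisher ratio in feature space via the dual criterion

$$\lambda \;=\; \frac{\alpha^\top K D K \alpha}{\alpha^\top K K \alpha},$$

where $D$ is block diagonal with one $n_c \times n_c$ block of entries
$1/n_c$ per class. Three numerical decisions matter:

1. **Reduced eigenbasis.** The denominator $\alpha^\top KK\alpha$ is
   singular whenever $K$ is rank deficient, so the problem is solved in the
   eigenbasis of $K$: eigenvalues below $10^{-10}$ of the largest are
   discarded, the reduced symmetric problem $P^\top D P\, y = \lambda y$ is
   solved there, and $\alpha = P\Gamma^{-1} y$ maps back. This is the
   standard stable route in the kernel-discriminant literature.
2. **Feature-space centering.** The kernel matrix is centered before the
   eigendecomposition. $D$ is a rank-$C$ projector whose range contains the
   constant vector; on an *uncentered* kernel matrix the leading
   "discriminant" can simply be the grand-mean direction, the criterion
   admits $C$ rather than $C-1$ informative directions, and the two-class
   linear-kernel limit no longer reproduces Fisher LDA (the total-scatter
   denominator picks up an $n\,\bar m \bar m^\top$ term). Centering
   restores all three properties — at most $C - 1$ discriminants, exact
   LDA ordering in the linear two-class limit (asserted against the
   $S_W^{-1}(m_1 - m_2)$ oracle), and Fisher ratios in $[0, 1]$ sorted
   descending — and matches the zero-mean assumption of the discriminant
   analysis this construction derives from.
3. **Normalisation.** Discriminant directions get unit feature-space norm
   ($\alpha^\top K \alpha = 1$), the same convention as KPCA. Downstream
   KNN/intensity classification depends on this scaling, so it is fixed
   rather than left free.

With a full-rank kernel (rbf on distinct samples) the top Fisher ratios
saturate at 1 and training classes collapse to near-points in the
projection — the familiar capacity of kernel discriminants. LOOCV, which
refits without the held-out sample, is the honest measure of whether that
separation generalises.

## Decision rules and their conventions

**KNN.** Euclidean distances in the projected space; majority vote among
the $K$ nearest. Ties are resolved deterministically: smallest summed
distance among the tied classes' neighbours, then lowest class index.

**Class intensity.** $\mathrm{IEFP}_C$ as above. Two situations the
inverse-square law leaves undefined are fixed by convention:

* $r \to 0$: a query within `epsilonCoincide` ($10^{-12}$ by default) of a
  training point takes that point's class directly — the limit of the
  diverging field, and what makes no-refit LOOCV well defined.
* exact intensity ties: lowest class index, reported via `message()`.

Useful identities, all property-tested: $\mathrm{EQPC}_C \cdot n_C = 1$;
scaling all coordinates by $s$ multiplies every intensity by $1/s^2$ and
never changes the argmax; with all class-$C$ points coincident the
intensity is independent of $n_C$ (charge halves as count doubles).

## Scaling and the LOOCV protocol

All inputs are range-scaled to $[0,1]$ per feature by default,
$(x - \min)/(\max - \min)$. The scaler is fitted on the training fold
*only*; held-out samples are transformed and clipped into $[0,1]$
(extrapolation would hand unbounded arguments to the kernels). Constant
training features map to 0.

`loocv()` refits the entire pipeline — scaler, projection, classifier —
for every fold (`refit = TRUE`). Published analyses do not always state
whether the projection was refitted per fold, so `refit = FALSE` offers
the other reading: fit once on all samples and hold each sample out of the
vote or field only. The leakage-free refitting mode is the default; the
report records the configuration used.

## Shipped presets

| preset | projection | kernel | rule |
|--------|-----------|--------|------|
| `datasetA` | KPCA | rbf $\sigma=0.5$ | KNN $K=3$ |
| `datasetB` | GDA | polynomial $d=4$, $\theta=1.5$ | intensity |
| `membrane-stage1` | KPCA | polynomial $d=2$, $\theta=0.1$ | KNN $K=5$ |
| `membrane-stage2` | GDA | rbf $\sigma=5$ | intensity |

The two membrane presets combine into the two-stage hierarchical pipeline
(`hierarchicalConfig()`): stage 1 separates the multipass-transmembrane
class from everything else; only samples routed to "rest" are classified
among the remaining types by stage 2. A stage-1 target call is final, and
stage 2 is not even fitted when nothing is routed to it.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of their parameters and a mandatory
seed.

* `makeGaussianBlobs()`: isotropic clusters with controllable separation;
  separation 0 collapses to chance level, a calibration the tests use.
* `makeConcentricShells()`: noisy hyperspheres of distinct radii — the
  canonical linearly-inseparable, radially-separable structure KPCA exists
  for. The ambient dimension defaults to 25, deliberately far above the 3
  projected dimensions: with a few dozen points per shell, extreme-value
  statistics of pairwise cosines (largest cosine $\approx\sqrt{2\ln n/d}$)
  then place a point's nearest within-shell neighbour *farther* than the
  opposing shell, so plain nearest-neighbour geometry in input space mixes
  the classes while an rbf projection that encodes the radius separates
  them. In three ambient dimensions a linear 3D projection is an isometry
  and the fixture would demonstrate nothing.
* `makeBiasedProteins()`: sequences drawn i.i.d. from per-class residue
  frequency profiles, lengths uniform in a range (200–400 by default).
  i.i.d. residues are sufficient *because the method only ever sees
  composition*; the generator makes no attempt at realistic evolution,
  homology structure, domain architecture or length–class correlation.
  `proteinProfiles()` builds hydrophobic / charged / polar / other
  signature classes (five residues boosted by 0.05 over uniform);
  `membraneProfiles()` adds a strongly hydrophobic-aromatic multipass-like
  class "C" as the natural stage-1 target.

Consequently, passing tests on these fixtures show that the machinery —
kernels, eigenproblems, charge fields, fold bookkeeping — is correct and
that the method recovers class structure *when composition carries it*.
They say nothing about accuracy on real curated protein datasets, whose
class signals are weaker and correlated; published benchmark rates cannot
be reproduced here because those datasets are distributed by their
original authors, not printed in the literature that uses them.

Problem sizes in the test suite and acceptance script (60-sample shells,
120-sample four-class and five-class protein sets) were chosen so that a
full LOOCV — $n$ dense eigendecompositions — completes in seconds while
keeping per-class counts large enough for stable rates.

## Numerical choices and degenerate inputs

* Rank thresholds: eigenvalues below $10^{-10}\times$ the largest are
  treated as zero (GDA basis reduction and the KPCA positive-eigenvalue
  count). Asking for more components than the positive rank is an error
  that reports the available rank.
* `epsilonCoincide` $= 10^{-12}$ for charge-field coincidence.
* Identical duplicate samples receive identical scores; a dataset of all
  identical points is still evaluable with an uncentered rank-1 linear
  KPCA, where the traced tie-break rules fully determine the outcome.
* Non-standard residues (B, J, O, U, X, Z, …) are excluded from both the
  numerator and denominator of composition fractions, counted and warned
  about — published composition-based analyses rarely state their policy,
  so this one is explicit and tested.
* Errors are raised early and name the offender: mismatched dimensions
  with both lengths, singleton classes by label, duplicate FASTA ids by
  id.

## Known limitations

* Dense $n\times n$ eigendecomposition per fit, $O(n^3)$; LOOCV multiplies
  that by $n$. Desk-scale datasets (up to a few thousand samples) are the
  intended regime; there is no Nyström or incremental eigenupdating.
* The projection dimension is a free parameter `k`, defaulting to 3
  everywhere (and bounded by $C-1$ for GDA); nothing in the data model
  hard-codes three dimensions, but only the 3D regime is exercised by the
  shipped tests.
* Soft class probabilities are out of scope: both rules return hard
  labels.
* Kernel hyperparameter selection is limited to `gridSearch()` over
  user-supplied candidates ranked by LOOCV rate (ties: fewer
  hyperparameters, then candidate order).

## A worked micro-example

```{r example}
set.seed(1)
shells <- makeConcentricShells(15, radii = c(1, 3), noise = 0.1, seed = 42)
cfg <- pipelineConfig("kpca", kernelSpec("rbf", sigma = 1), k = 3,
                      scale = FALSE, rule = decisionRule("knn", K = 3))
loocv(shells, cfg)
```

The same pipeline with a linear kernel fails on this geometry — compare
`kernelSpec("linear")` in the configuration above — which is precisely the
nonlinearity argument for working in a kernel space at all.
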