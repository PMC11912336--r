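---
title: "Methods: attention-corrected graph networks and masked subgraph Shapley values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-corrected graph networks and masked subgraph Shapley values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Toxicity endpoints for environmentally relevant organisms — here, ammonia-
oxidizing nitrifiers — typically come with a few hundred labelled compounds,
far too few to train a graph neural network from scratch with any
robustness. Baseline (narcosis-type) toxicity, however, is strongly driven
by membrane partitioning, for which the octanol–water partition coefficient
(log P) is the classical surrogate and for which large data sets exist.
`toxgat` implements a complete stack built on that observation:

1. a graph attention network (GAT) for molecular property prediction,
2. pretraining on a lipophilicity-style regression task and transfer
   fine-tuning on a small binary toxicity task,
3. an attention-correction algorithm that re-attributes post-convolution
   global attention to atoms in their original states,
4. a locality-restricted, zero-masked Shapley value for substructures, and
5. a structural-alert pipeline that separates baseline-toxicity
   substructures from specific-mode-of-action candidates by comparing
   Shapley signs across the toxicity and lipophilicity models.

## Model

A molecule with $m$ heavy atoms is featurized into node features
$X \in \mathbb{R}^{m \times F_n}$ (atom type one-hot, formal charge,
hybridization, hydrogen-bond donor/acceptor flags, aromaticity, degree and
hydrogen-count one-hots, chirality tags, a partial-charge surrogate) plus an
adjacency matrix; bond features (type, ring, conjugation, stereo) are
carried for completeness. Hydrogens are implicit. The layout is frozen in
`feature_layout()`.

The network stacks $n_{\mathrm{conv}}$ graph-attention convolutions. Layer
$l$ computes attention coefficients over each atom's closed neighborhood
(self-loops included) with the standard LeakyReLU-scored softmax, giving a
row-stochastic matrix $C_l$, then aggregates $H \leftarrow C_l (XW)$,
followed by a linear transform, batch normalization, ReLU and dropout. A
global multihead scaled dot-product attention block ($N$ heads of dimension
$D/N$, concatenated, output-projected) follows, with a residual connection
$U = \mathrm{attn}(H) + H$. The readout concatenates global max and mean
pooling, and two fully connected layers produce the prediction (raw value
for regression, logit for classification). Defaults mirror the tuned
reference setting: 3 convolution layers, embedding 128, 4 global heads,
dropout 0.1 (conv) / 0.2 (attention), weight decay 0.01, early-stopping
patience 10, learning rates $10^{-4}$ (pretraining) and $5\times10^{-5}$
(fine-tuning).

Training is implemented natively in R (hand-derived backpropagation,
AdamW with decoupled weight decay applied to weight matrices). The test
suite validates every gradient against central finite differences. In
evaluation mode batch normalization uses stored running statistics and
dropout is off, so predictions are deterministic and independent of
batching; mini-batches are laid out as block-diagonal unions so attention
never crosses molecules.

## Attention correction

After $n$ convolutions an atom's representation mixes information from its
$n$-bond neighborhood, so global attention computed post-convolution does
not refer to atoms in their original states. The correction composes the
per-layer attention matrices,

$$C = C_{L} \cdot C_{L-1} \cdots C_1,$$

so row $i$ of $C$ expresses final atom $i$ as a convex combination of
original atoms, then applies the head-averaged global attention
$\bar{A}$ with the residual scheme:

$$M = \bar{A} C + C.$$

Every row of $M$ sums to 2. The decomposition deliberately ignores the
per-layer linear transforms, normalization and nonlinearities: it tracks
attention mass only, which is exactly the approximation the method is
defined by. Per-atom scores are the column means of $M$ divided by 2 and
renormalized to sum to one — the attention mass received by each original
atom, averaged over query atoms. This is the minimal reduction of the
$m \times m$ matrix to atom colors consistent with "attention allocated to
atoms"; nothing in the formulation pins a unique choice, so it is exposed as
the documented default rather than asserted as canonical.

Candidate substructures are the connected components of the atoms scoring
strictly above the molecule mean, capped at 8 atoms by removing
lowest-score atoms whose removal keeps the component connected. The
threshold and cap are configuration values; no canonical threshold exists
for this step.

## Masked subgraph Shapley values

A substructure $S_i$ ($k$ atoms) is treated as a single player; the
individual atoms reachable within $L$ bonds (default $L = 4$, matching the
receptive-field argument for a 3–4 layer network) are the other $\gamma$
players. Everything outside the player set is permanently masked. Masking
zeroes feature rows (and bond rows when either endpoint is masked) but
never deletes atoms: molecular graphs are very sensitive to structural
deletion, whereas zero-masking preserves topology. For a coalition $E$ of
context atoms,

$$\varphi(S_i) = \sum_{E} \frac{|E|!\,(|T|-|E|-1)!}{|T|!}
  \left[\hat f(E \cup S_i) - \hat f(E)\right],$$

evaluated exactly for $\gamma \le$ `exact_cap` (default 14, i.e. at most
$2^{15}$ model evaluations, batched) and otherwise by a seeded
permutation-sampling estimator with reported standard error. For
classification models the value function defaults to the logit — the
additively natural scale — with a probability mode for reporting. The
global attention block gives every atom a whole-molecule receptive field,
so the $L$-bond restriction is an approximation; `L` is exposed so users
can quantify the gap against `brute_force_full_shapley()`, which plays the
unrestricted game.

## Synthetic benchmark: the stated world

The generator assembles 4–20-heavy-atom molecules from a template grammar
(alkyl chains; benzene, pyridine and thiophene rings; substituents Cl, Br,
OH, NH2, SH, acetylene, methyl/ethyl), validated by the parser and unique
within a call — a curated data set contains distinct compounds, and
duplicates would leak across train/test splits. The pretraining target is
an additive per-atom surrogate (aliphatic C +0.5, aromatic C +0.3, N −1.0,
O −0.7, S +0.2, Cl +0.9, Br +1.1) plus Gaussian noise (sd 0.2). The
toxicity label thresholds a latent $z = a\,\mathrm{logP} + \sum_j b_j\,
(\text{alert}_j\ \text{count}) + \varepsilon$; the planted thiourea-like
alert `NC(=S)N` (carried by ~30% of molecules) has total atom weight
−1.3 yet label effect $b = +3$, reproducing by construction the
specific-mode-of-action signature: positive toxicity contribution, negative
lipophilicity contribution. The threshold is auto-calibrated to a 60%
positive rate, mirroring a 172:116 class balance. The latent noise sd
(0.5) and the alert carriage rate are generator choices made once for a
desk-scale, learnable-but-not-trivial task.

What the generator does **not** emulate: real chemical diversity,
activity cliffs, measurement-protocol heterogeneity, multi-fragment salts,
tautomers, or any toxicokinetics. A green transfer-benefit test therefore
establishes that the implementation realizes the transfer mechanism under
the stated statistical structure — not that the same margin would appear
on a curated biological data set.

## Numerical choices and scaling

* Target standardization during pretraining (mean/sd stored in the
  checkpoint, predictions returned on the original scale).
* Batch-norm epsilon $10^{-5}$, momentum 0.1; running statistics update
  during fine-tuning by default with a `freeze_bn` option (the reference
  protocol is silent on this point).
* Loss functions: mean squared error (regression), binary cross-entropy on
  the logit (classification).
* Early stopping keeps the best-validation weights; improvement threshold
  $10^{-12}$, so a plateaued loss halts after exactly `patience` epochs.
* The partial-charge feature is an electronegativity-difference surrogate
  (formal charge + 0.1·sum of Pauling EN differences over neighbors,
  implicit H included) standing in for Gasteiger charges, which require a
  full cheminformatics toolkit.
* KDE overlap uses the Silverman reference bandwidth per sample, a shared
  512-point grid spanning both ranges ±3 bandwidths, trapezoidal
  integration of the pointwise minimum, clipped to [0, 1]; zero-variance
  samples get a widened minimal bandwidth with a warning.
* Acceptance-scale runs use the stated data sizes (pretrain $n = 2000$,
  task $n = 250$, 5 seeds) but a compute-scaled model (embedding 32) with
  correspondingly larger learning rates ($10^{-3}$ / $5\times10^{-4}$) and
  3 repeated splits per seed, to fit a 25-minute single-CPU budget. The
  package defaults remain the reference values.

## Design choices on genuinely open points

* **Operator order in the composition.** "Successive product" fixes only
  the sequence; left-multiplication ($C = C_L \cdots C_1$) is forced by the
  aggregation semantics (row $i$ of each $C_l$ mixes layer-input atoms into
  layer-output atom $i$); the tests verify associativity-consistency and
  row-stochasticity rather than asserting a literal formula.
* **Bond masking rule.** A bond is masked when either endpoint is masked: a
  bond's information is meaningless without both atoms.
* **Disconnected SMILES** are rejected by default (`keep_largest_fragment`
  opts in): reachability and Shapley locality assume connectivity.
* **Alert de-duplication** across molecules uses canonical SMARTS of the
  induced subgraph (colored canonical labeling, deterministic writer);
  "contributing positively" is operationalized as mean Shapley > 0 over
  supporting molecules with minimum support 2.
* **Pattern-first alert scoring.** Attention-driven selection recovers
  alert regions but not always the exact planted atom set, so
  `score_pattern_alert()` scores every match of a given SMARTS under both
  models and aggregates them into one alert record; the attention-first
  `aggregate_alerts()` remains the discovery route.
* **External reference comparison** is replaced by comparison against the
  generator's known atomic contributions — the in-repo ground truth —
  since the reference log P fragment program is external software.

## Known limitations

* The SMILES dialect is the organic subset plus common bracket atoms; no
  kekulized-aromaticity perception (aromatic rings must be written
  lowercase) and no stereochemistry beyond tag carriage.
* The SMARTS emitted for substructures use element+aromaticity atom
  primitives only.
* Conv-layer multi-head support averages head attention for the downstream
  correction (mean preserves row-stochasticity); per-head correction is not
  implemented.
* The Shapley exact path enumerates $2^{\gamma+1}$ coalitions; beyond
  `exact_cap` results are stochastic estimates with reported standard
  error, not exact values.
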