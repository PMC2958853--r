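---
title: "Three-body Delaunay buriedness scoring for solubility mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-body Delaunay buriedness scoring for solubility mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soludel)
```

## The model and its assumptions

Solubility is dominated by what happens on a protein's surface.
This package scores mutations through a purely combinatorial notion of
surface exposure, avoiding solvent-accessible-surface-area computation
entirely. The modelling chain is:

1. **Unified residue representation.** Each amino acid becomes one 3D
   point: the centroid of its side-chain heavy atoms (all non-hydrogen
   atoms except N, CA, C, O, OXT), falling back to CA for glycine or
   unresolved side chains. This representation survives missing atomic
   detail and — crucial for mutagenesis — is the only level at which
   the mutant structure can be assumed identical to the wild type.
2. **Delaunay tessellation.** The tessellation of the residue points
   (computed without any distance cutoff) partitions the convex hull
   into tetrahedra whose triangles define three-body contacts. The
   empty-circumsphere property gives a parameter-free notion of
   nearest neighbours, more robust than fixed pairwise cutoffs.
3. **Buriedness classes.** A triangle shared by two tetrahedra is
   *buried*; in at most one, it is on the surface. An edge or vertex is
   non-buried iff it belongs to at least one non-buried triangle.
   Under these rules exactly 9 triangle configurations and 4 edge
   configurations are possible (`enumerate_triangle_classes()`,
   `enumerate_edge_classes()` prove this by constrained enumeration).
   Backbone connectivity adds a 3-level factor c counting
   sequence-adjacent pairs in the triangle.
4. **Potential.** Each triplet type t = (i,j,k,c,b) scores
   `Q_t = log(f_t / (C a_i a_j a_k p_cb))` — observed within-stratum
   frequency over expected under composition independence. Scoring is
   restricted to the five most surface-like triangle classes (b 0–4),
   reflecting the hypothesis that surface composition drives
   solubility.
5. **Mutation score and training.** A mutation's score is the change
   in the weighted total over only the triangles whose composition
   changes (provably equal to full rescoring, and verified against it
   in the tests). Weights w_t ∈ [0, 2] around the neutral default 1
   are trained by maximizing the minimum margin of a linear program;
   at prediction time, types absent from training contribute with
   weight exactly 1.

The key assumptions: wild-type geometry is reused for the mutant
(reasonable for the moderate substitutions typical of solubility
engineering, wrong for destabilizing ones); one chain is analysed at a
time; and the reference structure set is representative enough that
within-stratum frequencies are meaningful.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 9 | Å | maximum triangle edge length for a contact to count |
| `b` range scored | 0–4 | – | surface-like triangle classes entering scores |
| weight bounds | [0, 2] | – | LP box around the neutral weight 1 |
| `tie_break` | 1e-6 | – | secondary objective resolving degenerate LP optima toward w = 1 |
| `pseudocount` | 0 | counts | optional additive smoothing over the full 1540 × 27 key grid |
| `jitter` | 0 (off) | Å | deterministic symmetry-breaking for cospherical inputs (use 1e-6) |
| `d_sign` | `"margin"` | – | class-D constraint sign (see below) |
| `min_separation`, `max_step` | 3.5, 4.5 | Å | generator: residue separation and backbone step |
| `effect_size` | 2 | score units | generator: minimum |score| of accepted planted mutants |
| `noise_sd` | 0 | score units | generator: label noise; 0 keeps datasets separable |

The 9 Å screen is applied **after** buriedness assignment, and to the
three edges of each triangle: buriedness is a topological property of
the whole tessellation, while the cutoff only selects which contacts
are biochemically relevant. Applying the screen first would relabel
interior triangles as surface and change the class populations.

## Canonical class ordering

The defining constraints leave the 9 triangle configurations without an
inherent order. The package indexes them by total number of buried
component simplices ascending, ties broken by buried edge count
ascending. This reproduces every anchor the classification is built
on: class 0 is fully on the surface, class 1 has only the face buried,
class 5 has all vertices on the surface with edges and face buried,
class 8 is fully buried. The two four-buried configurations (one
vertex + two edges + face, versus three edges + face) order as classes
4 and 5. Users comparing against an externally defined figure ordering
can remap through the table returned by
`enumerate_triangle_classes()`.

## The linear program in detail

For training mutants with increase set *I* and decrease set *D*, with
M_i/W_i the mutant/wild-type key multisets of changed b 0–4 triangles:

$$\max \mu \;\; \text{s.t.}\;
\textstyle\sum_{t \in M_i} w_t Q_t - \sum_{t \in W_i} w_t Q_t \ge 1 + \varepsilon_i \;(i \in I),\;
\le -1 - \varepsilon_i \;(i \in D),\;
\mu \le \varepsilon_i,\; 0 \le w_t \le 2.$$

Three numerical decisions matter:

* **Class-D sign.** Written with `+ε_i` on the decrease side, each
  decrease-instance slack is only bounded below and the max–min
  objective never sees class D. The default implementation uses the
  symmetric `−1 − ε_i`, so ε measures margin beyond the unit band for
  both classes and μ = min ε at the optimum; the asymmetric variant
  remains available via `d_sign = "printed"` for comparison.
* **Degeneracy.** With many more triplet types than training mutants
  the optimal face of the LP is large, and a plain simplex solver
  returns arbitrary vertices that zero out types irrelevant to the
  binding constraints — held-out mutants composed of such types then
  score exactly 0. The implementation adds a tiny secondary objective
  (`tie_break`, default 1e-6 per unit of deviation) selecting, among
  max-margin optima, the weight vector closest to the pre-training
  default 1, via the substitution w = 1 + u − v with u, v ∈ [0, 1].
  Types that the margin does not constrain therefore keep their
  neutral weight, while genuinely discriminative types still reach the
  bounds. The penalty is orders of magnitude below the margin scale
  and leaves μ unchanged to ~1e-4.
* **Mechanics.** The LP is solved with the three-phase simplex in the
  `boot` package, which requires non-negative variables: ε_i and μ are
  shifted by a data-derived constant L = 2 + 2·max_i Σ_t |a_it| large
  enough that the optimum is interior to the shift. Returned weights
  are clipped to [0, 2] to absorb solver round-off (tolerance 1e-8);
  ε is recomputed from the returned weights rather than read off the
  solver. Ties s_j = 0 at prediction are resolved to D with a flag, so
  reports are deterministic.

Types with Q = 0 everywhere (never observed in the reference set)
cannot influence any score; they are excluded from the LP and keep
weight 1. Unobserved types score 0 rather than −∞: an unseen
composition is treated as uninformative, not impossible. The optional
pseudocount provides smoothing when a caller prefers it.

## What the synthetic generator emulates — and what it does not

`generate_structure()` produces a self-avoiding random walk: 3.5–4.5 Å
backbone steps, ≥ 3.5 Å pairwise separation, confined to a box sized
at ~130 Å³ per residue (the packing density of residue centers in
globular proteins). This exercises every connectivity class at
realistic rates and yields tessellations with both surface and deeply
buried simplices. It does **not** reproduce secondary structure,
side-chain packing correlations, or native-like amino-acid
composition–environment coupling; buriedness-class frequencies on
these blobs differ from those of real chains. Passing tests therefore
demonstrate algorithmic correctness (tessellation, classification,
scoring, training), not biological accuracy of the potential on any
particular proteome.

`generate_planted_dataset()` creates labelled mutants with a
recoverable signal. Because a potential estimated from the fixture
ensemble makes essentially every forward mutation score negative (the
wild-type compositions are exactly what the potential has seen), the
generator first perturbs `n_planted_sites` residues and uses the
perturbed chain as the dataset's wild type: reversions restore
high-likelihood compositions and score strongly positive (class I),
mutations of other sites score negative (class D). Labels are the sign
of the unweighted score plus optional Gaussian noise, with |score| ≥
`effect_size` enforced, so at `noise_sd = 0` the unit weight vector
separates every instance with margin ≥ `effect_size` and the LP
optimum satisfies μ ≥ effect_size − 1 by construction. The default
`effect_size = 2` keeps that guarantee strictly positive even under
the tie-break perturbation.

## Problem sizes

The shipped tests and the acceptance script work at sizes chosen to
exercise every code path while staying quick on one core: reference
ensembles of four 50-residue structures, oracle sweeps over thirty
structures of 20–100 residues, one hundred random mutants for the
delta-vs-full-rescore identity (tolerance 1e-9), and planted datasets
of 30 mutants for leave-one-out, 10-fold and 3-fold cross-validation.
Real applications simply substitute larger structure lists; cost is
dominated by one tessellation per structure and one LP solve per
cross-validation fold.

## Degenerate inputs

* Fewer than 4 residues, or a coplanar point set, is an error.
* Exactly cospherical points (lattice-like coordinates) make the
  tessellation ambiguous; `jitter = 1e-6` Å with a fixed seed
  (`jitter_seed`, default 0) breaks ties deterministically and is
  verified by an internal triangle-multiplicity check.
* Residues missing both side-chain atoms and CA are skipped with a
  warning; unknown chains and empty chains are errors naming the
  available chains.
* Mutation sites are matched by author residue number within the given
  chain, and the recorded wild-type amino acid must agree with the
  structure — a guard against numbering offsets.

## Known limitations

* One chain per analysis; no mmCIF; first NMR model only; first
  alternate conformer only.
* The potential shipped in examples is estimated from synthetic
  ensembles; quantitative claims about real mutant panels require
  re-estimating it from a large nonredundant chain set and a curated
  mutant table, which are consumed from local files rather than
  bundled.
* Three-class prediction (no-change mutants) and SVM/Lasso baselines
  are out of scope; the feature construction (signed Q contributions
  per type) is exposed through `build_lp_instances()` for callers who
  want to fit such baselines with their preferred toolkit.
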