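---
title: "Detecting internal symmetry in protein structures with parasymd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal symmetry in protein structures with parasymd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasymd)
```

## The problem

Many single-chain protein domains are built from structural repeats arranged
around an internal axis: beta propellers, TIM barrels, solenoids. Such a
chain is approximately invariant under a nontrivial rigid motion — a
rotation about an axis, possibly combined with a translation along it (a
screw). `parasymd` decides whether a CA trace has such internal symmetry,
and reports the symmetry axis, rotation angle and repeat offset.

## The alignment scan

Let the chain have residues $1..N$ with CA coordinates $x_i$. For every
circular-permutation offset $k = 1..N-3$ the structure is aligned against a
copy of itself in which residue $i$ is matched to residue $i+k$. Each offset
is refined by an iterated two-step cycle:

1. **Superposition.** The weighted Kabsch algorithm finds the proper
   rotation $R$ and translation $t$ minimizing
   $\sum_i w_i \lVert R\,x_{j_i} + t - x_{i}\rVert^2$
   over the current residue correspondence $(i, j_i)$. The first cycle uses
   the seed correspondence $(i, i+k)$ with uniform weights; later cycles use
   the previous alignment's similarity values as weights.
2. **Re-alignment.** With $y_j = R\,x_j + t$ the similarity matrix
   $S_{ij} = \dfrac{1}{1 + (d_{ij}/d_0)^2}, \qquad d_{ij} = \lVert x_i - y_j\rVert$
   is computed, and the best strictly monotone matching (dynamic
   programming, zero gap penalty, entries below $s_{\min}$ ineligible) is
   extracted, excluding near-self pairs.

The cycle stops when the score improves by less than `tol` or after
`max_cycles`; the best alignment over all cycles is kept. Its score is the
**T-score** $T_k = \sum_{(i,j)} S_{ij}$ — a weighted count of aligned
residues. The per-offset T-scores are standardized within the protein to
**Z-scores**, and the chain is called symmetric when $\max_k Z_k$ reaches
the cutoff (8 by default; 10 is the stricter convention). The screw axis —
direction, on-axis point, angle $\theta$ with
$\cos\theta = (\operatorname{tr} R - 1)/2$, and pitch — is decomposed from
the best offset's transformation.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `d0` | 3.0 Å | similarity half-distance: a pair at `d0` scores 0.5 |
| `s_min` | 0.2 | eligibility floor, equivalent to `d <= 2 * d0` |
| `max_cycles` | 10 | refinement cycle limit per offset |
| `tol` | 1e-6 | per-cycle T-score improvement needed to continue |
| `register_window` | 0 | allowed register drift around each offset |
| `min_shift` | 3 | minimum \|i − j\| of an aligned pair |
| `cutoff` | 8 | Z-score for the symmetric verdict |
| `z_mode` | robust | Z standardization (robust or moment) |

Two of these deserve their own sections, because they were genuinely open
design choices.

### Why the refinement is register-bounded

With a fully unconstrained monotone re-alignment, the refinement at almost
*every* offset of a strongly symmetric structure escapes into the basin of
the nearest true symmetry rotation: on a clean C4 toy, offsets 14–37 all
converge to the one 90° alignment and score identically. The per-offset
score profile then carries no contrast, and any standardization computed
within that profile is useless — a perfect positive control would be called
asymmetric. `register_window` restricts the eligible pairs of offset $k$ to
$|(j - i) - k| \le w$. The default $w = 0$ scores each offset as the exact
circular-shift hypothesis, which keeps neighbouring offsets in separate
basins and the T-profile sharp. The price is indel tolerance: real repeat
proteins have units of slightly varying length, and aligning them across an
indel needs $w > 0$ (at the cost of score bleed between offsets closer than
$w$). Setting `register_window = Inf` restores the unconstrained behaviour.

### Why near-self pairs are excluded

Excluding only exact self pairs ($i = j$) is not enough: every chain aligns
well to itself shifted by one or two residues, because consecutive CA atoms
are a constant 3.8 Å apart — the copy simply threads along the backbone.
This is self-similarity of any polymer, not internal symmetry, and it
produced large T-scores at offsets 1–2 on random coils. `min_shift = 3`
makes pairs with $|i - j| < 3$ ineligible, which suppresses the threading
artifact entirely and is consonant with the scan range stopping at $N - 3$.
Offsets below `min_shift` still appear in the report, with $T = 0$.

### Z standardization

The T-scores of one protein's scan are standardized against their own
distribution: $Z_k = (T_k - \mathrm{median})/(1.4826\,\mathrm{MAD})$. The
robust location/scale keeps the handful of true symmetry peaks from
inflating the scale they are judged against. When the MAD is zero (a
constant background, possibly with isolated outliers) the moment estimate
$(T_k - \bar T)/s$ is used instead, and if the scores are entirely constant
all Z-scores are 0. `z_mode = "moment"` selects mean/sd standardization
directly. No external calibration database is needed; the trade-off is that
the Z scale depends on the protein's own offset count and background, so
short chains (fewer than roughly 40 residues, i.e. under ~37 background
offsets) rarely reach a Z of 8 even when perfectly symmetric.

## The parallel scan

The scan is embarrassingly parallel across offsets. `run_parallel()`
implements a master–worker protocol: the master (rank 0) does housekeeping
only — it partitions offsets `1..N-3` into $p-1$ contiguous chunks of size
$\lfloor (N-3)/(p-1) \rfloor$ with the remainder appended to the last rank,
sends the structure and one chunk to each worker, and blocks until every
worker has replied. Workers return their chunk's full per-offset results
(the master needs the whole T distribution to standardize, so returning
only a per-chunk best would not suffice). The master concatenates results
in offset order and runs the *same* final aggregation code as the serial
scan, so serial and parallel results are identical to the last bit for any
process count — which is also the package's central test. The backend is
pluggable: a process pool (fork on unix, socket cluster elsewhere) or an
in-process executor that follows the same chunk protocol and serves as
automatic fallback. Chunking is static; there is no work stealing, which
keeps determinism trivial. `measure_speedup()` reports $S = T_1/T_p$
against the ideal speedup $p - 1$ (only the workers compute), plus
communication, computation (max over workers) and master postprocessing
times from a monotonic timer.

## The synthetic controls

`make_cn_structure()` builds a Cn-symmetric CA trace: one random-walk motif
(3.8 Å virtual bonds) of `unit_size` residues, its centroid placed `radius`
Å from the z axis, replicated `n_units` times by rotation about z (an
optional `rise` per unit yields a screw arrangement), plus isotropic
Gaussian noise. With zero noise, rotating the structure by $360/n$ degrees
and shifting ranks by `unit_size` maps each CA exactly onto another — the
ground truth that the scan should recover. The generation axis is always z
through the origin; tests that need an axis in general position apply a
random rigid transform afterwards (`random_rigid_transform()`).
`make_random_coil()` is the negative control: a self-avoiding-ish walk
(3.8 Å steps, non-consecutive pairs kept at least 3.0 Å apart).

What these controls do *not* emulate: secondary structure, side chains,
compact unit packing, and unit-length variation (indels). Passing the
package's tests therefore demonstrates the machinery — optimal
superposition, correct DP alignment, axis decomposition, serial/parallel
identity — not detection performance on real domains, where `d0`,
`register_window` and the cutoff may need calibration.

## Numerical choices

* Kabsch uses SVD with the standard determinant-sign correction, so the
  rotation is always proper; collinear point sets are solved but flagged.
* The DP traceback compares cell values by exact floating equality against
  the stored maxima (safe because stored values are copies of candidate
  values) and prefers taking a pair at ties, making alignments
  bit-reproducible; score ties between distinct matchings have measure
  zero for continuous similarity values.
* Axis decomposition clamps $\cos\theta$ into $[-1, 1]$, takes the axis
  from the antisymmetric part of $R$ when $\sin\theta$ is not tiny and from
  $R + I$ (with a deterministic sign convention) near 0° and 180°, and
  computes the on-axis point as the minimum-norm solution of
  $(I - R)\,p = t - (t \cdot u)\,u$ via a pseudoinverse. Rotations under
  0.5° are flagged degenerate: the axis of a near-identity transform is
  numerically meaningless.
* Best-offset ties break toward the smallest offset (the finest repeat).
* If an alignment collapses below 3 pairs the offset is reported with the
  score of the remaining pairs, a degenerate flag, and the transformation
  frozen at the last valid superposition.
* Seed correspondences omit the wrapped tail of the circular shift; since
  alignments are strictly monotone in original-frame indices, wrapped
  matches are not representable and are not recovered.

## Problem sizes and reproducibility

The test suite exercises chains of 10–200 residues and 2–8 processes, with
positive controls C2×30, C3×20, C4×15 and C7×10 (radius 12 Å) and twenty
60-residue coils; partition invariants are swept over all
`n_offsets` ≤ 1000 and `p` ≤ 128. These sizes give each statistical check a
comfortable margin while keeping a full run on a laptop in minutes. All
generators are deterministic per seed and never perturb the caller's RNG
state. Known limitations worth restating: detection power fluctuates around
the cutoff for marginal repeat units (~10 residues) when the motif is
resampled; symmetry *order* classification (C vs screw families) is not
attempted beyond reporting angle and pitch; mmCIF input, multi-chain
(quaternary) symmetry and NMR model averaging are out of scope.
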