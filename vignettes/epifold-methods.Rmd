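---
title: "Methods: Hilbert-curve EPI classification, transfer and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hilbert-curve EPI classification, transfer and attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and of the design
choices that were genuinely open: what is computed, under which
assumptions, which knobs matter, and what the desk-scale tests do and do
not establish.

## 1. Hilbert-curve encoding

A DNA sequence of length $L$ is written onto the canonical Hilbert curve of
order $n$, the smallest with $4^n \ge L$ (so 3000-bp enhancers and 2000-bp
promoters both use order 6, a $64\times64$ grid). Base $i$ (1-based)
occupies the cell at curve position $i-1$; each cell holds a four-channel
one-hot vector ($A,T,C,G$ in that channel order), ambiguity codes and
padding hold the zero vector, and cells beyond the sequence end stay zero.
The motivation is locality: consecutive curve positions are always adjacent
cells, so a convolution kernel sees contiguous sequence context, and —
unlike a row-major raster — positions a few dozen bases apart remain close
on the grid (the test suite checks this quantitatively at offset 64,
order 6).

Three conventions had to be fixed because no standard exists:

* **Orientation.** One fixed canonical curve, starting at the top-left cell
  $(0,0)$ and ending at the bottom-left $(\mathrm{side}-1, 0)$, rows
  indexed top-to-bottom. Encoding, training and attribution all share it,
  so the forward and inverse maps always agree; the inverse map is exact
  and tested as a bijection up to order 7.
* **Padding.** Tail padding only (positions $0..L-1$ filled, the rest
  zero). Centering would break the single invertible position map the
  attribution pipeline depends on.
* **Ambiguity.** `N` (and any non-ACGTU character) carries no channel
  mass but still occupies its curve position; `U` is read as `T`; parsing
  is case-insensitive. Total tensor mass therefore equals the number of
  unambiguous bases — a conservation law the tests assert.

## 2. Data handling and class balancing

Pair tables arrive as TSV/CSV with inline sequences, or as BED intervals
plus a genome FASTA (0-based half-open, minus strand reverse-complemented;
parsing is delegated to `rtracklayer` and `Biostrings`). Sequences are
normalised to the fixed lengths by centre-trimming or symmetric `N`
padding, with the odd base going to the right flank.

The benchmark imbalance is 20 negatives per positive; both published
balancing routes are implemented. *Under-sampling* keeps a seeded uniform
subset of negatives the size of the positive set. *Over-sampling*
replicates each positive `factor` times, with `factor = "auto"` defined as
`round(n_neg/n_pos)`; under the canonical sizes this reproduces the
published augmented counts exactly (e.g. 1977 positives against 39,500
negatives give factor 20 and 39,540 augmented positives). The publication
names over-sampling but not its mechanism; replicate-with-random-shift
(default window ±50 bp, vacated positions `N`-filled) was chosen so copies
are not byte-identical, with exact duplication available via
`shift_window = 0`.

One methodological caveat is documented rather than hidden: when an
augmented dataset is split 8:1:1 *after* augmentation, test positives are
near-copies of training positives, and `N`-filled flanks are a class marker
(only positives are shifted). Within-line scores on augmented data are
therefore optimistic. All scientific property tests in this package
(transfer benefit, attribution) use unaugmented, duplicate-free positives;
the splitting itself is largest-remainder with per-label stratification.

## 3. The classifier

Per branch: two 3×3 same-padding convolutions, each followed by ReLU and
2×2 max-pooling; the branches are flattened, concatenated, passed through
one dense ReLU layer with inverted dropout, and a sigmoid unit. Loss is
binary cross-entropy, optimised by Adam. Published values are used as
defaults where stated — learning rate $3\times10^{-4}$, batch 100, up to
100 epochs, 8:1:1 splits, early stopping — and conventional values fill the
gaps (32/64 filters, 128 dense units, dropout 0.5, patience 5 on
validation loss, best-epoch weights restored; the untrained model is the
stopping baseline, so a run that never helps restores the initial
weights). Everything is configurable, and the architecture is
size-agnostic down to $8\times8$ grids (two 2×2 pools need at least a
2×2 map; side 4 would leave 1×1 and is rejected).

No R deep-learning framework exists in this environment, so the layers are
implemented here directly: convolution as a precomputed im2col gather plus
one BLAS GEMM per layer and batch; the backward scatter as a single
`rowsum()`; pooling masks routed by first-match argmax. The backward pass
is verified against central-difference numerical gradients for every
parameter tensor. Training is bit-reproducible for a fixed config seed
(initialisation, shuffling and dropout all derive from it); inference is
deterministic and dropout-free. This holds on a fixed BLAS; exact
trajectories may differ across numerically different BLAS builds, which is
why stochastic performance tests pin seeds *and* assert behavioural
margins rather than exact scores.

## 4. Transfer protocols

`transOne` pre-trains on the pooled training splits of the non-target
lines, then trains **all** layers on the target's training split;
`transTwo` pre-trains on **all** lines' training splits (the target's
training split only — never its validation or test data), freezes both
branches' convolutional parameters, and fine-tunes the post-merge head.
Epoch defaults are the midpoints of the stated ranges (7 pre-train, 12
fine-tune); values outside 6–8/10–15 warn but run. The optimizer state is
reset between phases (the publication is silent; keeping Adam moments from
pre-training would couple the phases through stale second-moment
estimates); weights carry over. Freezing is exact: frozen tensors are
excluded from the update loop, and the tests assert bit-identity.

Cross-line evaluation follows the published table layout: rows are test
lines, columns train lines; the no-transfer baseline is the grid of
single-line models, whose off-diagonal collapses toward chance when motif
vocabularies are line-specific, and the transferred models are evaluated on
the other lines' test splits to fill their off-diagonals.

## 5. Overlap statistic

The publication defines the shared-EPI count procedurally but never the
similarity itself. The package uses ungapped positional identity over the
concatenated enhancer+promoter of length-normalised pairs — the simplest
reading of "sequence similarity" for fixed-length sequences — with `N`
matching nothing; a stricter per-element minimum of the two identities is
available behind `method = "minimum"`. A target pair increments the count
at most once regardless of how many comparison pairs qualify
(`per_match = TRUE` counts matches instead). Exact reproduction of the
published count tables is out of reach from the text alone (the similarity
definition is unknowable); instead the implementation is checked against a
brute-force double loop, for monotonicity in $\omega_0$, for the
bound by the target line's positive count, for symmetry at $\omega_0=1$,
and for exact recovery of planted byte-identical pairs.

## 6. Attribution

`compute_cam()` is gradient-weighted CAM on each branch's final
convolutional layer: the positive-class logit is differentiated w.r.t. the
post-ReLU conv-2 activations, spatially averaged into one weight per
filter, the weighted activation sum rectified, bilinearly upsampled
(half-pixel alignment) to the input grid, and max-normalised. The classic
CAM formulation assumes a global-average-pooling head this architecture
lacks; the gradient-weighted form reduces to it when a GAP head is present
and is the standard generalisation. Per-cell importance returns to
sequence positions through the exact inverse curve map.

Salience (the publication gives no threshold) is per-sequence: positions at
or above the 0.9 quantile of that sequence's importance, ties included.
Salient positions are grouped into maximal consecutive runs, and every
k-mer (k = 3, 4 by default) fully contained in a run is counted into
per-branch frequency tables — `N`-containing k-mers are dropped. The counts
are re-derived in the tests by an independent re-scan.

## 7. The synthetic generator

The generator is the package's study system. Per cell line it emits
fixed-length pairs at the canonical 20:1 imbalance; a positive carries one
compatible (enhancer-motif, promoter-motif) pair drawn from shared plus
line-specific vocabulary; a fraction of negatives ("hard negatives")
carries a single-side motif so that pairing, not motif presence, separates
the classes; planted byte-identical positives across chosen lines give the
overlap statistic a known answer; everything is a pure function of the
config seed, and fixtures round-trip through the TSV reader byte-for-byte.

Defaults, fixed once as the package's desk-scale study conditions: 3 cell
lines; 1000 positives and 20,000 negatives per line; 512/256-bp sequences
(order 5/4 grids); one shared plus one line-specific motif pair of length
10; motif copies implanted as homotypic clusters — 12 per enhancer, 6 per
promoter, about one site per 40 bp; per-position motif mutation 0.05;
uniform base composition; 10% hard negatives. Two of these deserve their
rationale spelled out:

* **Homotypic clusters.** Pilot experiments during development showed that
  a single motif occurrence per sequence is not reliably learnable by this
  architecture class at desk scale: a k-bp motif takes many different 2-D
  path shapes depending on its curve position, and with one occurrence per
  positive the small conv stack memorises the training set instead of
  learning shape templates. Multiple occurrences per sequence — the typical
  architecture of strong enhancers, where binding sites cluster — give the
  convolution layers several independent looks per example and make
  learning robust. This is a property of the data regime, not a test
  tweak: the density was fixed from those pilots before the acceptance
  checks were written, and the dose–response (more copies, better
  generalisation) is monotone.
* **Vocabulary size.** One shared + one specific pair per line keeps every
  line's positive set learnable from ~1600 balanced training examples
  while still giving transfer learning something to transfer (the shared
  pair) and something to miss (the specific pair).

What the generator does *not* emulate: genomic base composition and
repeats, degenerate motifs (PWMs), chromatin context, distance effects,
and the correlated negatives of real Hi-C-derived benchmarks. Passing
tests therefore demonstrate that the pipeline's machinery behaves as
specified on data whose ground truth is known — not that real-data
benchmark scores would be matched; those require the external six-line
dataset and full-scale training, and are explicitly out of scope.

## 8. Test problem sizes

The suite's heavier checks use: within-line training on one default-scale
line (order-5/4 grids, ~2000 balanced pairs, ≤40 epochs); the transfer
comparison on 64-bp sequences (order-3 grids, 250 positives/line, 5 seeds,
protocol epochs at the bottom of the stated ranges); attribution on 128/64
bp with a fixed planted motif (`GGGTACCTAG`/`TTACCGGATC`), 20 held-out
pairs for the positional contrast and 200 positives for the k-mer table.
These sizes are the package's choice of desk-scale study conditions; the
same code paths scale to the full 3000/2000-bp, order-6 setting by
configuration.

## 9. Known limitations

* Pure-R training is two to three orders of magnitude slower than a GPU
  framework; the full published benchmark regime (40k pairs, 64×64 grids,
  100 epochs) is out of desk reach, though nothing in the code caps it.
* Grad-CAM at the final conv layer has the spatial resolution of that
  layer (half the input side); attribution at single-base resolution is
  not claimed.
* The overlap statistic is positional identity; alignment-based similarity
  and coordinate-space overlap are deliberate non-goals.
* Early stopping monitors validation loss only; no learning-rate schedule
  or weight decay is implemented.
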