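---
title: "Methods: factorized convolutions, CTC training and the squiggle simulator"
author: "nanocallr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorized convolutions, CTC training and the squiggle simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocallr)
```

# The problem

A nanopore sequencer measures ionic current roughly 4000 times per second
while a DNA strand translocates through the pore at about 450 bases per
second.  Each base therefore dwells in the pore for about 9 samples, with
large variance, and the measured level at any instant depends on a short
context of roughly 5–12 bases around the pore head.  Base calling inverts
this process: raw current in, DNA sequence out.  `nanocallr` implements a
convolutional base caller for this problem end to end — the convolution
factorizations, the residual blocks, the CTC loss and decoders, a training
loop, and a synthetic signal simulator that makes the whole pipeline
trainable and checkable on a single CPU.

# Convolution factorizations

All operators act on a time-by-channel matrix $X \in \mathbb{R}^{T \times
C_{in}}$.  The full 1-D convolution of odd depth $D$ zero-pads by
$\lfloor D/2 \rfloor$ on both ends and computes

$$Y_{t,j} = \sum_{0 \le d < D}\ \sum_{0 \le i < C_{in}} X_{t+d,i}\,W_{j,d,i} + B_j,$$

at a cost of $C_{out} D C_{in}$ weights and $T\,C_{out} D C_{in}$ multiplies.
The separable factorization replaces this with a depthwise pass
($Z_{t,j} = \sum_d X_{t+d,j} W^{(D)}_{d,j} + B^{(D)}_j$) followed by a
pointwise channel mix ($Y_{t,j} = \sum_i Z_{t,i} W^{(P)}_{j,i} + B^{(P)}_j$),
reducing the multiplies to $T(DC_{in} + C_{out}C_{in})$; the blueprint
variant applies the pointwise step first.

The k-blueprint-separable convolution generalizes the blueprint form: a
*fat-pointwise* stage — a standard convolution of small odd depth $k$ —
mixes channels over a width-$k$ window, and a $k$-dilated depthwise stage of
depth $D/k$ completes the receptive field $D$.  The depthwise kernel (the
memory-bound operation on edge accelerators) shrinks by a factor of $k$
while the factorization gains roughly $k$ times more parameters than the
separable form (for $C_{in}=C_{out}=128$, $D=15$, $k=3$: $49{,}792$ weights
against $18{,}304$, a ratio of about 2.7).  At $k = 1$ the operator reduces
exactly to the blueprint-separable composition, which the test suite checks
to $10^{-12}$.

**Padding placement.**  The composition is padded so that output frame $t$
is centred on input frame $t$: the fat-pointwise stage pads
$\lfloor k/2 \rfloor$, the dilated depthwise stage pads
$\lfloor (D/k)/2 \rfloor \cdot k$.  When $D/k$ is even the receptive field
cannot be centred; the operator emits a warning rather than an error, since
the arithmetic is still well defined.  `full_conv` rejects even $D$
outright, and `k_blueprint_separable_conv` rejects $D$ not divisible by
$k$.

# Residual blocks and depth-to-space compression

The classical residual block runs $R$ separable-convolution sub-blocks
(conv + batch norm + Swish, the last without activation) against a
pointwise + batch-norm skip connection, sums, and applies a final Swish.

The compressed variant trades depth for width: a strided convolution with
depth and stride both $x$ turns $(T, C)$ into $(T/x, C\,y)$, the $R-2$
inner convolutions run k-blueprint-separable at the compressed resolution
with kernel depth reduced by a factor of $x$, a single depthwise operation
precedes the inverse transform, and a strided transposed convolution (depth
= stride, so slots do not overlap) restores $(T, C)$.  The block is a
drop-in replacement: identical shape contract, and any pointwise operation
after compression effectively mixes $x$ original samples, enlarging the
receptive field.  Pointwise work grows by $y^2/x$ (4/3 at the default
3:2 ratio), which the compression of the depthwise kernels more than
offsets on memory-bound hardware.

Choices the block design left open, and how this package resolves them:

* **Inner kernel depth.**  With block depth $D$ at the input resolution,
  the inner depth is $k\,q$ with $q$ the smallest odd integer at least
  $D/(xk)$ — rounding *up* keeps the compressed-branch receptive field at
  least $D$, and an odd $q$ keeps it centred.
* **Pre-decompression depthwise.**  Its depth is $D/x$ rounded to the
  nearest odd integer $\ge 1$, followed by batch norm without activation
  (mirroring the "last sub-block omits the activation" convention).
* **Decompression output** passes through its own batch norm before the
  branch sum, for symmetry with the skip branch.
* **Length bookkeeping.**  A $T$ not divisible by $x$ is right-padded with
  zeros inside the block and trimmed after decompression, so the drop-in
  length contract holds for every $T$.

# Identity initialization

Inside the compressed main branch, depthwise kernels are initialized to a
centred delta, $W^{(D)}_{d,j} = \delta_{\lfloor (D/k)/2\rfloor, d}$, and
fat-pointwise kernels to a centred identity plus noise,
$W^{(P)}_{j,d,i} = \delta_{\lfloor k/2 \rfloor, d}\,(\delta_{i,j} +
U(-\epsilon, \epsilon))$ with $\epsilon = 0.02$ by default; biases start at
zero and every other layer falls back to Glorot-uniform weights with bound
$\sqrt{6/(C_{in}+C_{out})}$.  At $\epsilon = 0$ every parameterized layer
of the branch is an exact identity map.  Two numerical details make that
exactness testable: batch-norm running variances are initialized to
$1-\epsilon_{BN}$ so that the inference-time scale
$\gamma/\sqrt{\sigma^2 + \epsilon_{BN}}$ is exactly 1, and the
fat-pointwise identity uses the leading $\min(C_{in},C_{out})$ diagonal
when the layer is not square.  Note that the branch *as a whole* is the
identity only up to the fixed Swish activations interleaved between
sub-blocks — an activation is not the identity function, so "identity
initialization" is a statement about the parameterized layers, which is
how the property tests assert it.

The rationale for near-identity starts is specific to base calling: the
hard part of the task is segmenting the signal into events, not naming the
base once an event is known (a logistic regression on correctly segmented
event means already separates purines from pyrimidines, which
`experiment_purine_probe()` demonstrates on synthetic data).  Identity
starts let the network learn the easy per-event discrimination first
without having to unlearn spurious long-range mixing from random kernels.
The package replicates this qualitatively: `ablation_identity_init()`
trains matched models under identity and Glorot initialization across
seeds, and `experiment_boundary_input()` shows that handing the network a
ground-truth event-boundary channel dramatically accelerates training —
diagnostic only, since no real base caller can be given ground-truth
boundaries.

# Network, decoding and loss

The default topology is a stride-3 full-convolution block (so the frame
rate is one-third of the sample rate, about 3 frames per base), a stack of
compressed residual blocks, two separable C blocks, and a pointwise decoder
to five channels followed by a row-wise softmax over $\{A, C, G, T,
\text{blank}\}$ (blank last).  The `"small"` preset (32 channels, 2
residual blocks, $D = 15$, $k = 3$, ratio 3:2, about 57k parameters) is the
desk-scale training default; the `"full"` preset uses the classic
three-C/five-residual topology at 64 channels.  Both presets are explicit
stand-ins rather than replicas of any production base caller, with kernel
depths in the range (9-21) where this family of architectures operates
well; every value is overridable through the YAML configuration.

Training minimizes the CTC negative log-likelihood, computed by the
standard forward recursion over the blank-augmented label in log space
(safe up to $10^5$ frames).  The gradient with respect to the log-score
matrix is the exact forward–backward occupancy, verified against central
finite differences and against a brute-force enumeration of all $5^{T'}$
paths for $T' \le 8$.  Infeasible labels (more bases plus required
repeat-separating blanks than frames) get $+\infty$ loss rather than an
error, so the training loop can skip them.  Two decoders are provided:
greedy best-path (argmax per frame, ties broken to the lowest channel
index, collapse repeats, drop blanks) and a prefix beam search.  At a
stride-3 frame rate (about 3 frames per base) the per-frame argmax
systematically drops short-dwell events whose probability mass is spread
over neighbouring frames — error anatomy on held-out synthetic reads shows
deletions outnumbering substitutions roughly two to one under greedy
decoding — so the final held-out evaluation and `predict()` use the beam
decoder (width 8 by default), which recovers most of that mass; the cheap
greedy decoder serves the frequent evaluations inside the training loop.

**Chunked inference.**  Long signals are split into overlapping windows
whose length and step are rounded to the model's *shift period* — the
product of the stride and the compression factor $x$.  Depth-to-space
compression is only shift-invariant for shifts that are multiples of this
period; unaligned windows would change the grouping phase and produce
different posteriors.  Half of each overlap is discarded on stitching, and
frames farther than the receptive radius from any cut are bit-identical to
the unchunked forward pass.

# The squiggle simulator

`simulate_squiggle()` emulates the generative story the base caller must
invert:

* **Dwell.**  Samples per base follow a shifted negative binomial with mean
  $4000/450 \approx 8.9$ and dispersion chosen so the coefficient of
  variation is about 0.58 ("large variance"), minimum 1 sample.
* **Level.**  An additive per-position context table over a 6-base window
  (configurable 5–12) rather than a $4^c$ lookup: desk-scale memory, still
  context-dependent.  Central contributions are fixed and equally spaced
  ($A = 1.2$, $G = 0.4$, $C = -0.4$, $T = -1.2$ in normalized units) so
  that every base is individually identifiable from a well-estimated event
  mean and the purine/pyrimidine margin (1.6) exceeds the noise scale, as
  in real pore tables.  Flank and adjacent-position interaction terms are
  drawn from bounded uniforms whose worst-case sum (0.7) stays below the
  minimal central gap (0.8), so noiseless event means are strictly
  separable — and distinct contexts can still collide on very similar
  levels, a known difficulty of real pores.
* **Noise.**  I.i.d. Gaussian noise per sample, `noise_sd = 0.25` in
  normalized units.  There is no canonical noise magnitude for a synthetic
  pore; the value is a declared stand-in and is recorded in every exported
  dataset.

What the simulator deliberately does *not* emulate: real R9.4.1 pore
chemistry, homopolymer-specific error structure, current drift, stuck
pores, or FAST5 containers.  Passing tests on synthetic data therefore
demonstrate that the architecture, loss, gradients and training loop are
correct and that the pipeline can learn a realistic signal model — not
that the shipped defaults would reach any particular accuracy on real
reads.

Signals are normalized by median and MAD (`(x - \mathrm{med})/(1.4826
\cdot \mathrm{MAD})`), a robust, affine-invariant choice applied
identically at training and inference time; constant signals are rejected
explicitly.

# Training procedure

`train_basecaller()` uses Adam (learning rate $4 \times 10^{-3}$, batch 8,
half-cosine decay to zero over the budget — chosen for desk-scale
stability, since no canonical training schedule exists for this setting) on
mini-batches of fixed-size chunks (default 1200 samples) cut from whole
reads at event boundaries, each chunk carrying its exact label slice.
Chunking keeps the CTC cost per step roughly constant regardless of read
length.  Reads are split 80/20 into training and held-out sets by a
deterministic hash of the read id.  Gradients for every layer are
hand-derived and finite-difference-verified; training aborts with
diagnostics if the loss turns non-finite.

Two batch-normalization regimes are exposed at inference.  `"infer"` uses
running statistics, which are *recalibrated* after training (flat average
of batch statistics over training chunks with frozen weights) because the
exponential moving average tracked during optimization lags the final
weights.  `"instance"` recomputes statistics from the input itself —
read-adaptive normalization, the default for `predict()` and evaluation,
consistent with the per-read median/MAD normalization philosophy and
empirically a few accuracy points better on held-out reads.  Chunked
inference via `batch_forward()` uses running statistics so that stitched
and unchunked results agree exactly.

**Problem sizes.**  The package's own experiments are sized for a single
CPU: the end-to-end run trains the small preset on 500 synthetic reads of
200–500 bases for 1000 steps; the initialization ablation and the
boundary-input experiment use a reduced model and budget with at least 3
seeds per arm.  These sizes are the package defaults for its desk-scale
experiments, stated here so results are interpreted at the scale they were
computed.

# Evaluation

Read accuracy is $1 - d(\mathrm{call}, \mathrm{ref})/|\mathrm{call}|$,
floored at zero, with $d$ the unit-cost Levenshtein distance — note the
*call* length in the denominator.  Empty calls are excluded and counted as
unmapped; since no aligner is in scope for synthetic data, the "mapped
fraction" is the fraction of reads with a nonempty call.  The
implementation uses `utils::adist`; the test suite checks it against an
independent dynamic-programming oracle on a thousand random pairs.

# Known limitations

* Accuracy numbers on the synthetic task do not transfer to real nanopore
  reads; the simulator's additive pore model is simpler than a real pore's
  response, and no quantization or hardware-specific behaviour is modelled
  (all arithmetic is double-precision floating point by design).
* Bases whose dwell is shorter than the frame period (about 5% of bases at
  the default stride of 3) are intrinsically hard for frame-synchronous
  CTC; beam decoding recovers part, not all, of them.
* In the boundary-input experiment the ground-truth-boundary arm is
  marginally *slower* for the first ~100 steps — both arms must first learn
  level decoding — and pulls decisively ahead only in the
  segmentation-limited regime, which is why the steps-to-threshold
  comparison uses a threshold above the baseline's plateau.
* The training loop is single-threaded, pure R plus a small C++ core for
  the CTC recursion; it is sized for tens of minutes of CPU, not for
  production training runs.
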