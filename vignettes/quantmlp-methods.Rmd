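---
title: "Methods: fixed-point MLP inference and its cycle-level latency model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-point MLP inference and its cycle-level latency model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantmlp)
```

## The problem

Real-time diagnostic pipelines classify a protein mass spectrum — a vector
of ion intensities over thousands of mass/charge (m/z) positions — as
normal or disease with a small multi-layer perceptron (MLP). Meeting
real-time latency budgets on dedicated hardware means running inference in
fixed point, streaming the weight matrix through a blocked datapath, and
knowing *in advance*, cycle by cycle, how long each layer takes.
`quantmlp` models that whole stack in software, bit-exactly for the
arithmetic and cycle-exactly for the timing, so quantization fidelity and
architecture sizing can be studied without hardware.

## Fixed-point representation

Weights are quantized per layer, symmetrically about zero:
$q_w = \mathrm{round}\!\left(w \cdot 127 / \max_i |w_i|\right)$, so the
most extreme weight of each layer lands on $\pm 127$ and zero is exactly
representable. We use symmetric max-abs scaling rather than asymmetric
min/max onto $[-128, 127]$: it keeps negation symmetric and costs at most
one representable level. Rounding here is round-half-away-from-zero; this
is an offline calibration step, so there is no hardware pressure to
truncate (the datapath truncates only in the on-line requantizer).

Inputs are nonnegative intensities and are mapped to $[0, 127]$ by
$q_x = \lfloor x \cdot 127 / x_{\max} \rfloor$ — the full range the
datapath's activation input admits, since a ReLU guarantees the 8-bit
word's MSB is zero. Values above the calibration maximum saturate at 127,
as an 8-bit input channel would.

Biases live in the 32-bit accumulator domain:
$q_b = \mathrm{round}(b \cdot s_w \cdot s_{in})$, saturated to signed
32 bits with a warning. The scale algebra across layers is genuinely open
design space: after requantization, the activation scale of layer $\ell+1$
depends on the truncation shift chosen at run time from that layer's data.
`calibrate_quantize()` therefore accepts a calibration matrix; it
propagates $s_{in,\ell+1} = s_{w,\ell}\, s_{in,\ell} / 2^{\hat t_\ell}$
where $\hat t_\ell$ is the shift implied by the float activation maximum
over the calibration rows. Without calibration, activations are assumed to
fill the 7-bit range of a unit-scale float activation ($s_{in} = 127$).
The estimate is static while the true shift is per-case; the argmax
decision is robust to this (see the fidelity property below), but absolute
32-bit outputs of deep layers should not be compared across the float and
fixed-point paths.

## The datapath

One cycle consumes an $N \times M$ block of the layer's weight matrix
against $M$ input elements: per-row multiplier banks feed adder trees of
depth $\lceil \log_2 M \rceil$ (`scalar_product_block()`). Accumulate
registers sum the $\lceil \mathrm{cols}/M \rceil$ column blocks of each
row block, injecting the bias on the first column block (the choice of
*where* to add the bias is free; first-block injection lets the reset and
the bias share a trigger). Edge blocks are zero-padded in both weights and
inputs, which preserves sums exactly.

Finalized row blocks stream through a max search (local maximum per
$N$-vector, then a global register), and the layer's global maximum keys a
leading-one detector whose output $p$ is clamped to $[6, 30]$: $p = 6$
means everything already fits 7 magnitude bits; $p = 30$ is the largest
positive 32-bit value. Requantization is then ReLU followed by an
arithmetic right shift of $p - 6$, mapping the maximum's leading 1 to
bit 6 — truncation instead of division, because division hardware is
expensive and the compression context keeps the difference small. A
non-positive global maximum clamps $p$ to 6; every ReLU output is zero in
that case, so any shift is exact. The final layer's decision is the argmax
of its raw 32-bit sums (ties to the lowest class index); requantizing a
layer that feeds no successor would only discard information.

Two invariants anchor the test suite: the blocked result is bit-identical
for every valid $(M, N)$, including blocks larger than any layer; and
every requantized activation lies in $[0, 127]$ with its leading 1 at
position $\le 6$. Overflow anywhere is a hard error, never wraparound —
the modelled hardware sizes its accumulators to exclude it, and silent
wraparound would corrupt verification.

## The latency model

Module latencies follow one closed form,
$D\,(A \lceil \log_2 B \rceil + C)$ cycles: $A$ pipeline stages per tree
layer, fan-in $B$, constant offset $C$, call count $D$. The defaults
realize the standard datapath: `L_QA = 1`, `L_MM = 1 + ceil(log2 M)`,
`L_AC = 1`, `L_MX = ceil(log2 N)`, `L_LO = ceil(log2 32) = 5` (the
leading-one tree has a fixed 32-bit input). All five can be overridden to
model a different hardware realization, e.g. a comparator-heavy max
search.

Latency splits into a **variable critical path** — the
$\sum_i \lceil \mathrm{rows}_i/N \rceil \lceil \mathrm{cols}_i/M \rceil$
block cycles, which shrink as $M, N$ grow — and a **persistent critical
path**, the fixed per-layer tail
($\lceil \log_2 M \rceil + \lceil \log_2 N \rceil + 8$ cycles), which
grows with $M, N$. The total adds one single-cycle buffer transfer
between consecutive layers. The PCP also has a compact summary form,
$K(\lceil \log_2 M \rceil + \lceil \log_2 N \rceil + 8) - 1$, which is
exactly $K$ cycles tighter than the persistent portion of the full total
(the summary drops the per-layer transfer bookkeeping); we treat the full
total as authoritative for optimization and expose both. $M$ and $N$ may
be any positive integers — the ceil-logs are well defined off powers of
two — but the CLI warns off the power-of-two lattice, where hardware
sweeps are normally reported.

## The control schedule

The control plane is instruction-free: a single global counter fires every
trigger at precomputed cycle values ("latency tags"), with no feedback
from modules. `layer_tags()` computes the twelve implemented tags verbatim
from the module constants and the layer's block counts; tags 2 and 3 are
reserved for external connectivity and are deliberately *absent* from the
map rather than zero-filled, so indexing them fails loudly.
`build_schedule()` expands the tags into a full per-cycle trigger trace —
block feeds, max updates, the leading-one latch, the single-cycle bank
swap between the buffer's write bank and read bank — and
`simulate_inference()` replays that trace against the functional datapath
under the two-bank discipline (the next layer reads only the bank written
at the swap). Column blocks iterate innermost, matching the
accumulate-register reuse; the counts, not the order, determine the cycle
totals. The simulator works at the resolution of the module latency
constants — that is the resolution of the closed-form model and the tag
table — not at per-gate pipelining. Its central property, checked over
hundreds of random shapes and both benchmark shapes, is that the
schedule's completion cycle equals the closed form exactly, and its
functional outputs are bit-identical to the direct blocked implementation.

## Design-space exploration

A multiplier budget of $2 \cdot \mathrm{DSP} + \mathrm{ALM}$ (each DSP
block hosts two multipliers) bounds $M \cdot N$. The explorer enumerates
admissible pairs (powers of two by default, full grid behind a flag),
evaluates the closed-form total for each, and ranks ascending. Ties break
toward larger $M$, then smaller $N$ — measured hardware favours spending
resources on $M$ — and the full ranking is retained rather than a single
winner, because under the closed form alone several configurations can sit
within a few cycles of each other. For the large benchmark shape
(15154 x 512 x 512 x 2) the block cycles dominate: the winning
configuration's VCP exceeds 95% of its total, so in this regime the
explorer is effectively minimizing block count subject to the persistent
tail's slow growth.

## Synthetic spectra and the reference trainer

The generator emulates the *statistical shape* of two-class SELDI
profiles, not mass-spec physics: a log-normal baseline (meanlog 0,
sdlog 0.5) over `n_features` positions, plus Gaussian-shaped peaks
(default: 6 per class, amplitude 4, width 3 features, per-case amplitude
jitter of ±30%) at class-specific locations drawn once per dataset,
disjoint between classes. Intensities are nonnegative by construction and
everything is a deterministic function of the spec's seed. Presets mirror
the published benchmark shapes: `"ovarian-like"` (15154 features,
160 train / 92 test), `"jnci-like"` (15154 features, 100 train / 32 test),
and `"small"` (1024 features, 160/92) for fast end-to-end runs. Case
counts are totals split evenly across classes, with odd counts giving the
extra case to class 0. What the generator does *not* reproduce: correlated
baselines, peak-location drift, instrument saturation, class-imbalanced
prevalence. Passing tests therefore demonstrate the pipeline's arithmetic
and timing fidelity, not diagnostic performance on real spectra.

The bundled trainer is deliberately minimal — dense layers, ReLU hidden
activations, softmax cross-entropy, He-scaled Gaussian initialization,
plain mini-batch SGD (default 40 epochs, learning rate 0.05, batch 32) on
inputs normalized to $[0, 1]$ by the training-set maximum. It exists so
the pipeline is testable with no external data or frameworks; any
externally trained model can be imported through the JSON model format.
Training is seeded and reproducible; `epochs = 0` returns the seeded
initialization untouched.

The bridge property tying everything together: on the `"small"` preset
with a 1024 x 64 x 2 model, the fixed-point argmax agrees with the float
argmax on at least 95% of held-out cases for at least 8 of 10 seeds — a
desk-scale stand-in for the observation that 8-bit conversion preserves
high classification accuracy.

## Numerical choices

All integer arithmetic runs on R doubles, which represent integers exactly
up to $2^{53}$; every quantity on the datapath is bounded by $2^{31}$ and
guarded (`check_int32()`), so no precision is ever lost. Ceil-log is
computed by integer doubling, not `log2()`, to avoid floating-point edge
cases at powers of two. Model JSON is written with 17 significant digits
so float weights round-trip bit-exactly. Argmax ties (both paths) resolve
to the lowest class index. Degenerate inputs fail fast: all-zero weight
layers (degenerate scale), empty max streams, dimension mismatches, and
any accumulator overflow raise errors rather than propagating garbage.

## Problem sizes used in the checks

Randomized oracle comparisons use models with layer sizes 2–9 (50 models
by 3 block configurations for the blocked-vs-unblocked equivalence;
200 random shape/(M, N) draws for schedule-vs-closed-form agreement), the
two benchmark shapes exercise the latency path at full scale, and the
fidelity bridge trains 10 seeded models at 1024 x 64 x 2 on 252-case
datasets. These sizes make the whole suite run in well under a minute
while covering every code path; the properties they check are
size-invariant (bit-exactness and cycle-exactness do not get harder with
larger layers, only slower to verify).

## Known limitations

- The latency model predicts cycles, not wall-clock time; clock frequency
  and compiler pipelining effects are out of scope.
- Static bias scales cannot track per-case truncation shifts; deep
  networks with many hidden layers would accumulate scale mismatch.
- Per-layer (not per-row or per-channel) weight scales, by design.
- The explorer optimizes the closed form only; measured per-module
  penalties can be injected via `module_latency_spec()` overrides but no
  calibration data ships with the package.
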