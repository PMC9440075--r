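---
title: "The scaled-gamma-tanh activation: model, backward rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scaled-gamma-tanh activation: model, backward rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgtnet)
```

## The activation model

An SGT layer transforms each feature `x` of channel `n` in two steps. Step
one is a channel-wise gamma correction with fixed branch gains and
learnable exponents,

$$y = \begin{cases} a\,x^{|\alpha_n|} & x < 0 \\ b\,x^{|\beta_n|} & x \ge 0,\end{cases}
\qquad a = 0.1,\; b = 1.1,$$

and step two squashes with the hyperbolic tangent, $z = \tanh(y)$. A
fractional power of a negative base is complex; only the real part of the
principal branch is kept, $\mathrm{real}(x^p) = |x|^p\cos(\pi p)$ for
$x<0$. This is the only convention under which a unit exponent recovers the
identity on the negative axis ($(-0.5)^1=-0.5$) and hence the
Leaky-ReLU-like shape of the activation at $\alpha=\beta=1$. Exponents are
used as absolute values wherever they appear as powers, so the gamma
correction always has a positive exponent; at $x=0$ both branches give 0
and the point is assigned to the positive branch.

The exponents $\alpha_n,\beta_n$ are learnable per channel (64 values each
per layer in the reference network, initialized uniformly on (0, 1)); the
gains $a,b$ are fixed. With both exponents at 1 the layer behaves like
tanh on the positive side and like a Leaky-ReLU with slope 0.1 on the
negative side.

## The backward rules, and why they are not the chain rule

The layer's input gradient is defined as

$$\frac{dL}{dx} = \mathrm{sech}^2(Y')\,\frac{dL}{dz},\qquad
Y' = \frac{dy}{dx} = \begin{cases} a\,\alpha_n\,\mathrm{real}(x^{|\alpha_n|-1}) & x<0\\
b\,\beta_n\,\mathrm{real}(x^{|\beta_n|-1}) & x\ge 0.\end{cases}$$

Note that $\mathrm{sech}^2$ — the derivative of $\tanh$ — is applied to the
step-1 *derivative* $Y'$, not to the pre-tanh value $y$. The exact chain
rule would be $\mathrm{sech}^2(y)\,Y'\,dL/dz$. The deviation is deliberate
and is the package's training default: it is confirmed by the rule's own
closed-form consequences, namely that at $\alpha=\beta=1$ the factor is the
branch constant $\mathrm{sech}^2(1.1)=0.3592$ for $x\ge0$ and
$\mathrm{sech}^2(0.1)=0.99006$ for $x<0$ (both reproduced by
`sgt_backward_input()` to machine precision). Because the factor never
approaches zero on the negative branch, gradients survive depth better
than under plain tanh. The calculus-exact gradient remains available as
`sgt_true_gradient()` for diagnostics and finite-difference validation and
is never used in training.

The exponent gradients accumulate over the batch and all spatial positions
of a channel,

$$\frac{dL}{d\alpha_n} = \sum_{x<0} a\,\mathrm{real}(\log_{10} x)\,
\mathrm{real}(x^{|\alpha_n|})\,\frac{dL}{dz},$$

analogously with $b$ on $x>0$ for $\beta_n$; $\mathrm{real}(\log_{10}x)$
for negative $x$ is $\log_{10}|x|$. The base-10 logarithm (where exact
calculus would give a natural log times the step-1 output) is kept
verbatim — fidelity to the published rule over calculus correctness.
Summation is over batch and space only, never over channels, since the
exponents are declared channel-wise.

**Zero guard.** $\log(0)$ and $0^{p}$ with $p<0$ are indeterminate. Before
any log or potentially-negative-exponent power in the backward rules, exact
zeros in $x$ are replaced by 0.001 (`zero_guard()`); the forward pass uses
raw values, where no indeterminacy arises. The same replacement applies to
exponents that reach exactly 0.

**Open choices resolved.** Whether the *multiplicative* $\alpha$ in $Y'$
should also be absolute-valued is unspecified in the source; we use the raw
signed value (switchable via `abs_multiplier`), which is immaterial to the
result because $\mathrm{sech}^2$ is even — an invariance the test suite
asserts. Trained exponents are reported by `alpha_beta_report()` but never
range-enforced, since observed ranges are quoted inconsistently in the
source material.

## The network

`divnet_spec()` builds the diverging architecture: four blocks of
(convolution, batch normalization, activation, max pooling) with kernels
3³, 5³, 7³, 9³, 64 filters, pool window 2 at strides 1, 2, 3, 4, then a
fully connected layer as wide as the flattened map (1728 at the reference
scale), 50% dropout, a 3-way fully connected layer and softmax. Shape
inference and parameter counting are symbolic (`infer_shapes()`,
`count_parameters()`) and reproduce the reference chain
64→63→31→10→3 and counts 1728 / 512,000 / 1,404,928 / 2,985,984 conv
weights and 1728² first-FC weights exactly.

Numerical choices where the source is silent: batch-norm epsilon 1e-5 and
running-statistics decay 0.9 (common defaults, configurable); convolution
is cross-correlation (no kernel flip); 'same' padding is symmetric (all
kernels are odd); dropout uses inverted scaling so evaluation is the
identity; input normalization subtracts the per-voxel mean map of the
training split ("zero-center"); Glorot uniform initialization with
variance $2/(\mathrm{fan_{in}}+\mathrm{fan_{out}})$ for conv/FC weights and
U(0,1) for the SGT exponents. The tensor layout is
`(batch, channel, d1, d2, d3)`; spatial-first notations elsewhere are a
display convention mapped at the I/O boundary.

3D convolution and max pooling (forward and backward) are implemented in
C++ via Rcpp — no installed R package offers these primitives with
user-controlled backward — while every other layer is vectorized R on
BLAS. The complete backward pass is validated against central finite
differences on a small all-tanh network (the SGT layers are excluded from
that check precisely because their training rule is intentionally not the
derivative of their forward pass; they are validated against a literal
scalar-loop oracle instead).

## Training

`train_loop()` runs shuffled mini-batches with either the published Adam
variant or SGD with momentum. The Adam update is
$w \leftarrow w - \mathrm{lr}\, m/(\sqrt{v}+\varepsilon)$ with
$m \leftarrow 0.9\,m + 0.1\,g$, $v \leftarrow 0.990\,v + 0.010\,g^2$,
$\varepsilon = 10^{-8}$, and **no bias correction** — the published update
verbatim; standard bias-corrected Adam sits behind
`adam_state(bias_correction = TRUE)`. A practical consequence worth
knowing: without bias correction the per-step displacement is bounded by
roughly the learning rate, so convergence horizons scale like
$1/\mathrm{lr}$. Cross-entropy probabilities are floored at $10^{-12}$ so
an empty target probability yields a large finite loss rather than
infinity. SGDM uses momentum 0.9 (toolchain default). The learning rate
follows $0.001 \times 0.95^{\lfloor \mathrm{epoch}/10\rfloor}$. Mini-batch
size defaults to 8 (unstated in the source; small enough for desk-scale
memory, large enough for usable batch-norm statistics). Per-epoch data
order is reshuffled with a seed derived from the run seed and epoch index,
so runs are bit-reproducible.

**Stratified 5:2:3 split.** `stratified_split()` allocates per class by
largest remainder: the test subset is resolved first against a total of
$\lfloor\sum_c n_c \cdot 0.3\rfloor$ units, then validation against
$\lfloor\sum_c n_c \cdot 0.2\rfloor$, remainder to train, ties in the
remainders going to the larger quota. For class counts (209, 305, 474)
this reproduces the reference cohort exactly: test (63, 91, 142) = 296,
validation (41, 61, 95) = 197, train (105, 153, 237) = 495. We note this
because the flooring of the *subset totals* (rather than rounding) is what
makes all three published totals come out simultaneously; with rounded
totals the validation set would have 198 members.

## Evaluation metrics

Confusion matrices are oriented rows = true class: the six embedded
reference matrices have row sums (63, 91, 142), the per-class test totals,
which doubles as their transcription checksum. Under this orientation the
published per-class "precision" equals diagonal/rowsum (conventionally
recall); `class_precision()` reproduces the published vectors and
`class_precision_predicted()` exposes the column-normalized quantity under
a separate name — we reproduce the source rather than silently correct it.
Cohen's kappa is $(p_o-p_e)/(1-p_e)$ from the marginals. Two printing
conventions surfaced during verification and are documented in
`reproduce_table3()`: the published kappa column truncates (not rounds) its
third decimal, and the published tanh-row kappa of 0.897 is inconsistent
with its own matrix (the formula gives 0.881); that row is flagged, not
matched.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` draws labelled cubes with a dark background
(level 0.05) plus Gaussian noise (s.d. 0.02) and one bright concentric
spherical shell per volume whose radius fraction differs by class (0.35,
0.55, 0.75 of the half-edge; shared thickness and intensity 0.8), with a
small Gaussian jitter of the centre. The shell geometry loosely evokes
atrophy/ventricle differences between diagnostic groups while remaining
trivially auditable: a fixed-shell mean-intensity probe separates the
classes perfectly at zero noise and degrades monotonically as noise grows,
a property the test suite checks at three noise levels. These defaults
were chosen once as a plausibly separable desk-scale stand-in and all
generator parameters are exposed in `synthetic_spec()`.

What passing tests on these volumes *do* show: the full pipeline — layers,
custom backward rules, optimizer, schedule, split, metrics — can drive
training loss down and classify held-out volumes on structured 3D signal.
What they do *not* show: anything about real MRI, whose discriminative
signal is anatomically diffuse, non-spherical, and entangled with
acquisition effects; no skull stripping, registration or bias-field
correction is modelled, and the published end-to-end accuracy on clinical
data is out of reach of this synthetic setting by design.

Volumes round-trip through NIfTI via the RNifti reader/writer; 4D files
keep their first frame with a warning. `resize_to_cube()` uses trilinear
interpolation under the pixel-centre convention (the interpolation scheme
of the original preprocessing is unstated; trilinear is the standard
choice and an identity-size resample is exact).

## Problem sizes used by the checks

Tests run the network at cube edges 12–16 with 2–8 filters — the smallest
sizes at which the four-block pooling chain remains valid — chosen so the
whole suite completes in a few minutes on one CPU. The training-sanity
check trains the all-SGT plan for 15 epochs on 20 volumes per class at
edge 16 (batch 4, Adam at 0.005) and requires at least 90% accuracy on the
training split afterwards. The reference-scale architecture (edge 64,
64 filters) is exercised symbolically (shapes, counts, initialization
statistics) rather than trained.

## Known limitations

* The paper-faithful backward rules mean the training gradient is not the
  gradient of the loss; optimization still descends in practice (the test
  suite demonstrates it) but no convergence guarantee carries over.
* Batch normalization in eval mode relies on running statistics; with very
  few training steps those remain close to their (0, 1) initialization.
* The C++ kernels are straightforward loop nests: adequate at desk scale,
  not competitive with GPU frameworks at the reference scale.
* `stratified_split()` requires every class to admit three non-empty
  subsets; degenerate cohorts error out rather than silently merging.
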