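---
title: "The double-balanced loss: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double-balanced loss: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbloss)
```

## The problem

Medical image collections are rarely balanced. In colorectal white-light
endoscopy, roughly three quarters of polypoid lesions are adenomatous, so a
classifier trained with plain cross-entropy sees adenomas constantly and
cancers rarely; it learns to be good at the majority class and to miss the
minority one — the clinically expensive mistake. A second, distinct
imbalance is in *difficulty*: most samples of any class are easy, and their
accumulated small losses can drown out the few hard samples that actually
carry information about the decision boundary.

The double-balanced (DB) loss addresses both imbalances inside the loss
function, leaving data and architecture untouched.

## The model

### Size balance via effective sample sizes

New samples of a class overlap, in feature terms, samples already seen, so
the *effective* number of samples grows sublinearly in the raw count $n$:

$$E_n = \frac{1-\beta^{n}}{1-\beta}, \qquad \beta \in [0,1).$$

$E_n$ is the partial geometric sum $1 + \beta + \dots + \beta^{n-1}$: it
equals $n$ in the limit $\beta \to 1$ and saturates at $1/(1-\beta)$ for
large $n$. Inverting and normalizing gives the size-balance factors

$$\alpha_i = \frac{1/E_{n_i}}{\sum_j 1/E_{n_j}}, \qquad \sum_i \alpha_i = 1,$$

which weakly decrease in the class count.

### Difficulty via the prior-prediction distance

Each class gets a prior from its inverse frequency, tempered by an
exponent $\rho \ge 0$:

$$pp_i = \frac{n_i^{-\rho}}{\sum_j n_j^{-\rho}}.$$

$\rho = 0$ gives the uniform prior; $\rho = 1$ the inverse class
frequency. The difficulty of one sample is measured by the cross-entropy
distance between this prior and the prediction, restricted (via one-hot
extraction) to the true class $y$:

$$d(p, y) = -pp_y \log p_y.$$

A confidently correct prediction has $d \approx 0$; a wrong or uncertain
one on a rare class has large $d$.

### The combined loss

With $L = -\log p_y$ (natural logarithm), the default (`printed`) form is

$$\mathrm{DB}(p, y) = \bigl(1 + \alpha_y \, pp_y\bigr) \, L^2 ,$$

and the `derived` form, the literal composition of the size-balanced loss
$(1+\alpha_y)L$ with the difficulty weight $pp_y L$, is

$$\mathrm{DB}_{\mathrm{derived}}(p, y) = (1 + \alpha_y)\, pp_y \, L^2 .$$

The two published presentations of the loss disagree on this
parenthesization, so both are implemented behind the `variant` flag of
`loss_config()` and both satisfy the same qualitative properties:
non-negative, zero only at $p_y = 1$, strictly decreasing in $p_y$, and —
for unequal counts with $\beta, \rho > 0$ — strictly larger for rarer
classes at any fixed confidence. Neither variant is silently preferred;
`printed` is the default because it matches the loss as most readers will
have seen it typeset.

The squared log term is itself a difficulty mechanism: it grows
quadratically where cross-entropy grows linearly, so hard samples dominate
the batch gradient even before the per-class factors act.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `beta` | effective-size growth control, $[0,1)$ | 0.99 | with counts $\{838, 224, 305\}$, $\beta < 0.9$ makes all $E_n$ equal (no signal) while $\beta \to 1$ recovers raw counts; 0.99 sits where the class differences first become visible and was found near-optimal in the grid |
| `rho` | prior flexibility, $\ge 0$ | 0.25 | interpolates uniform (0) to inverse frequency (1); larger $\rho$ widens the between-class weight gap |
| `gamma` | focal modulation (comparison loss) | 2 | the customary focal default |
| `eps` | probability clamp before any log | 1e-12 | $(\log p)^2$ diverges quadratically; the clamp keeps losses finite without measurably moving any value at ordinary confidences |
| `lr`, `momentum` | SGD schedule | 0.005, 0.9 | the reference schedule; lr is multiplied by 1/3 every 3 epochs ("decreases by two-thirds" admits two readings — retain 1/3 or retain 2/3 — we default to retain 1/3 and expose `lr_decay`) |

`beta = 0` is permitted although the effective-size derivation assumes
$\beta \in (0,1)$: it is the analytic limit $E_n \to 1$ and makes the
class-balanced loss collapse to cross-entropy, which the identity tests
rely on. $\beta^n$ is computed as `expm1(n * log(beta))` so counts up to
$10^6$ neither overflow nor lose the $1-\beta^n$ difference to rounding.

Weights are computed **once** from the global training tallies and frozen
for the run — they are a property of the dataset, not of the mini-batch.
Tied counts give exactly equal weights; no jitter is added.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws class $i$ from an isotropic Gaussian at a fixed
center with common spread. The default specification reproduces the
three-class lesion bookkeeping exactly: the full profile
$\{1048, 280, 381\}$ (1709 samples) splits, stratified per class with
`round(0.8 * n_i)`, into the training profile $\{838, 224, 305\}$ (1367
samples) and a 342-sample test set. The default geometry — centers on a
circle of radius 1.2 in two dimensions, spread 1 — puts neighbouring
centers about $2.1\sigma$ apart: a moderate-overlap regime where the Bayes
rule is imperfect and the loss choice can matter.

Rounding (rather than flooring) the per-class training fraction is a
deliberate choice: it is the only rule that reproduces the printed
training profile and its 1367 total from the full collection.

What the generator does *not* emulate: image texture, intra-class
multimodality, label noise, annotation ambiguity, or any covariate shift
between collections. Passing the directional tests here shows the
mechanism works when the only pathologies are class imbalance and class
overlap; it does not certify gains on real endoscopy data, where the
detection pipeline (localization, thresholds) contributes errors this
package deliberately leaves out of scope.

## The trainer

`db_fit()` trains a linear-softmax model by mini-batch SGD with momentum,
using the package's own analytic gradients (chain rule through the softmax
Jacobian; for cross-entropy this is the familiar $p - \mathrm{onehot}(y)$,
and every kind is verified against central finite differences in the test
suite). A linear model is the point, not a compromise: the claim under
study is about the *loss*, and a fixed minimal architecture isolates it.
No hidden layer is provided; anything the linear model cannot separate
would confound loss effects with capacity effects. Gradients flow through
the full $(\log p)^2$ term — the difficulty factor is not detached — since
the loss is stated as a loss, not as a detached weighting.

Batch composition is plain uniform shuffling. All seeds are explicit, and
every seeded routine restores the caller's RNG state.

### Degenerate inputs and numerical corner cases

* Probabilities are clamped to $[\varepsilon, 1]$ before any logarithm.
* Non-finite logits during training raise an explicit divergence error
  carrying the epoch index, rather than propagating NaNs.
* Undefined rates (a class absent from the test set, or never predicted)
  surface as errors (`fnr()`, `fpr()`) or `NA` (`per_class_report()`),
  never as silent zeros, because a silent zero biases loss comparisons.
* Argmax prediction breaks ties toward the lower class index,
  deterministically.

## Problem sizes

The shipped experiments run at desk scale, chosen so the whole suite and
the acceptance script each complete in minutes on one CPU: 1709-sample
datasets in two dimensions, 12 epochs, batch 64, ten seeds for the
CE-versus-DB comparison and three per grid point for the
$\beta \times \rho$ sweep. These sizes already give the directional result
(higher minority recall, no-worse macro FNR/FPR under DB) with clear
margins across seed sets; they are not tuned quantities.

## Known limitations

* The comparison is classification-only; missed/wrong detection rates of a
  full detection system mix in localization failures that no
  classification loss can address.
* Macro-averaging of one-vs-rest FNR/FPR is a declared convention; the
  binary definitions do not dictate a multiclass aggregation.
* The DB loss's quadratic log term makes it more sensitive than
  cross-entropy to mislabeled samples (they look maximally hard); no
  outlier handling is included.
* With balanced counts the loss reduces to $(1 + 1/k^2)(\log p)^2$ — still
  a hard-example loss, so DB-versus-CE differences on balanced data
  reflect the difficulty mechanism alone.
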