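---
title: "Simulating federated learning for ultrasound steatosis classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated learning for ultrasound steatosis classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fedus` is a desk-scale simulation laboratory for a question that matters in
multi-center medical imaging: *how do data partitioning and the choice of
federated learning (FL) algorithm affect a model that classifies hepatic
steatosis (S0 vs S1 or higher) from B-mode ultrasound images?* Real
two-center cohorts of this kind are private; the package therefore ships a
synthetic cohort generator that emulates the relevant statistical structure
of such data, so that every component — partitioning, server aggregation,
local training, evaluation statistics — can be exercised end to end and
tested against oracles.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic results do and do not say about real data.

## The synthetic cohort

`cohort_config()` / `generate_cohort()` produce a two-site cohort shaped
like a real two-center steatosis case-control study:

* a **private-like** site: 153 patients, 35/51/29/38 across grades 0-3,
  age 52 ± 13 y, BMI 30.8 ± 8.0 kg/m², 49% male;
* a **public-like** site: 55 patients, 17/20/8/10, age 40 ± 9 y,
  BMI 45.9 ± 5.6 kg/m² (a bariatric-surgery population), 20% male;
* ten grayscale images per patient; the binary class is S0 (grade 0)
  versus S1plus (grades 1-3), giving 52 vs 156 patients globally.

Counts are configuration, never sampled; ages and BMIs are truncated
normals (age ≥ 18, BMI ≥ 15 — the table-style summaries only give
mean ± SD, so truncation bounds are a package choice); sex is Bernoulli.
Demographics exist for manifest realism only — the classifier never sees
them. The whole cohort, images included, is a pure function of the
configuration (including its seed).

## The image model

`render_image()` synthesizes a B-mode-like frame from the two textbook
sonographic signs of steatosis:

$$ I(r, c) \;=\; \underbrace{(B + g_s + k_e \cdot \text{grade})}_{\text{echogenicity}}
   \; \cdot \; \underbrace{e^{-(a_0 + k_a \cdot \text{grade})\, d(r)}}_{\text{posterior attenuation}}
   \; \cdot \; S(r, c), $$

where $d(r) \in [0, 1]$ is depth, and $S$ is unit-mean speckle — the
envelope of two independent Gaussian fields smoothed to a correlation
length of `speckle_scale` pixels (Rayleigh-distributed before smoothing,
the standard fully-developed-speckle model). Defaults: base level $B = 80$,
echogenicity slope $k_e = 15$ intensity units per grade, attenuation
$a_0 = 0.4$, $k_a = 0.45$ per unit depth per grade. Pixels are quantized to
integers in [0, 255] so datasets round-trip bit-exactly through 8-bit PNG.

**Site effects.** A single-center model only underperforms on an outside
center if the centers genuinely differ, so the generator models the
acquisition differences one would expect between a standardized
bariatric-imaging protocol and a mixed fleet of clinical scanners:

* **speckle scale** — 5 px at the public-like site (low-frequency sector
  probe, coarse point-spread function) vs 2.5 px at the private-like site;
* **gain offset** — +18 intensity units at the public-like site
  (different preset/TGC);
* **field of view** — the public-like site produces fan-shaped sector
  frames (black surround); the private-like site full rectangular frames;
* **automatic gain compensation** — public-like images are rescaled to a
  fixed mean brightness inside the fan, as scanner auto-gain does. On that
  site the steatosis signal therefore survives only in the
  depth-attenuation profile and the texture, not in absolute brightness.

These effect sizes were fixed once, against two design requirements stated
up front: (i) a pooled logistic regression on mean-intensity features must
separate the classes with AUC > 0.8 (the task is learnable), and (ii) the
cross-site shift must be large enough that a model trained on one center
alone shows a real deficit on the other — the phenomenon the federated
comparison is about. They are configurable (`cohort_config()`), so task
difficulty can be dialed up or down.

What the generator does **not** model: real anatomy (vessels, diaphragm,
kidney), operator variability, scanner-specific artifacts of named
devices, biopsy-timing effects, or any within-patient disease
heterogeneity — the ten images of a patient are independent draws from the
same grade-conditional distribution. Passing tests therefore demonstrate
that the *pipeline* behaves as specified under a controlled, plausible
image model; they do not certify clinical performance.

## Train/test split and partitioning

`make_test_split()` reserves, per site, five patients of each binary class
(10 + 10 by default) — a class-balanced test set; everything else is the
training pool (with the default cohort: 42 S0 and 146 S1plus patients).
Splits are by patient; all images follow their patient everywhere in the
package.

Four partition strategies turn the pool into simulated FL sites:

1. **Distribution-based class skew** — per class, site shares drawn from a
   symmetric Dirichlet $\mathrm{Dir}(\beta)$;
2. **Quantity-based class skew** — each site owns a fixed set of classes;
   one class per site is the extreme where site 1 holds all 42 S0 and
   site 2 all 146 S1plus patients;
3. **Quantity skew** — site *sizes* drawn from $\mathrm{Dir}(\beta)$,
   composition left to chance (unstratified by design; a `stratify`
   variant was considered and rejected as it would blunt the scenario);
4. **Source-based** — sites are the true centers of origin.

`imbalance_scenario()` builds the global-imbalance/local-heterogeneity
grid: a subsample of 84 patients with a chosen S0 fraction (10-50%),
split so that each site's class distribution is the mixture
$P_i = \alpha P_{\text{global}} + (1 - \alpha)\,\delta_{c_i}$, with the
pinned class $c_i$ cycling S0, S1plus by site index. One subtlety is not
stated by the mixture itself: with $\alpha < 1$ and an unbalanced global
distribution, *equal* site sizes cannot reconcile with conservation of the
global composition. Site totals therefore interpolate between equal shares
($\alpha = 1$) and class-proportional shares ($\alpha = 0$) — the unique
sizing for which the realized counts can match both the mixture and the
global composition exactly.

Fractional counts everywhere use largest-remainder (Hamilton)
apportionment — it conserves totals exactly and is order-independent given
the fixed tie-break (lower index wins). Heterogeneity is quantified by the
size-weighted cosine similarity $\overline{CS} = \sum_i (n_i/n)\,
\mathrm{CS}_i$ between site and global class-count vectors; empty sites
are structurally allowed, excluded from the metric (the cosine of a zero
vector is undefined) and flagged.

## Local training and the network

No deep-learning framework is assumed: the package implements its own
small sequential conv-net (3×3 same-padding convolutions and 2×2 max
pooling compiled via RcppArmadillo; dense layers, activations, Adam and
backpropagation in R, verified against finite differences to 1e-4
relative error).

Two architectures: `vgg16_like` (the thirteen-convolution VGG16 stack,
128 × 128 × 3 inputs, small dense head, sigmoid scalar output) preserves
the full-scale configuration for users with patience or better hardware;
`tiny` (three conv/pool blocks, 64 × 64 × 3 default) is the desk-scale
workhorse. Initial weights are Glorot-uniform (a uniform distribution with
fan-based bounds — the natural reading of "random uniform initialization"
when bounds are unstated), drawn from a seed shared by every site so all
parties start from the same model. Grayscale frames are zero-padded to a
square (extra pixel bottom/right), bilinearly resized, scaled to [0, 1]
and replicated to three channels.

Training uses focal loss (γ = 2, positive-class weight α = 0.25 — the
standard defaults where a study leaves them unstated), Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-7), batch size 32, and flip/±15° rotation augmentation.
Predicted probabilities are clipped to [1e-7, 1 − 1e-7] before the loss,
with a warning. FedProx adds the proximal penalty
$\frac{\mu}{2}\lVert \omega - \omega^{t-1} \rVert^2$ inside the local
objective (gradient $\mu(\omega - \omega^{t-1})$); its server step is
identical to FedAvg. One consequence of using Adam locally: because Adam
normalizes gradient magnitudes, a growing μ drives the local update toward
the anchor but the distance saturates at a step-size floor rather than
shrinking to zero — the tests assert the monotone regime and the
small-ball regime separately.

## Server algorithms

Each round: broadcast, local training at every non-empty site, then the
size-weighted average $\omega_{\text{avg}} = \sum_i (n_i/n)\,\omega_i$
followed by the server update:

* **FedAvg / FedProx** — the average is the new global model.
* **FedAvgM** — momentum over the pseudo-gradient
  $\Delta_t = \omega^{t-1} - \omega_{\text{avg}}$:
  $v^t = \beta v^{t-1} + \Delta_t$, $\omega^t = \omega^{t-1} - \eta v^t$
  (defaults β = 0.9, η = 1). With β = 0, η = 1 the update short-circuits
  to the average itself so the algebraic reduction to FedAvg is exact in
  floating point, not just to round-off.
* **FedYogi** — adaptive step with the *opposite* sign convention,
  $\Delta_t = \omega_{\text{avg}} - \omega^{t-1}$ (both conventions
  implemented exactly as their respective update rules are conventionally
  written): $m^t = \beta_1 m^{t-1} + (1-\beta_1)\Delta_t$,
  $v^t = v^{t-1} - (1-\beta_2)\Delta_t^2\,\mathrm{sign}(v^{t-1} -
  \Delta_t^2)$ with $\mathrm{sign}(0) = 0$, and
  $\omega^t = \omega^{t-1} + \eta\, m^t / (\sqrt{v^t} + \tau)$. Defaults
  β₁ = 0.9, β₂ = 0.99, τ = 1e-3, η = 1e-2; the second moment starts at
  τ² elementwise so the denominator is well-conditioned at round one (the
  Yogi recursion then keeps it positive).

Server hyperparameters follow the algorithms' original papers since the
study configuration leaves them unstated. The transport layer is an
in-process loop: deterministic, single-machine, with per-(round, site)
seeds derived from the trial seed by a counter scheme, so any run is
exactly reproducible and sites are independent. Client sampling,
stragglers, secure aggregation and differential privacy are out of scope.

## Evaluation statistics

`roc_auc()` is the Mann-Whitney estimator (midranks, ties count ½);
`confusion_metrics()` reports accuracy, sensitivity, specificity, PPV and
NPV at a 0.5 threshold (overridable; the threshold is a package choice),
with zero-denominator ratios reported as `NA` with a warning, never as 0.
`jackknife_ci()` resamples by *patient* — images within a patient are
correlated, so the patient is the honest exchangeable unit — and uses the
normal quantile multiplier. `delong_test()` implements the
placement-value (structural component) test for two correlated AUCs; the
tests verify it against pROC's implementation and a 10⁵-resample paired
bootstrap. Confidence intervals can alternatively be taken across
training trials; the patient jackknife is the primary interval, and both
views are available from the per-trial results table.

## The experiment runner and desk-scale conditions

`experiment_config()` describes a full study; `run_grid()` executes it:
one shared test split, every scenario × algorithm × schedule × trial cell,
centralized and single-site (private-only) baselines, the imbalance grid,
and a DeLong comparison of the best federated cell against the single-site
baseline; `write_reports()` emits the scenario-by-algorithm results table, the
per-round curves, the imbalance grid with $\overline{CS}$, partition CSVs
and heterogeneity JSONs. A failing cell is recorded and the grid continues.
The `"full"` profile keeps the full-scale configuration (VGG16-style
network, 128 × 128 inputs, native image resolutions, schedules 1 × 100 and
5 × 20, imbalance grid at 50 rounds, 3 trials); the `"tiny"` profile (tiny
network, 64 × 64, schedules 1 × 20 and 5 × 5, imbalance at 10 rounds)
differs only in configuration.

The package's own test suite runs the directional study at these
desk-scale conditions, chosen once: tiny profile, 4 images per patient,
learning rate 1e-3 (the tiny network trains comfortably at a larger step
than the full-scale default of 1e-4), 15 rounds × 1 local epoch, five
trial seeds. Under those conditions the simulation reproduces the
qualitative findings: source-based federation matches or beats the
single-center baseline on the two-center test set; the one-class-per-site
extreme trails the IID mixture by more than the across-seed standard
error; expected $\overline{CS}$ rises with local homogeneity α; and
quantity skew is benign. The *numbers* differ from any real study —
a tiny network on synthetic speckle is not VGG16 on clinical images — it
is the ordering of scenarios that carries over.

## Known limitations

* The image model is stationary speckle plus two grade effects; real
  B-mode anatomy is far richer, and real grade effects are subtler.
* Patient images are i.i.d. given grade, so patient-level clustering in
  the jackknife is conservative rather than strictly necessary on
  synthetic data (on real data it would be essential).
* The binary task only; the four-grade ordinal problem is out of scope.
* The FedYogi/FedAvgM sign conventions follow their conventional
  printed forms, which differ from each other; each is verified against
  hand-worked scalar recursions.
* Center cropping is available (`crop_frac`) but defaults to off: the
  synthetic frames contain no irrelevant border to remove.
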