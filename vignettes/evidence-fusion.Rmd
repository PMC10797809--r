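---
title: "Paradox-free Dempster-Shafer fusion of classifier outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paradox-free Dempster-Shafer fusion of classifier outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evidfuse)
library(dplyr)
```

## The problem

When several classifiers score the same image -- say, two convolutional
networks of different depth grading a fundus photograph into one of seven
disease classes -- their softmax outputs rarely agree exactly. Decision-level
fusion asks: given each model's per-class probability vector, what single
decision should the ensemble emit?

Dempster-Shafer (D-S) evidence theory is the classical machinery for this.
A *frame of discernment* $\Theta = \{A_1, \dots, A_\varphi\}$ holds the
mutually exclusive hypotheses (here, the disease classes). Each evidence
source $s$ supplies a *basic probability assignment* (BPA): a mass function
$m_s$ with $m_s(A) \in [0,1]$ and $\sum_A m_s(A) = 1$. A classifier's
softmax output is exactly such a BPA, concentrated on singletons; this
package works with these singleton-only ("Bayesian") mass functions
throughout, because that is what softmax layers produce. Mass on composite
subsets, belief/plausibility intervals, and alternative rules (Yager,
Murphy, PCR) are deliberately out of scope.

Dempster's rule combines $l$ sources by product and renormalization:

$$(m_1 \oplus \cdots \oplus m_l)(A) \;=\; \frac{1}{1-k}\prod_{s=1}^{l} m_s(A),
\qquad
k \;=\; 1 - \sum_{A \in \Theta}\ \prod_{s=1}^{l} m_s(A),$$

where the *conflict factor* $k$ is the product mass falling on incompatible
label combinations and $1-k$ is the normalization coefficient. (For
singleton masses, "the sources agree" means they all name the same label,
which is how the conflict sum is implemented here.)

## The four paradoxes, and the remapping that removes them

The classical rule fails in well-known ways as $k \to 1$. The package ships
the four canonical failure fixtures (`paradox_fixtures()`):

* **complete conflict** -- two sources are point masses on different labels,
  $k = 1$, the denominator is zero and the rule is undefined;
* **zero trust** -- one source assigns a hypothesis mass 0, which vetoes it
  regardless of the other sources (the *one-vote veto*);
* **one trust** -- a hypothesis every source considers unlikely receives
  fused mass 1;
* **high conflict** -- a hypothesis strongly backed by four of five sources
  is dismissed.

```{r paradoxes}
fx <- paradox_fixtures()
combine_classical(fx$zero_trust)       # G wins; F is vetoed by one source
try(combine_classical(fx$complete_conflict))
```

The remedy implemented here does not change the combination rule; it
re-expresses the evidence. Every input BPA is remapped by exponential
(softmax) normalization before combination:

$$m'(A_\alpha) = \frac{\exp(m(A_\alpha))}{\sum_{i=1}^{\varphi} \exp(m(A_i))}.$$

The map is strictly increasing, so the ranking of hypotheses within each
source is untouched (ties stay ties), but every remapped mass is strictly
positive and the spread between masses shrinks. Two consequences follow
immediately: no single source can veto a hypothesis, and the post-remap
conflict factor is strictly below 1, so the combination never divides by
zero. All four paradoxes disappear:

```{r remapped}
combine_idset(fx$complete_conflict)    # F recovered, k = 0.959
combine_idset(fx$one_trust)            # H wins, as the evidence warrants
```

Remapping is applied **exactly once**, to the raw BPAs; the fused output is
not remapped again (re-remapping a `remapped_mass` is an error). Fusing the
remapped-then-combined output a second time through the remap would change
the worked-example results and has no justification in the rule.

### Numerical choices

* **Validation tolerance.** Row sums may deviate from 1 by `1e-6` (sized
  for CSV round-trips of softmax outputs); an opt-in `renormalize` divides
  by the sum. Fused masses are normalized exactly and checked to `1e-9` in
  the tests.
* **Complete-conflict detection.** $k \ge 1 - 10^{-12}$ counts as $k = 1$;
  exact zero products are the typical case, so the threshold only guards
  rounding.
* **Products, not log-space.** With at most a few dozen sources and a few
  hundred labels the label products stay far above double-precision
  underflow; the batch path additionally rescales unnormalized products by
  their maximum before dividing.
* **Tie-breaking.** The decision is the argmax of the fused masses; masses
  within a relative `1e-12` of the maximum are treated as tied, the lowest
  frame index wins, and a warning is raised. This is not cosmetic: on the
  zero-trust fixture the remapped rule puts F and G in an *exact*
  mathematical tie (the remapped fused mass of label $A$ is proportional to
  $\exp\!\big(\sum_s m_s(A)\big)$, and the raw column sums of F and G are
  both 1.5), while floating-point evaluation separates them by one part in
  $10^{16}$. The tolerant tie-break makes the decision F, deterministically.
  Published treatments of this example that round the remapped masses to
  three decimals before combining report F slightly ahead of G
  (0.385 vs 0.382); at full precision the honest answer is the tie
  (0.3837, 0.3837, 0.2327), and this package computes at full precision.
* **Temperature.** `softmax_remap()` exposes a `temperature` argument for
  experimentation; it defaults to 1 and every documented result uses the
  parameter-free map.

## Batch fusion of prediction matrices

`fuse_predictions()` lifts the two-source diagram -- classifier A and
classifier B each produce a BPA per image, the BPAs are fused, the argmax
is the diagnosis -- to any number of sources and samples. Each sample's row
is fused independently, and the per-sample conflict $k$ is reported.
Softmax outputs are taken as BPAs directly; the remap happens inside the
`idset` rule, and no per-model calibration is applied. Under the classical
rule a completely conflicting sample cannot be fused; such samples are
collected into a failure report rather than aborting the batch, because the
classical rule's known failure mode should be observable, not fatal.

```{r batch}
sim <- gen_predictions(300, accuracies = c(0.85, 0.85), seed = 7)
fused <- fuse_predictions(sim$predictions, rule = "idset")
glance(fused)
mean(fused$decision == sim$truth$label)
```

## What the synthetic generator emulates -- and what it does not

`gen_predictions()` stands in for trained networks. It emulates the
statistical setting of two (or more) imperfect classifiers over an
imbalanced multiclass frame:

* **Class priors** default to the proportions of a 25,336-image seven-class
  fundus training corpus (N 13,588; D 6,665; G 1,046; C 1,260; AMD 1,138;
  H 497; M 1,142) -- a realistic, heavily skewed prior.
* **Accuracy** is exact by construction: each source predicts the true
  class with its target accuracy, errors uniform over the wrong classes.
* **Sharpness**: the predicted class receives mass
  $p = \mathrm{conc}/(\mathrm{conc}+1)$ (default concentration 8, so
  $p = 8/9$, a typical confidence for a trained softmax); the residual
  $1-p$ is spread over the other classes by a Dirichlet draw, and rows
  approach one-hot as the concentration grows.
* **Runner-up signal**: when a source errs, the true class's share of the
  residual receives Dirichlet weight `runner_up_bias` (default 4, vs 1
  for the other classes); when it is correct, the residual is symmetric.
  This reflects a robust empirical property of softmax classifiers: on
  misclassified inputs the true class is usually a high runner-up. The
  parameter matters more than it looks. If the residual were fully
  symmetric, a disagreement between a correct and an incorrect source
  would be decided by a comparison of two i.i.d. residual shares -- a fair
  coin under any product rule -- and fused accuracy could only equal, never
  exceed, single-source accuracy. The runner-up signal is precisely the
  disagreement-resolving information that makes ensemble fusion profitable,
  so the generator includes it by default.
* **Error correlation**: under `errors = "independent"` each source errs on
  its own samples and fusion resolves their disagreements; under
  `"shared"` all sources err on the same samples, there is nothing to
  resolve, and fusion yields no gain. The shared mode is the negative
  control that the mechanism of any observed gain is disagreement
  resolution, not arithmetic.

What the generator does **not** model: inter-class visual similarity
structure (confusions are uniform), per-model calibration differences,
correlated confidence between sources on correct samples, and anything
about actual images. Passing the fusion-gain tests therefore demonstrates
that the rule exploits disagreement with a runner-up signal -- not that any
particular accuracy will be reached on real fundus data.

The fusion-gain testbed used by the test suite runs 50 replicates at
$n = 500$ samples with two 0.85-accuracy sources, and checks that remapped
fusion beats both sources in at least 95% of replicates (independent
errors) and shows no gain under shared errors. These sizes keep the whole
suite comfortably fast while leaving binomial noise at $n = 500$
(about $\pm 1.6$ percentage points per replicate) well below the observed
gain (about $+9$ points).

## Evaluation metrics

`metrics_report()` evaluates decisions against truth with the standard
multiclass panel: per-class one-vs-rest precision, recall, specificity and
F1; accuracy; unweighted Cohen's kappa (classes are nominal); and
per-class one-vs-rest AUC via the rank (Mann-Whitney) statistic with
midranks, which equals trapezoidal ROC integration. Headline values are
macro averages (unweighted over classes), with per-class values always
emitted so any other aggregation can be recomputed. Rates with zero
denominators are reported as `NA`, excluded from macros, and logged --
substituting 0 would silently deflate the averages.

Confidence intervals, when requested, are percentile bootstrap over samples
(default 2000 replicates, seeded). This is generic plumbing for uncertainty
on a held-out set, labelled as such; it is not tied to any particular
published interval protocol.

```{r metrics}
rep <- metrics_report(sim$truth, scores = fused, ci = TRUE, boot = 200,
                      seed = 1)
rep$summary
```

## Image augmentation

The augmentation module implements a sixfold expansion used for fundus
corpora: each image yields the original, a random rotation, horizontal and
vertical mirrors, and the RBG and BGR channel permutations -- the unique
composition of that transform list under which $n$ images become exactly
$6n$ (e.g. 5258 become 31,548). Design choices where the recipe is
underdetermined:

* rotation angle uniform on $[-180^\circ, 180^\circ)$, bilinear, original
  canvas kept, exposed corners filled black (configurable via `angle`);
* resize is a direct bilinear rescale to a square target (default 512),
  no cropping;
* channel permutations and mirrors are pure reindexing: bitwise-invertible,
  with per-plane histograms preserved exactly (permuting channel planes
  changes rendered brightness and contrast but not image structure);
  rotation interpolates and is excluded from invertibility claims.

`split_train_test()` performs the seeded 8:2 split. Splitting *after*
augmentation -- as augment-then-split pipelines do -- places transformed
copies of one source image on both sides of the split; the utility supports
that workflow but warns about the leakage when told the data are augmented.

## Known limitations

* Singleton-only masses: this is a Bayesian-evidence toolkit, not a general
  D-S engine; composite focal elements would require the $2^\Theta$
  machinery and different paradox analysis.
* The softmax remap compresses evidence: after remapping, even a point mass
  retains at most $e/(e+\varphi-1)$ of the mass, so fused masses are far
  less extreme than classical ones. Decisions are unaffected (ranking is
  preserved per source), but fused masses should not be read as calibrated
  probabilities.
* The remapped rule resolves a genuine tie by frame order; callers who care
  about margins should inspect the fused masses, and no margin threshold is
  imposed.
* Bootstrap intervals assume i.i.d. samples; they are not valid across
  augmented copies of the same source image.
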