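---
title: "Evaluating LLM confidence signals on multiple-choice questions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating LLM confidence signals on multiple-choice questions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tokenconf)
```

## The problem

A language model answering a lettered multiple-choice question produces
two kinds of confidence. It can be asked to *verbalize* one ("rate your
confidence from 0 to 100"), and it implicitly holds one in the
probability it assigned to the answer token it emitted. Verbalized
confidence is known to cluster in a narrow high band (80–100, multiples
of 5) almost independently of correctness, which makes it dangerous in
high-stakes settings: a user cannot tell a confident right answer from a
confident wrong one. The token-level probability, by contrast, disperses
across the options precisely when the model hesitates.

`tokenconf` operationalizes this comparison. Given a QA item set and an
answer log carrying per-position top-k token log-probabilities, it
computes four per-answer signals and evaluates each along two distinct
axes:

* **discrimination** — can the signal *rank* correct answers above
  incorrect ones? (AUROC, DeLong tests, Youden thresholds);
* **calibration** — does the signal's *value* match empirical accuracy?
  (adaptive calibration error, Brier score).

A signal can discriminate well while being badly calibrated (token
probabilities skewed toward 1 still rank answers usefully), which is why
both axes are reported.

## Signals

Let the answer-token position hold top-k entries with natural-log
probabilities. For the chosen letter $\ell$:

* **Token probability** $p(\ell)$, taken *raw*. It is deliberately not
  renormalized over the option letters: if half the mass sits on
  non-letter tokens, the model was genuinely less committed to any
  letter, and renormalizing would hide that. This matches what an API
  user can read off directly.
* **Entropy** $H = -\sum_o p_o \log_2 p_o$ over the option letters, with
  the top-k mass not matching any letter folded in as one residual
  pseudo-outcome. Treating the residual as a single outcome keeps the
  distribution proper without inventing per-letter mass; the alternative
  (entropy over the full vocabulary top-k) is not recoverable once
  tokenizer variants are merged. Base 2 is a readability choice — any
  base is a strictly monotone rescaling, so ROC ranks are unaffected.
* **Perplexity** $\mathrm{PPL} = \prod_t 1/p_t = \exp(-\sum_t \ln p_t)$
  over *all* emitted tokens of the response (both template sentences),
  computed in log space. No length normalization by default (a
  length-normalized variant sits behind a flag); on fixed-template
  responses lengths are nearly constant, so the distinction is minor.
* **Expressed confidence**, stored raw on its declared scale (100 for
  the standard prompt, 1 for the confidence-scaling prompt) and divided
  by the scale maximum only when entering calibration, keeping the
  stored values auditable.

Entropy and perplexity are *doubt* scores; the discrimination layer
negates them so that every signal is oriented "higher = more confident"
and AUROCs are comparable. They are excluded from calibration because
they are not probabilities; only expressed confidence and token
probability are calibrated.

## Parsing and exclusions

Responses are elicited with a fixed template ("The correct answer is:
[letter]. My confidence level is: [number].") and parsed with a
case-insensitive, whitespace-tolerant regular expression. Off-template
responses go through a deterministic rule-based fallback (first
standalone uppercase option letter; first number within the scale) — a
reproducible stand-in for model-based fallback parsing, with the
`parse_status` field preserving the distinction so analyses can be rerun
on template-only records. The fallback does not accept lowercase
standalone letters ("a" is an English article); the template branch,
which has the phrase as context, does.

Parse failures are a *status*, not an error. Failed records are excluded
from every metric denominator and reported in an exclusion tally, making
explicit the kind of silent n-reduction QA studies often leave implicit.
A response whose letter never appears as an emitted token is likewise
flagged and excluded from token-level analyses only; a record with a
letter but no confidence number stays in accuracy and token-level
analyses and is excluded from expressed-confidence analyses only.

Answer-token matching strips leading whitespace/brackets and trailing
punctuation from token text (" B", "B.", "(B", "B)" all match B) because
tokenizer dialects differ across model families; the *first* matching
emitted token wins, which is the answer slot in the template.

## Discrimination analysis

The AUROC is computed in its Mann–Whitney form — the probability a random
correct answer outscores a random incorrect one, ties counting ½ — via
midranks in $O(n \log n)$, with the correct answer as the positive class.
Its variance, confidence interval and the paired comparison between two
signals on the same items use the DeLong structural-components estimator
(deterministic, no bootstrap needed). Degenerate edge: under exactly
perfect separation all structural components are constant and the DeLong
variance is genuinely zero; the paired test then returns p = 1 only when
the two AUCs are equal and raises an explicit error otherwise.

Optimal thresholds maximize Youden's $J = TPR - FPR$ over the observed
score values (no midpoints — mirroring the integer-percent thresholds
such data produce), with ties broken toward the **highest** threshold:
the conservative rule that flags the fewest answers as confident.
"Above" means `score >= threshold`, so a threshold of 1.0 keeps
probability-1 answers above (a strict `>` variant is available).
Threshold blocks report TPR, FPR and the accuracy above/below with
Wilson intervals; signal-vs-signal comparisons of these indicator-based
rates use the exact-binomial McNemar test for fewer than 25 discordant
pairs and the continuity-corrected chi-square otherwise. Model-vs-model
accuracy contrasts use the Fisher exact test.

## Calibration analysis

Confidence distributions from LLMs are extremely skewed (most mass at
0.9–1.0), so fixed-width bins would leave most bins nearly empty.
Equal-mass (adaptive) binning sorts by confidence — stably, so ties keep
input order — and cuts into `n_bins` contiguous groups whose sizes differ
by at most one, larger groups first. Ties may span bin boundaries; no tie
merging, which keeps masses exactly balanced. The default of 10 bins is a
conventional reliability-diagram resolution, exposed as a parameter.

$ACE = \frac{1}{B}\sum_b |acc(b) - \overline{conf}(b)|$; with one bin it
degenerates exactly to |overall accuracy − mean confidence|. ACE > 0.25
is flagged as poor calibration. The Brier score
$\frac{1}{n}\sum_i (conf_i - y_i)^2$ complements it as a proper scoring
rule. Uncertainty for both comes from the percentile bootstrap (default
2000 replicates, mandatory seed); BCa corrections were deliberately
skipped — at the sample sizes involved (thousands of items) the
difference is negligible and the percentile form is transparent and
exactly reproducible. Paired signal comparisons bootstrap items jointly
and report $p = 2\min(P(\Delta^* \le 0), P(\Delta^* \ge 0))$ with
add-one smoothing, flooring p at $2/(reps+1)$.

## The synthetic generator

`simulate_items()` / `simulate_responses()` emulate the study conditions
the pipeline is meant for, with every draw a function of one seed:

* 4–5-option items, gold letter uniform;
* correctness drawn first, Bernoulli at `target_accuracy` (default 0.7,
  mid-range for current models on licensing-exam benchmarks);
* a latent confidence conditioned on correctness. Binormal mode:
  Normal(μ, 1) if correct, Normal(0, 1) if not, mapped through the
  logistic function to (0, 1) and used as the chosen letter's token
  probability (remaining mass spread evenly over the other letters). The
  logistic map is strictly monotone, so the true AUC is exactly
  $\Phi(\mu/\sqrt2)$ — the default μ = 1.4652 gives 0.85, within the
  range token probabilities achieve on real logs. Correctness-first
  conditioning was chosen over difficulty-first generation precisely for
  this closed form: recovery tests need an exact target. Dirichlet mode
  instead draws ragged option-probability vectors (flat for incorrect
  answers, concentrated on the chosen letter for correct ones) for
  realism; it has no closed-form AUC.
* verbalized confidence: `constant_high` pins it at `expressed_base`
  (default 95) — the nearly uninformative clustered profile real models
  produce, making expressed-confidence AUROC exactly 0.5; or
  `quantized_informative`, `clip(round5(100(s + δ)))`, quantized to
  multiples of 5 like real verbalized scores, with δ the overconfidence
  offset used in calibration-recovery tests.
* every response follows the elicitation template exactly, tokens are
  emitted with probability 1 except the answer token, and top-k depth
  (default 5, the common API limit) is constant within a record.

Note one subtlety the calibration tests must respect: because
correctness is drawn first, the latent score is *not* perfectly
calibrated even at δ = 0 — the population probability of correctness
given the score follows from Bayes' rule on the binormal mixture. The
recovery tests therefore compare the sample ACE against a numerical
evaluation of that closed form rather than against δ itself.

What the generator does **not** emulate: off-template and free-text
responses (real logs need the fallback parser; simulated ones never do),
per-item difficulty structure, language effects, correlated errors
between prompt variants, and non-letter token mass at the answer
position. Passing recovery tests therefore demonstrates the statistical
machinery is correct, not that any particular model is well or poorly
calibrated.

## Numerical choices and degenerate inputs

* Log-probabilities stay in natural log from file to metric code and are
  exponentiated once, avoiding silent double-exponentiation.
* AUROC via midranks is exact under ties (verified against the
  $O(n^2)$ pairwise oracle); monotone-transform invariance holds to
  machine precision.
* Single-class inputs (all correct or all incorrect) are an error for
  every ROC quantity, not a silent 0.5 or 1.
* Empty threshold strata yield `NA` estimates and a flag rather than
  0/0.
* Wilson intervals are used for all proportions (they behave at 0 and
  1, where Wald intervals collapse).
* Bootstrap draws restore the RNG state afterwards, so adding a
  bootstrap to a pipeline does not shift later draws; identical
  (inputs, config, seed) produce byte-identical report CSVs, written at
  6 significant digits.
* Duplicate records for one (item, model, prompt variant) are kept on
  read — re-runs must not silently overwrite — and grading uses the
  first in file order.

## Problem sizes

The bundled tests exercise the pipeline at the scales the methods are
meant for while staying quick: oracle equivalence on a few hundred random
instances up to n = 500; binormal AUC recovery at n = 2500; DeLong
type-I error over 1000 null replicates of n = 500; calibration recovery
at n = 5000; bootstrap coverage over 200 simulated datasets. The
acceptance script reruns the study-scale analyses (n = 2500 and
n = 5000) end to end from a single seed.

## Limitations

Only single-letter answers are supported — free-text answers spread the
decision over many tokens and need aggregation methods out of scope
here. No recalibration (temperature scaling) is fitted; the package
measures calibration, it does not repair it. P-values are two-sided at
5% with no multiplicity correction, matching common practice in this
literature; treat the threshold-block comparisons as descriptive. The
adaptive-binning variant (equal-mass, no tie merging, larger bins first)
is one documented choice among several in use; ACE values are comparable
only under the same binning scheme and bin count.
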