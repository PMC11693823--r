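---
title: "Modeling cognate facilitation in bilingual vocabulary acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cognate facilitation in bilingual vocabulary acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bivocab implements an analysis pipeline for a recurring question in early
bilingualism: do *cognates* — translation equivalents that sound alike, such
as Catalan /ˈgat/ and Spanish /ˈga.to/ — enter a child's lexicon earlier than
non-cognates like /ˈgos/–/ˈpe.ro/, and is that advantage concentrated in the
language the child hears less? This vignette explains the model and the
design choices behind each stage; the README shows the code in action.

## Cognateness as normalized phonological distance

Each checklist item carries a broad X-SAMPA transcription. `tokenize_xsampa()`
splits transcriptions into phoneme tokens by maximal munch against an
editable inventory; stress marks (`"`, `%`) and syllable dots are
suprasegmental and are stripped first. Two choices here were genuinely open:

* **Tokens, not characters.** X-SAMPA writes some single phonemes with two
  characters (`tS`, `dZ`). Character-level edit distance would count an
  affricate substitution as two edits and inflate form lengths, so both the
  Levenshtein distance and the *Length* predictor operate on phoneme tokens.
* **Suprasegmentals excluded.** Word length is defined as the number of
  phonemes, and stress or syllable marks are not segmental insertions, so
  they never reach the distance computation.

Cognateness of a pair is `1 - d / max(len)`, where `d` is the unit-cost edit
distance between the token sequences: 0 for fully dissimilar pairs
(/ˈtaw.lə/–/ˈme.sa/), 1 for identical ones (/ˈmar/–/ˈmar/), 0.75 for
/ˈgat/–/ˈga.to/ (one insertion over four segments).

## Predictors

* **Frequency.** Counts from child-directed speech are mapped onto both
  members of a pair through a shared English lemma (both name the same
  concept), then put on the Zipf scale,
  `log10((count + 1) / (corpus tokens / 1e6)) + 3`, i.e. log-10 occurrences
  per billion words. The add-one smoothing keeps unattested forms finite;
  the per-billion convention is the standard psycholinguistic scale. Items
  without a mapped lemma are flagged and later dropped by the filter
  cascade.
* **Exposure.** Caregivers report cumulative exposure proportions per
  language; a response to a Catalan form takes the child's Catalan
  proportion, a Spanish form the Spanish proportion (65% Catalan implies
  0.35 for Spanish forms). Exposure is attached per administration, since
  it is reported at each questionnaire completion.
* **Standardization.** All five predictors are z-scored at the observation
  level, pooled across languages, after all filtering, using the sample
  (n−1) SD. Interaction regressors are products of the standardized main
  effects and are not re-standardized. The (mean, SD) pairs are kept on
  the fitted object so effects can be mapped back to raw units (per month,
  per phoneme, per 10% of exposure).

## Data processing

`filter_items()` applies the exclusion cascade in a fixed order — non-nouns,
missing frequency, multi-lemma items, multi-word items, untranslated items —
counting each item at its first failing stage, so the per-stage counts plus
the retained count always reconstruct the input count, and re-filtering is a
no-op. `exclude_participants()` drops children with *more than* 10%
third-language exposure; exactly 10% is retained, reading "more than"
literally. `encode_responses()` maps the three caregiver options onto the
ordered scale 0 = No (the questionnaire default) < 1 = Understands < 2 =
Understands-and-Says.

## The ordinal item-response model

Responses are modeled with a cumulative-logit (proportional-odds) model on a
latent acquisition scale. With linear predictor $\eta$ and ordered
thresholds $\tau_1 < \tau_2$:

$$P(\text{No}) = \mathrm{logit}^{-1}(\tau_1 - \eta), \quad
P(\text{U\&S}) = 1 - \mathrm{logit}^{-1}(\tau_2 - \eta),$$

with the middle category as the difference. $\tau_1$ is the comprehension
boundary and $\tau_2$ the production boundary, so one fit yields both
acquisition curves. $\eta$ contains the five standardized predictors plus
the two- and three-way interactions of age, exposure and cognateness;
participants contribute correlated random intercepts and slopes for age,
exposure, cognateness and their interactions, and translation equivalents
for age, exposure and their interaction (the maximal structure for this
design). The logit link is the conventional choice for cumulative models in
this literature.

Priors are weakly informative: N(−0.25, 0.50) on each threshold (location,
SD), N(0, 1) on slopes, positive-truncated N(1, 0.25) on random-effect SDs,
and LKJ(2) on each correlation matrix. Threshold order is enforced by an
ordered transform ($\tau_2 = \tau_1 + e^{\delta}$) rather than rejection.

### Sampling

The package carries its own implementation of the No-U-Turn sampler over an
analytically differentiated log posterior (C++): non-centered random
effects, tanh stick-breaking Cholesky parameterization of the correlation
matrices, dual-averaging step-size adaptation (target acceptance 0.8) and
windowed diagonal mass-matrix adaptation during warmup. All randomness runs
through R's RNG, so a seed fixes the draws exactly. The default settings
are four chains of 1000 warmup plus 1000 sampling iterations. Gradients are
verified against finite differences in the test suite, and the likelihood
against an independent R-side evaluation of the category probabilities.
Convergence policy (package policy, not a statistical law): warn at
split-Rhat > 1.01 or bulk ESS < 400, computed with rank-normalized split
chains and Geyer-truncated autocorrelations. Degenerate groupings (a single
participant or item) drop the corresponding random-effect block with a
warning instead of failing.

## Inference the study's way

Posterior slopes are summarized with 95% highest-density intervals
(exhaustive minimal-window search over the sorted draws; if a sample looks
multimodal the shortest single interval is returned with a warning).
Slopes are mapped to the probability scale with the divide-by-4 rule (the
logistic's maximum slope), and compared against a region of practical
equivalence of ±0.025 on that scale. Two choices deserve note:

* The ROPE is defined on the probability scale while coefficients live on
  the logit scale, so draws are transformed *before* the comparison.
* p(ROPE) is computed on the draws inside their own 95% HDI — the literal
  reading of "the proportion of posterior samples in the 95% HDI that fell
  into the ROPE". `p_rope(within_hdi = FALSE)` gives the full-posterior
  variant.

`marginal_effects()` produces population-level curves (random effects at
zero): $P(\text{response} \ge 1)$ and $P(\ge 2)$ over a raw-unit grid,
converted with the stored standardization metadata; grid points outside the
observed predictor range are flagged as extrapolation.

## Synthetic data: what it emulates and what it does not

`simulate_glmm()` draws directly from the ordinal model — correlated random
effects, the same design matrices, responses from the category pmf — and is
the basis of parameter-recovery checks. Default conditions mirror the study
design: ages uniform on 12–32 months, Catalan exposure uniform on
\[0.1, 0.9\], cognateness uniform on \[0, 1\], Zipf scores N(4.5, 0.7),
form lengths 2–9 phonemes, and logit-scale fixed effects set to four times
the probability-scale medians reported for this design (e.g. age 1.636,
exposure 0.928, exposure × cognateness −0.232). Thresholds default to
(−0.4, 0.6), plausible comprehension/production baselines for a
22-month-old at average predictors. Random-effect SDs (participant
intercept 1.2 down to 0.3 for high-order interaction slopes; item intercept
0.8) were chosen once as realistic for checklist data.

`simulate_accumulator()` formalizes the theoretical account the statistical
model is meant to detect. A word accrues *learning instances* — exposure
events contributing information toward acquisition — at rate

$$A_{ij}(t) = a_i \, r \, t \,\bigl(E_{L(j)}\,\omega_j +
\gamma\, s_j\, E_{L(j')}\,\omega_{j'}\bigr),$$

where $a_i$ is a log-normal child ability, $r$ the accrual rate
(instances/month at reference frequency), $E$ exposure proportions,
$\omega$ a Zipf-derived token weight ($10^{\mathrm{zipf}-6}$, normalized so
the median item weighs 1 — a mean normalization would let the few
highest-frequency items define the scale), $s_j$ the pair's cognateness and
$\gamma$ the co-activation
efficiency. Comprehension and production are reported once $A$ crosses
thresholds $\theta_c < \theta_p$ (defaults 90 and 130, with $r = 10$,
placing typical comprehension around 18 months and production in the mid
20s at balanced exposure), and reports are flipped to an adjacent category
with probability 0.05. The linear-in-time accrual and the
similarity-proportional, exposure-frequency-driven co-activation are this
package's explicit formalization — the underlying verbal account does not
fix equations, and deliberately leaves open whether instances are discrete
or continuous. Strength asymmetries beyond exposure frequency are
deliberately excluded, as is any estimation of accumulator parameters from
data (it is a generator, not an estimator). Because
$\partial^2 A / \partial E \,\partial s = -\gamma\,\partial(E\omega)/
\partial E \cdot \omega < 0$ under a two-language budget ($E' = 1 - E$),
data generated with $\gamma > 0$ should yield a negative
exposure-by-cognateness coefficient when fitted with the ordinal model —
the signature the study reports — and $\gamma = 0$ should not.

Passing these checks shows the pipeline is consistent with its own
generative assumptions at moderate scale; it does not certify the real
data's sample sizes, questionnaire subset structure, response biases
(caregivers inferring one language from the other), or longitudinal
dependence beyond shared random effects.

## Problem sizes and numerical choices

Recovery checks run at 100 participants × 60 translation equivalents × both
forms (12,000 records) with the full four-chain, 1000+1000 sampler
settings; theory-direction checks run ten seeds at 60 × 30 with two chains
of 300+300, sizes chosen so a complete validation cycle runs comfortably on
one CPU. The syllabic-frequency control regression uses a Gaussian
likelihood on the \[0, 1\]-bounded cognateness response — adequate away from
the boundaries, where most mass lies, and the simplest faithful reading of
the analysis; its slopes are judged against a configurable ROPE (default
±0.05 in cognateness units per predictor SD). HDI computation requires at
least 20 draws; `standardize()` refuses constant predictors; exactly-tied
HDI windows resolve to the lowest interval. Syllabic frequency sums the
caller-supplied frequency values over token syllables (a repeated syllable
in a word counts each occurrence), with each containing word contributing
once to a syllable's table entry; which language's syllabification to use
is left to the caller, since the choice is not fixed by the design.

## Known limitations

* The Gaussian control model can in principle predict outside \[0, 1\].
* p(ROPE) conditioned on the HDI is discontinuous in the draws at the HDI
  boundary; the full-posterior variant is smoother and exposed.
* The accumulator is one formalization among several compatible with the
  verbal theory; its parameters are conventions, not estimates.
* Reported exposure is a coarse proxy for input quantity; the simulators
  treat it as exact.
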