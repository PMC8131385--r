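---
title: "Modelling bilingual lexical access, stroke damage, and treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bilingual lexical access, stroke damage, and treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilexr)
```

## The model

`bilexr` implements a neural-network patient model of the bilingual mental
lexicon for simulating word-retrieval impairment and treatment response in
bilingual aphasia. The model consists of three self-organizing maps (SOMs):
a shared semantic map, and one phonetic map per language (L1 = Spanish,
L2 = English in the bundled cohort). The maps are joined by six directed
associative link matrices — semantic to and from each phonetic map, and the
two phonetic maps to and from each other — trained by Hebbian co-activation.

Lexical access is simulated by presenting a word's binary semantic feature
vector to the semantic map, transferring the resulting activation through
the semantic-to-phonetic links, and reading out the most highly activated
phonetic unit: the word is named correctly iff that unit is labelled with
the same word. Naming accuracy on a word set is the proportion named this
way; a 60-word probe set scored as `round(60 * accuracy)` plays the role of
a 60-item picture-naming test. Semantic processing is probed with 52
triplet trials (a target plus two same-category options differing in one
defining feature shared with the target), simulated entirely on the
semantic map from the winner units' weight vectors.

The pipeline has four stages, each exposed as package functions:

1. **Prestroke training** (`schedule_from_profile`, `train_exposure`):
   exposure-proportion-scheduled paired-map training driven by the
   patient's L2 age of acquisition and lifetime exposure percentages.
2. **Lesion fitting** (`fit_poststroke`): unit deletion calibrated so the
   model reproduces the patient's semantic-association and naming scores,
   followed by continued exposure training to the age at testing.
3. **Treatment simulation** (`run_treatment`): session-wise retraining on a
   30-word baseline-matched treatment set under a six-parameter protocol.
4. **Parameter fitting** (`fit_treatment_params`, `leave_one_out`): an
   evolutionary algorithm that fits the six protocol parameters to observed
   probe trajectories, with leave-one-out cross-validation across patients.

## Training mechanics and their parameters

Each exposure presentation samples a word and a language from the current
epoch's proportions. The semantic map and the exposed language's phonetic
map are SOM-trained on the word (winner-take-most with a Gaussian
neighbourhood truncated at three sigma); the semantic/exposed links receive
a Hebbian update from the two winner-centred activation bumps; and the
activation the semantic map evokes in the *unexposed* phonetic map through
its links is used, after peak normalization, to train the
phonetic-phonetic links. Hebbian rows are renormalized to unit sum over
alive target units after every update, so each source unit carries a
conditional distribution over target units; this keeps cross-map transfer
scale-free and makes the "row sums to one" invariant checkable after any
operation, including lesioning (lesions zero the rows and columns of
deleted units and renormalize the survivors).

Parameters that matter, with the package defaults (all in
`bilex_config()`):

| parameter | default | meaning |
|---|---|---|
| `words_per_year` | 1000 | exposure presentations per simulated year |
| SOM rate | `0.02 + 0.28 exp(-age/5)` | learning-rate decay with age (years) |
| SOM sigma | `0.4 + (grid/3 - 0.4) exp(-age/4)` | neighbourhood decay (grid cells) |
| `hebb_rate` | 0.01 | associative-link rate during exposure |
| `act_sigma` | 0.5 | transfer-bump width (grid cells) |
| `poststroke_plasticity` | 0.25 | rate scale for poststroke-phase exposure |
| `sigma_treat` | 1 | fixed SOM neighbourhood during treatment sessions |

The decay time constants were chosen so that maps are converged by early
adulthood (the youngest stroke-onset age in the bundled cohort is 23) — a
developmental assumption, since human lexical-semantic knowledge is mature
well before that age. The Hebbian rate of 0.01 gives link rows an effective
memory of roughly a hundred co-activations; much larger values make rows
track only the last few words presented and collapse transfer onto "hub"
units. The transfer bump of half a grid cell keeps cross-map transfer
graded but nearly unit-specific; widths of a full cell or more mix adjacent
words' mappings appreciably and depress naming. These values were
calibrated on convergence diagnostics of a balanced bilingual model
(quantization error, winner distinctness, naming and translation ceilings),
not on any published target quantity.

`poststroke_plasticity` reflects the standard lesion-modelling assumption
that the damaged system relearns more slowly than the healthy developing
one. At full plasticity, a model lesioned to severe anomia relearns most of
its naming over a decade of simulated poststroke exposure, contradicting
the premise that the lesioned model should still match the patient's
scores at testing (up to 14 years post-onset in the cohort).

## Exposure schedules

The prestroke schedule is L1-only from birth to the L2 age of acquisition,
then a constant mixture whose proportion is solved in closed form so that
the time-weighted lifetime average equals the reported lifetime-exposure
percentages at the age of testing; a share that cannot be reached in the
time available is clamped to 1 with a warning. The poststroke epoch uses
the reported poststroke use percentages, both for the lesion-to-testing
interval and for the one simulated week of exposure between treatment
sessions.

## Lesions and impairment matching

Lesions delete units along with their associative connections. The default
is a circular lesion: the disc around the map centre whose enclosed
fraction of alive units best matches the requested extent (deterministic,
so damage searches need no averaging); diffuse random deletion is retained
for comparison. Fitting is sequential, as the diagnostic logic requires:
semantic damage is increased over a 41-point extent grid until the
simulated semantic-association score best matches the patient's, then each
phonetic map is damaged independently until naming matches in that
language. If the semantic lesion alone already pushes naming below the
naming target, the target is flagged unreachable and phonetic damage stays
at zero. The fit is performed at the age of stroke onset; the model is then
aged to the testing age under poststroke exposure and the achieved scores
are evaluated (not re-fitted) there, with both sets reported.

## The treatment protocol

A treatment course on a 30-word set (selected randomly under the constraint
that the model's treated-language baseline on the set matches a target
proportion) runs, per session: (1) semantic retraining on the treatment
words at `rate_step1`; (2) treated-language retrieval retraining — treated
phonetic map, semantic map, and the links between them — at `rate_step2`;
(3a) for words passing `cond_3a`, retraining of the semantic/untreated
links from the activation the treated phonetic map evokes in the untreated
map, at `rate_step3a`; (3b) for words passing `cond_3b`, retraining of the
phonetic/phonetic links from the activation the semantic map evokes in the
untreated map, at `rate_step3b`; then a naming probe of the set in both
languages. Conditions are evaluated at session start and select words named
in the treated language, words translatable between languages, or all
words. Between sessions the model trains for one simulated week
(`words_per_year / 52` presentations) at the poststroke use proportions.
Step 1 uses the whole word vector as the semantic input; feature-level
training would be an alternative reading of a semantic-feature protocol,
and the whole-word form was chosen because the synthetic feature inventory
carries no per-feature typing.

Two behavioural notes, both visible in the test suite. First, the
cross-language channel is consolidative rather than generative: the evoked
activation used in steps 3a/3b points wherever the current links point, so
unconditioned retraining ("all") can reinforce wrong associations and
depress the untreated language, while the gated conditions protect
surviving associations. Correspondingly, simulated cross-language
generalization is weak — a property the treated/untreated asymmetry of the
protocol makes expected rather than surprising. Second, with near-total
phonetic destruction the treatment curves are flat at any learning rate,
which is the model's account of patients with severe aphasia who show no
treatment response.

## Evolutionary parameter fitting

Candidate protocols C are scored against observed probe trajectories by the
mean-squared error across patients, sessions (including the session-0
baseline) and both languages, with each patient's sum divided by their
number of treatment sessions — the published normalization, kept verbatim
even though it divides `n+1` terms by `n`; `normalize_by = "n_points"`
selects the alternative. The optimizer is a generational EA: tournament
selection (k = 3), uniform crossover of the six genes, log-normal mutation
of the rates (sigma = 0.3) plus a 10% chance of resampling each rate from
its log-uniform prior, 10% random resets of the condition genes, elitism of
one, and a restart from a fresh random population — preserving the global
best — after 20 stagnant generations. The prior-resampling step matters:
pure log-scale mutation can never escape a rate gene that has collapsed
toward zero. Defaults are population 30 and 100 generations; the test suite
uses population 20 and 40 generations, which the parameter-recovery
experiment shows is sufficient at its problem size.

Because the per-session patient probe data exist only in published figures,
the EA and the cross-validation driver are exercised on synthetic ground
truth: probe series generated by the package itself under known parameters
(`simulate_probe_series`), which also provides the parameter-recovery
check. The recovery experiment uses three synthetic patients with
asymmetric damage (treated map extent 0.7, untreated 0.45); symmetric heavy
damage leaves the untreated trajectory flat and makes the condition genes
formally unidentifiable.

## What the synthetic lexicon does and does not emulate

The generator builds `n_words` words in `n_categories` semantic categories.
Each category owns four disjoint core features plus three shared "pool"
features; each word adds word-distinctive pool features, and half of the
later words in a category are taxonomic siblings — an existing word plus
exactly one extra feature. Sibling pairs are what make valid triplet items
constructible: the two options differ in a single defining feature that an
out-of-category target shares. Phonetic vectors are uniform in [0, 1]^d,
with a 20% cognate fraction whose L1/L2 forms are correlated.

This synthetic structure reproduces the *task logic* (category similarity,
single-feature distinctions, cross-language form overlap) but not the
statistics of real lexical norms: no word-frequency distribution, no
feature typing, no real phonology. Consequently the package's quantitative
results should be read as behaviour of the model class under controlled
conditions, not as predictions about particular words. One measurable
consequence: an untrained semantic map scores around 0.6 on the triplet
test rather than at the 0.5 coin level, because winner selection among
random units still weakly encodes vector similarity.

## Problem sizes

The reduced ("desk") scale used by the test suite and the acceptance
script is 120 words in 12 categories (100 semantic, 40 phonetic
dimensions), an 18x18 semantic map, 14x14 phonetic maps, and 1000
presentations per simulated year. Map sizes were chosen so that each
phonetic map holds more units than there are words — a structural
requirement of the winner-labelling naming rule, whose ceiling is capped by
the number of units that can carry distinct labels. At this scale a
balanced 40-year model names about 90% of the lexicon in each language,
translates about 90%, and scores about 96% on the 52-item triplet test;
the full 13-patient lesion-fitting cohort builds in about a minute. The
`"full"` configuration (638 words, 30x30/26x26 maps, 5000 presentations
per year) mirrors the published corpus size.

## Numerical choices and degenerate inputs

All competitions break ties by the lowest row-major unit index, making
every run bit-reproducible under a fixed seed; all randomness — including
inside the compiled kernels — flows through R's RNG via explicit seed
arguments, with child seeds derived deterministically per patient, repeat
and candidate. A destroyed phonetic map scores naming as incorrect rather
than erroring; a destroyed semantic map scores triplet items by a seeded
fair coin; winner search on a destroyed map is an explicit error only for
the low-level `find_winner`. Grid searches resolve ties toward the smaller
lesion extent. The circular-lesion radius is quantized to the distinct
grid distances from the centre, so the achievable extents on a small map
form a coarse ladder; extent grids finer than that ladder add nothing.

## Known limitations

Cross-language generalization is underestimated by construction (see
above). Lesions are geometric, not anatomical, and their placement is fixed
at the map centre by default. Treatment probes score the 30-word treatment
set, while the clinical protocol probed 10-17 treated items; proportions
keep the scales comparable but the granularities differ. The mixed-effects
analyses of treatment response are out of scope: the harness exports a tidy
long-format table (patient, session, language, observed, predicted) for
use with any standard statistics environment, and `session_regressions`
provides the simple per-session regression summary, honouring the
`exclude_untreated` patient flag for untreated-language rows.
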