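# bilexr

Neural-network patient models of bilingual lexical access, stroke damage,
and treatment response.

`bilexr` is for researchers in aphasia rehabilitation and computational
neuroscience who want to simulate, at the level of an individual bilingual
patient, (i) prestroke naming ability in each language given the person's
bilingual history, (ii) poststroke impairment via calibrated lesions, and
(iii) response to word-retrieval treatment in the treated and the untreated
language — including fitting the treatment model to observed naming probes
and predicting response for held-out patients.

## The model

The bilingual lexicon is modelled as three self-organizing maps (SOMs): a
shared semantic map *S* and phonetic maps *P₁*, *P₂* (one per language),
joined by six directed associative link matrices *W* trained by Hebbian
learning with row normalization:

    ΔW[u,v] = η · a_src[u] · a_tgt[v],   then   W[u,·] ← W[u,·] / Σ_alive W[u,·]

where *a* are Gaussian activation bumps centred on the winner units. A word
is named correctly in language ℓ iff the most highly activated alive unit of
*P*ℓ under transfer `a_P = Wᵀ a_S` carries that word's label. Training
presentations sample words and languages per an exposure schedule derived
from the patient's L2 age of acquisition and lifetime exposure percentages.

Stroke damage deletes map units together with their connections; lesion
extents are fitted sequentially (semantic first, against a 52-trial
semantic-association score; then each phonetic map, against 60-point naming
scores). Treatment is a six-parameter protocol (four learning rates, two
word-selection conditions) fitted to per-session naming-probe trajectories
by an evolutionary algorithm minimising

    err(C) = (1/|T|) Σ_i (1/nᵢ) Σ_{j=0..nᵢ} [(E_ij − Ê_ij)² + (S_ij − Ŝ_ij)²]

with leave-one-out cross-validation across patients. See the methods
vignette (`vignettes/bilex-methods.Rmd`) for assumptions, parameters and
limitations.

## Worked example: lesion-fit one patient

```r
library(bilexr)

cfg   <- bilex_config()                      # desk-scale configuration
lex   <- generate_lexicon(cfg$n_words, cfg$n_categories,
                          cfg$d_sem, cfg$d_phon, seed = 11)
items <- generate_papt_items(lex, 52, seed = 12)
probe <- with_seed(13, sort(sample(lex$id, 60)))

pats <- bilex_patients()                     # bundled 13-patient cohort
fit  <- fit_poststroke(pats[pats$patient_id == "P8", ],
                       lex, items, probe, cfg, seed = 14)
print(fit)
```

```
Lesion-fitted poststroke model for P8
  lesion extents (circular): sem=0.175 L1=0.975 L2=0.35
         papt bnt_L1 bnt_L2
target     45      4     31
achieved   44      2     31
residual   -1     -2      0
```

The model for patient P8 needed a small semantic lesion (17.5% of units) to
reproduce the semantic-association score of 45/52, heavy damage to the
Spanish (L1) phonetic map to bring naming down to the target 4/60, and
moderate damage to the English (L2) map for 31/60. `achieved` is evaluated
after the model is aged from stroke onset to the age at testing under the
patient's poststroke language-use proportions, so it can drift a point or
two from the at-onset fit. `coef(fit)` returns the extents,
`residuals(fit)` the achieved-minus-target scores, and `plot(fit)` draws
the three damage-search curves with their targets.

From there, `select_treatment_words()`, `run_treatment()`,
`fit_treatment_params()` and `leave_one_out()` simulate and fit treatment
response; `build_patient_cohort()` runs the lesion fit for all 13 patients
and regresses actual against simulated scores.

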