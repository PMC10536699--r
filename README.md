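# anchormi

Cross-group comparability of ordinal rating scales with anchoring vignettes.

When two language groups answer the same rating-scale items, apparent group
differences can be artifacts of *scale use*: respondents at the same true
level pick different categories ("response-category differential item
functioning", RC-DIF). Measurement-invariance analysis by multi-group
confirmatory factor analysis (MGCFA) detects the damage but cannot repair
it. Anchoring vignettes — short scenarios pinned to fixed levels of the
concept, rated by every respondent on the same scale — reveal each
respondent's personal category boundaries and make two repairs possible:

* **non-parametric**: rescale each self-report `y` against the respondent's
  vignette ratings `z1..zJ` into a relative score
  `C ∈ {1, …, 2J+1}` (odd = between anchors, even = tied with an anchor);
  tied or misordered anchors make `C` interval-valued `[Cs, Ce]`, and the
  analysis is run on the lowest and highest admissible ratings;
* **parametric**: fit the compound hierarchical ordered probit (CHOPIT),
  `Y* ~ N(Xβ + η, 1)` and `Z*_j ~ N(θ_j, σ_j²)` sharing respondent-specific
  thresholds `τ¹ = γ¹V`, `τᵏ = τᵏ⁻¹ + exp(γᵏV)`, and carry the predicted
  thresholds into the MGCFA as manifest covariates.

The package implements the full chain for a 7-indicator, 5-category health
system responsiveness instrument in two language groups: a synthetic survey
generator with injectable non-invariance, the rescaling operations with an
exact interval semantics, maximum-likelihood CHOPIT with Gauss–Hermite
quadrature, a multi-group ML CFA engine (configural/metric/scalar sequence,
χ²/CFI/RMSEA/adjusted-BIC decision rules, score-test modification indices,
covariate models, composite reliability), and five end-to-end workflows.
Survey data are not bundled: the generator is the first-class substitute, and
its defaults define the study condition every check runs under.

## Worked example

Simulate the study condition — two languages, identical latent structure,
a uniform scale-use shift for the Arabic group — and compare the unadjusted
invariance analysis with the vignette-rescaled one:

```r
library(anchormi)

spec <- hsr_study_spec()              # language-level RC-DIF, magnitude 0.5
dat  <- simulate_survey(spec, n_per_group = c(english = 183, arabic = 121),
                        seed = 1)
dat  <- apply_missingness(dat, spec$missing, seed = 2)

run_workflow(list(workflow = "initial", data = dat, seed = 1))
run_workflow(list(workflow = "rescaled_lowest", data = dat, seed = 1))
```

The unadjusted analysis rejects scalar invariance (the raw group gap of more
than one scale point is pure scale use):

```
      model   chisq(df) dchisq(ddf) p_delta RMSEA dRMSEA   CFI  dCFI    aBIC  decision
 configural  15.19 (28)                     0.000        1.000       3919.60 supported
     metric  24.98 (35)    9.79 (7)   0.201 0.000  0.000 1.000 0.000 3913.65 supported
     scalar 148.43 (42)  123.46 (7)   0.000 0.149  0.149 0.770 0.230 4022.38  rejected
```

Rescaling every self-report against the respondent's own anchor means
(bottom/middle/top vignette ratings) removes the artifact — all three levels
are retained on the lowest admissible ratings:

```
      model  chisq(df) dchisq(ddf) p_delta RMSEA dRMSEA   CFI   dCFI    aBIC  decision
 configural 47.11 (28)                     0.079        0.969        5383.06 supported
     metric 54.16 (35)    7.06 (7)   0.423 0.071 -0.008 0.969  0.000 5374.60 supported
     scalar 60.99 (42)    6.83 (7)   0.447 0.064 -0.006 0.970 -0.000 5365.92 supported
```

Both reports also print the shared diagnostics, e.g.

```
Vignette ordering accuracy: 69% overall (arabic 70%, english 68%)
Composite reliability (pooled): 0.90
```

meaning about 69% of respondent–indicator vignette triples were rated in
their intended order, and the seven indicators form a highly reliable single
factor. The individual steps are available directly: `rescale_one(3, c(3, 3))`
returns the interval `[2, 4]` (a self-report tied with two tied anchors can
rank 2, 3 or 4); `fit_chopit(dat, indicator = "comm")` estimates the
communication item's CHOPIT and `predict_thresholds()` returns each
respondent's four category boundaries.

## The analysis, step by step

The numbered drivers under `analysis/` replay the whole study and write
tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generate the two-language survey with RC-DIF and nonresponse |
| `02_rescale.R` | ordering-accuracy diagnostics, anchors, lowest/highest rescaling |
| `03_chopit.R` | per-indicator CHOPIT fits, threshold prediction and screening |
| `04_invariance.R` | the five invariance workflows, side by side |
| `05_calibration.R` | the initial-vs-rescaled contrast over 40 replicates |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

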