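---
title: "Anchoring-vignette adjustment and measurement invariance: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring-vignette adjustment and measurement invariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchormi)
```

## The problem

Self-reports on ordinal rating scales ("very bad" ... "very good") are only
comparable across groups — languages, cultures, survey translations — if
respondents in all groups use the response categories the same way. When they
do not, individuals at the same true level of the measured concept pick
different categories; this response-category differential item functioning
(RC-DIF) can masquerade as substantive group differences and causes
measurement-invariance analyses to reject comparability. Anchoring vignettes
attack the problem at its root: every respondent also rates short hypothetical
scenarios pinned to fixed levels of the concept, and those ratings reveal the
respondent's personal category boundaries.

`anchormi` implements the complete analysis chain around this idea for a
7-indicator, 5-category health system responsiveness (HSR) instrument
administered in two language groups:

1. a **synthetic survey generator** whose data-generating process contains all
   the moving parts the analyses assume (one-factor measurement structure,
   covariate-driven thresholds, response-consistent vignette ratings),
2. the **non-parametric adjustment**: rescaling each self-report against
   vignette anchors into a relative score,
3. the **parametric adjustment**: a compound hierarchical ordered probit
   (CHOPIT) whose predicted respondent-specific thresholds become manifest
   covariates,
4. a **multi-group CFA engine** with mean structure, the
   configural/metric/scalar invariance sequence, fit-change decision rules,
   and score-test modification indices,
5. the **five workflows** that tie these together on one dataset.

## The measurement model and the invariance sequence

The observed score of individual $i$ on indicator $s$ in group $j$ follows the
one-factor model
$$Y_{ij} = \tau_j + \Lambda_j \eta_{ij} + e_{ij},$$
identified by fixing the factor mean to 0 and variance to 1 in every group,
so that all loadings and intercepts are free and can be constrained.
Configural invariance requires only the same model shape; metric invariance
adds $\Lambda_j = \Lambda$; scalar invariance adds $\tau_j = \tau$. Each level
is fitted by minimising the multi-group normal-theory discrepancy
$$F=\sum_g \frac{n_g}{N}\Big(\log|\Sigma_g| + \mathrm{tr}(S_g\Sigma_g^{-1})
  - \log|S_g| - P + (m_g-\mu_g)'\Sigma_g^{-1}(m_g-\mu_g)\Big)$$
over the free parameters (analytic gradient, quasi-Newton iterations).

Conventions differ across SEM software, so the engine fixes and records its
own: $\chi^2 = (N-G)\,F_{\min}$; the CFI baseline is the per-group
independence model with free means and variances;
$\mathrm{RMSEA} = \sqrt{G}\sqrt{\max(\chi^2-df,0)/(df\,N)}$; the
sample-size-adjusted BIC penalises with $\log((N+2)/24)$. Decision rules
follow small-unequal-sample practice: the configural model is accepted when
$\mathrm{CFI}\ge 0.95$ and $\mathrm{RMSEA}\le 0.08$; a higher level is
rejected when the $\Delta\chi^2$ test is significant at $0.05$ **or**
$\Delta\mathrm{CFI}\ge 0.005$ **or** $\Delta\mathrm{RMSEA}\ge 0.010$ (each
rule can be disabled; a $\Delta$aBIC of 6 is reported alongside). When the
configural model fails, a modification-index-guided search may add
equal-across-group error covariances one at a time — largest index first,
only while it exceeds 3.84, capped at two additions — because ad-hoc
modifications beyond that degrade comparability and generalisability.

Estimation is plain maximum likelihood on the ordinal ratings treated as
continuous. Robust (sandwich-type) chi-square corrections are deliberately
not implemented; the calibration study below quantifies what plain ML costs
with 5-category data (a null rejection rate of roughly 0.07 at $\alpha=0.05$,
inside the 0.02–0.10 band we consider acceptable).

## Non-parametric rescaling

With anchors $z_1,\dots,z_J$ (intended order bottom to top), a self-report
$y$ maps to a $2J{+}1$-point relative scale: odd values are the gaps below,
between and above the anchors, even values are exact ties. When the anchors
are strictly ordered this is a single value; ties and misorderings make the
score ambiguous, and `rescale_one()` returns the full interval $[C_s, C_e]$
of attainable values under the semantics:

* an anchor involved in a **strict inversion** contributes no usable relation
  to $y$ (its rating contradicts vignette equivalence, so its position is
  treated as unknown);
* $y$ **tied** with a block of equal, consistently ordered anchors may sit
  anywhere from the block's lowest to its highest rank (with two vignettes
  and $y=z_1=z_2$ the admissible values are 2, 3 and 4).

These semantics reduce exactly to the piecewise rule for ordered anchors, are
monotone in $y$, invariant under joint strictly increasing transforms, and
are verified against a brute-force enumeration oracle over every rating
combination with $J\le3$. Equality is exact on integers and within $10^{-9}$
for real-valued (mean) anchors — which also means mean anchors essentially
never tie with integer self-reports, so pooled-anchor rescaling yields only
odd scores.

**Anchor choice.** Two modes exist. *Per-respondent anchors* (default for the
workflows) average each respondent's own ratings of the bottom, middle and
top vignettes across whatever indicators their assigned set covered; they
carry the respondent's personal scale use, which is exactly what the
adjustment must remove, and they produce the interval-valued scores (about a
quarter to a third of respondents misorder their anchors) that motivate the
separate lowest-rating ($C_s$) and highest-rating ($C_e$) analyses.
*Pooled anchors* (`pooled_anchor_means()`) average each indicator-level over
all respondents; they are a common monotone recode of the raw ratings —
useful as a reference but unable to correct respondent-level DIF, and they
make the lowest and highest analyses coincide. The default reflects that only
respondent-level anchors can do the scientific job the rescaling exists for.

## The CHOPIT model

The parametric route models self-reports and vignette ratings jointly. The
self component gives respondent $i$ a latent value
$Y^*_{i} \sim N(X_i\beta + \eta_i,\, 1)$ with a normal respondent effect
$\eta_i \sim N(0, \omega^2)$; the vignette component places vignette $j$ at
$Z^*_{j} \sim N(\theta_j, \sigma_j^2)$ with no respondent effect. Both are
discretised by the same respondent-specific thresholds
$$\tau^1_i = \gamma^1 V_i,\qquad \tau^k_i = \tau^{k-1}_i + e^{\gamma^k V_i},$$
which are ordered by construction for any covariates $V_i$ and are what link
the two components: vignette ratings identify how the respondent's covariates
move the thresholds, i.e. the RC-DIF. The likelihood integrates the random
effect by Gauss–Hermite quadrature (15 nodes by default; the log-likelihood
changes by under $10^{-4}$ per observation between 15 and 31 nodes, and with
one observation per respondent the integral also has the closed form
$\Phi\!\big((\tau-\mu)/\sqrt{1+\omega^2}\big)$, used as an internal
cross-check). Optimisation is quasi-Newton with an analytic gradient from a
deterministic start (marginal ordered-probit thresholds, zero slopes);
$\omega$ and $\sigma_j$ are log-parameterised so no iteration can leave the
admissible region.

**Identification.** The residual SD of the self component is fixed at 1 and
$X$ carries no intercept; location and scale are absorbed by the threshold
intercepts. One consequence deserves emphasis: in the per-indicator design
(a single self-report per respondent, free vignette SDs) a joint rescaling of
all thresholds, locations, SDs and effects trades *exactly* against
$\omega$ — the profile likelihood is flat along that ridge (empirically, a
near-zero Hessian eigenvalue at the optimum). `fit_chopit()` therefore fixes
$\omega=0$ by default; `omega = "free"` remains available for designs with
several self items sharing the effect. Without vignette data the mean effects
$\beta$ are likewise collinear with the first-boundary slopes and are pinned
at zero; adding `slopes = "proportional"` then makes the model an ordinary
ordered probit, which the test suite verifies coefficient-for-coefficient
against an independent implementation.

Each indicator is fitted separately, pooling vignette ratings from every set
that covered it. Education is excluded from the default covariates because
its nonresponse would shrink the estimation sample disproportionately. The
four predicted thresholds per indicator are exported for all
covariate-complete respondents and screened: a threshold enters the covariate
CFA only if it has a significant simple linear path ($p<0.05$, per group) to
at least one indicator; constant thresholds have no defined slope and are
never selected. Because every predicted threshold is an (almost) linear
function of the same handful of covariates, the screened set is typically
rank deficient; the workflow therefore keeps, in order of screening strength,
only thresholds that still add at least 1% independent variation given those
already kept, which is what keeps the covariate moment matrix invertible.
In the covariate model the selected thresholds are manifest
exogenous variables — correlated among themselves, uncorrelated with the
factor, regressed on the indicators — because positing a latent variable
behind them would presuppose the vignette equivalence the analysis is meant
to probe. Because a threshold's language component is constant within a
group, a purely between-group scale shift is absorbed by the group
intercepts, not by these covariates; the covariate route mainly controls
within-group DIF heterogeneity, which is one reason it can trail the
non-parametric route at the scalar level.

## The synthetic study condition

The generator's defaults are the package's statement of the conditions the
analyses address:

* **Groups and sizes.** English and Arabic, defaults 145/91 (the analysis
  sample sizes); the drivers simulate 183/121 and let item nonresponse
  (self-reports 4%, vignettes 5%, education 12%, insurance 6%) shrink them.
* **Measurement structure.** Seven indicators, loadings 0.70, unique SD
  $\sqrt{0.51}$, factor $N(0,1)$: unit latent residual variance per
  indicator, so the generator's self-report component *is* the CHOPIT
  measurement model with $\sigma_s=1$, and the composite reliability of the
  scale is about 0.87 with all loadings above 0.50.
* **Covariates.** Gender (23% female), five age bands
  (46/19/15/9/11%), three education levels, insurance card (40%); one-hot
  encoded with the first level as reference. Mild covariate effects on the
  thresholds (e.g. insured respondents place the top boundary higher) and on
  the factor mean give the screening and covariate models realistic signal.
* **Thresholds and vignettes.** Baseline boundaries $(-2.2,-1.4,-0.6,0.4)$
  reproduce the generous right-skewed category use typical of care ratings
  (mean about 4 on 1–5); vignette locations $(-1.6,-0.8,0,0.8,1.6)$ with unit
  rating SD give an ordering accuracy near 70%, matching what such surveys
  report. Five vignette sets are assigned with equal probability: set 1 =
  bottom/middle/top for all seven indicators; sets 2–5 = all five levels for
  attention+respect, communication+amenities, confidentiality+choice, and
  autonomy.
* **The DIF condition.** `hsr_study_spec()` shifts the intercept row of every
  indicator's threshold matrix by 0.5 for the Arabic group — a language-level
  difference in how the response labels are read, uniform across items
  because scale use is a property of the respondent, not the item. The latent
  distributions, loadings and intercepts are identical across groups, so any
  non-invariance the unadjusted analysis reports under this condition is pure
  artifact. The respondent random effect $\omega$ defaults to 0: a nonzero
  value adds a uniform residual covariance that the strict one-factor
  analysis model would count as misfit in both groups.

What the generator does **not** emulate: item-specific cross-cultural meaning
shifts (construct/item bias), clustered sampling of accommodation centres,
non-normal latent distributions, and respondent inattention beyond random
rating noise. Passing tests therefore show that the chain of methods recovers
comparability when the problem really is scale use; they cannot show that
real survey incomparability is of that kind.

## What the checks establish

* The rescaling operation is verified exhaustively against enumeration, and
  its worked tie case returns the interval $\{2,3,4\}$.
* The decision engine, applied to externally reported fit statistics of an
  unadjusted and a rescaled analysis, reproduces the published verdicts —
  the engine is deliberately separable from the fitting machinery.
* The CHOPIT likelihood agrees with brute-force Monte-Carlo integration
  ($10^6$ draws per respondent, agreement within 3 MC standard errors) and
  its maximum-likelihood estimates recover generating parameters at
  $n=2000$ (every parameter within 3 reported SEs; median absolute bias
  under 0.05 over 20 replicates).
* The CFA engine inverts model-implied population moments exactly
  ($\chi^2<10^{-6}$, parameter error $<10^{-5}$) at every constraint level
  whose restrictions are true, and its constrained minima match an
  independently coded discrepancy minimiser.
* Under a homogeneous scalar-invariant population the $\Delta\chi^2$ tests
  reject at 0.07 at the metric and scalar levels ($n=200$ per group, 200
  replicates) — the plain-ML inflation on 5-category data stays inside
  0.02–0.10. A loading shift of 0.4 on one indicator at the study's sample
  sizes (145/91) is detected by the metric-level rules in 80% of 200
  replicates; this sits exactly at the conventional power benchmark, which is
  worth knowing before planning a study of this size.
* Modification indices track the refit $\Delta\chi^2$ within 15% and rank a
  truly omitted error covariance first in over 90% of replicates, while a
  truly-zero candidate stays below 3.84 in over 90%.
* End to end, the unadjusted workflow rejects an invariance level in
  essentially every replicate of the DIF condition, while the lowest-rating
  rescaled workflow retains configural and metric invariance in a clear
  majority — the package-level restatement of the claim that vignette
  adjustment, not socio-demographic adjustment, restores comparability.

Problem sizes are chosen to make these studies precise but quick: recovery at
$n=2000$ with 20 replicates, calibration and power at 200 replicates each,
modification-index studies at $n=300$ per group with 100 replicates, and the
pipeline contrast at 100 replicates of the 304-respondent survey.

## Numerical choices and edge behaviour

* Moment matrices use divisor $n$; groups need at least $P+1$
  listwise-complete rows, and zero-variance columns are an error.
* The discrepancy is evaluated via Cholesky factorisation; a non-positive-
  definite $\Sigma(\vartheta)$ (or one within $10^{-6}$ of singular) returns
  a flat penalty plateau, which keeps the optimizer inside the admissible
  region without constraining residual variances — Heywood cases are
  estimated as they are and flagged, never silently truncated.
* Degenerate reference distributions: $df=0$ models report RMSEA 0 with a
  flag; a zero baseline span yields CFI 1; numerically negative $\Delta\chi^2$
  (possible without robust scaling) is floored at 0, with a warning only when
  the negativity exceeds rounding error.
* Standard errors come from the numerically differentiated observed
  information (central differences of the analytic gradient); modification
  indices use the Schur complement of the candidate in that information, so
  equality-constrained parameters can be probed per group without refitting.
* All random draws flow from a single integer seed per dataset, recorded in
  the output; identical configuration and seed reproduce reports exactly.

## Limitations

Ordered-categorical (polychoric/WLSMV) estimation, robust ML corrections,
multilevel CFA, survey weights, alignment and Bayesian approximate invariance
are out of scope. The covariate model assumes covariates are uncorrelated
with the factor. The interval-valued rescaled scores are collapsed to their
lower or upper bound before the CFA rather than treated as censored
observations — the two bounds bracket, but do not exhaust, what interval
methods could extract.
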