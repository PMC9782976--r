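---
title: "Expert-knowledge-guided Bayesian networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expert-knowledge-guided Bayesian networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ekbn` models an imbalanced binary clinical outcome (an event affecting a
quarter, or a twentieth, of roughly a hundred analysis units) with discrete
Bayesian networks, and asks whether physician-designated expert-knowledge
features (EKFs), injected through a structured human-in-the-loop procedure,
yield better-discriminating and more credible models than a pure
data-driven (PD) baseline.  This vignette is the package's own account of
the statistical machinery, the tunable parameters, the numerical choices,
and what the synthetic validation does and does not establish.

## The model

All modelling happens on categorical data.  A Bayesian network over the
outcome and a feature subset factorizes the joint as
$P(x_1,\dots,x_m) = \prod_i P(x_i \mid \mathrm{pa}(x_i))$; prediction is
the exact posterior $P(\text{outcome} = \text{event} \mid \text{evidence})$
by variable elimination.  Conditional probability tables are estimated with
a symmetric Dirichlet (BDeu) prior of equivalent sample size `ess` (default
1: each CPT cell receives prior weight $\mathrm{ess}/(rq)$), so no
posterior is ever exactly 0 or 1 at the cohort sizes we target.

### Feature selection: Markov blankets

The outcome's Markov blanket — parents, children, spouses — is the minimal
set rendering it independent of everything else, and is found with
Inter-IAMB: grow by adding the candidate with the smallest G² p-value
against the target given the current blanket (if below `alpha`, default
0.05), shrink after every addition by removing members that have become
conditionally independent.  Two small-sample safeguards matter at n ≈ 100:

* tests whose average contingency-cell count falls below 5 are flagged
  ineffective and treated as non-rejections (they cannot reliably reject);
* no multiple-testing correction is applied inside the search, matching
  the classical algorithm; the audit trail records every decision so the
  selection is reviewable.

### Structure learning

Score-based search over DAGs: tabu search (add/delete/reverse moves, tabu
list of the last `tabu_len = 10` structures, up to `tabu_len` non-improving
moves allowed, in-degree capped at `max_parents = 4`) on the decomposable
BIC score.  Reported networks are model averages: `R` nonparametric
bootstrap resamples are each searched, an arc is kept when its bootstrap
frequency reaches `threshold = 0.5`, and the kept arc takes its majority
orientation.  Averaging can assemble a directed cycle out of individually
acyclic networks; cycles are broken by removing the weakest arc per cycle
(logged), so the averaged graph is always a DAG.

### The human-in-the-loop pipeline

K tree-ensemble learners (default random forest and gradient boosting)
are cross-validated and each yields a ranking of all J features by
out-of-fold permutation importance (20 shuffles per feature; this metric
is seed-deterministic and learner-agnostic, unlike internal impurity
importances).  The lists are fused by the weighted ranking score
$\mathrm{WRS}_j = \sum_k N_j(L^k)\,\frac{\sum_{k'}\mathrm{AUC}^{k'}}{\mathrm{AUC}^k}$,
ascending.  The typeset grouping of this aggregation rule is ambiguous —
read literally it gives *lower*-AUC models the larger multiplier — so the
package implements the literal rule as the default (`weighting =
"inverse"`) and the intuitive alternative $w_k = \mathrm{AUC}^k / \sum
\mathrm{AUC}$ as `"proportional"`, exposing rather than hiding the
ambiguity.  With equal per-model AUCs both reduce to a Borda count, so the
choice only matters when the learners' performances separate.

The initial model takes the top $n = 100\,D/N$ percent of the integrated
list — exactly $D$ features.  $D$ defaults to
$\min(10, \lfloor n_\text{units}/10 \rfloor)$: conditional-independence
tests on ~100 units cannot faithfully support more than about ten
candidate dimensions.  EKFs inside the window are filtered through the
outcome's blanket over the window; non-EKFs through each kept EKF's
blanket over the window's non-EKFs (window-restricted by default,
`mb_window = "full"` searches the whole list).  Each subsequent step
proposes the next EKF in list order together with the non-EKFs ranked
between it and the previous EKF that appear in a selected EKF's blanket
(computed over data restricted to that between-set plus the anchor EKF),
relearns the structure, prunes, and accepts only if the cross-validated
AUC improves by more than `epsilon = 0.001` *on the same fold splits as
the incumbent* — pairing removes most of the split noise from the
comparison.  The run stops at list exhaustion, at `target_auc`, or after
`patience` consecutive rejections.  An optional `ask` callback lets a
human veto steps before they are evaluated; batch runs never block.

### Evaluation

Discrimination is repeated stratified k-fold cross-validation (default
5 × 2 here; with ~23 events unstratified folds go degenerate and
leave-one-out is noisy), pooling out-of-fold scores within each repeat and
averaging the pooled AUC over repeats.  The whole pipeline under
evaluation — blanket search and structure learning — is refit inside every
training fold, so no selection information touches the held-out fold.
Models that degenerate to an empty network score a *fixed* constant (all
ties, AUC exactly 0.5) rather than the training-fold prevalence: pooling
fold-specific constants anti-correlates with the test fold's event density
and would bias the pooled AUC below 0.5.  Confidence intervals are
percentile intervals from 2000 stratified bootstrap resamples (a
DeLong-variance interval is available; which one the clinical literature
used is usually unstated, so both are labelled).  Paired model comparisons
use DeLong's test on placement-value covariances.  The final
model-vs-model claim is made on a held-out sample scored once, after the
trace is frozen.

## The synthetic generator

`scenario_spec()` defines a ground-truth network around the outcome: 2+
parents, one child, one spouse (all three blanket roles are always
present), `n_redundant` shadow features (noisy copies of blanket members:
marginally associated with the outcome, conditionally independent of it
given their source — classic redundancy), and independent noise.  All
features are binary at generation time so the designed blanket is exactly
faithful; a Gaussian-emission wrapper (`continuous_emission()`) produces
continuous columns to exercise the discretizer.  The outcome CPT is
$\mathrm{clamp}(b + \text{effect}\cdot s)$ with $s \in [-1,1]$ the scaled
parent sum, the intercept $b$ solved by `uniroot` so the *analytic*
marginal event probability equals the requested prevalence to ~1e-12
(infeasible prevalence/effect pairs raise an error with the attainable
range).  `effect = 0.3` by default: a single parent shifts the event
probability by about 0.3, making recovery achievable but not trivial at
desk scale.  The presets mirror the clinical study conditions —
`ialbi_like`: 81 units, prevalence 23/81, 69 features (45 pre-treatment,
24 during, named with the `D_` prefix), 12 EKFs; `lc_like`: 104 units,
prevalence 4/104, 93 features, 13 EKFs.  A third of the flagged EKFs are
deliberately non-informative decoys (half redundant shadows, half pure
noise), modelling imperfect expert knowledge.

What the generator does **not** emulate: within-patient correlation of
multiple tumors (units are independent, as the clinical analysis itself
assumed), longitudinal lab trajectories, realistic dosimetric physics, or
measurement missingness beyond what the discretizer's mode imputation
handles.  Passing tests therefore show the machinery is correct and the
procedure behaves as designed under faithful discrete truth — not that it
will attain any particular AUC on real cohorts.

## Numerical and design choices

* **Discretization**: 3 quantile bins per continuous feature (2 below 5
  distinct values) — cohorts of ~100 units cannot populate finer CPTs.
  Collapsed quantiles fall back to fewer bins with a warning; single-bin
  columns are dropped; missing cells are mode-imputed after binning.
  Whether the original analysis discretized or used Gaussian tests is not
  recorded anywhere; bins and method are therefore configuration, not
  assumptions.
* **Event coding**: the minority class is always the internal event `"1"`;
  the original label mapping is kept on the cohort object.
* **Tie-breaks** are lexical by feature name everywhere (ranking, blanket
  candidate choice, tabu moves, arc orientation at an exact 0.5 split), so
  identical inputs reproduce identical models across platforms.
* **Seeds**: one master seed fans out per stage via a documented string
  hash (`derive_seed`), so any stage can be replayed in isolation; a run's
  config echo replays the whole trace bit-for-bit.
* **Fold-internal structure learning** uses a single tabu search
  (`sl_config(r_cv = 1)`) instead of full bootstrap averaging: fold models
  are throwaway evaluations of a candidate feature set, and averaging
  inside every fold would multiply cost ~50× for a second-order change in
  the AUC estimate.  The final reported network always uses the full
  `R`-replicate average (default `R = 200`).
* **Backward elimination** (drop features disconnected from the outcome in
  the learned graph, then greedily remove features whose deletion improves
  or preserves the CV AUC within ε) is applied to the whole selected set
  in the initial model, but only to a step's newly added candidates in the
  incremental steps — the incumbent set was already pruned when it was
  accepted.
* **Acceptance thresholds**: ε = 0.001 on the paired repeated-CV AUC; the
  original procedure says only that the model "cannot be improved", so the
  strictness is configurable and a DeLong-gated acceptance can be emulated
  by comparing evaluations explicitly.
* **Oracle-equivalence testing** of the blanket search against the
  exhaustive-subset oracle is run at α = 0.01 on n = 5000 samples: power
  is essentially 1 there, and the stricter level suppresses the per-test
  false rejections that would otherwise make two correct procedures
  disagree by chance.  Recovery-quality checks (F1, null behavior) use the
  operational α = 0.05.
* **Problem sizes in the test suite** were chosen so each property is
  measured where it should hold: exactness checks at tiny n, calibration
  at 500–1000 simulations, recovery at n = 5000, and the end-to-end
  pipeline comparison at the preset's own 81 units over 20 replicate
  seeds with an independent 400-unit held-out sample per replicate (large
  held-out samples stabilize the *measurement* of AUC without changing
  the training conditions).

## Known limitations

* At the preset cohort size (81 units, effect 0.3) even the generating
  model's oracle AUC is only ≈ 0.72–0.80, and the G² tests sit at the edge
  of their power; exact blanket recovery by *any* procedure is unreliable
  at that n, which is precisely the regime the human-in-the-loop guidance
  targets.  Comparisons between the pipelines are meaningful; absolute
  recovery rates at n = 81 are not a property of the implementation.
* Only discrete (multinomial) networks are supported; continuous features
  must pass through the discretizer.  Gaussian conditional-independence
  tests and hybrid networks are future work.
* The blanket search implements the Inter-IAMB family; HITON/MMMB-style
  algorithms are out of scope.
* XOR-type parity mechanisms are unfaithful to any DAG and are neither
  generated by the synthetic module nor recoverable by score-based search;
  the test fixtures avoid them deliberately.
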