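---
title: "Estimating and comparing anxiety–sleep symptom networks from ordinal questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing anxiety–sleep symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` analyses comorbidity at the symptom level. Each of the fourteen
items — seven GAD-7 anxiety items and seven PSQI sleep components, all scored
0–3 — is a node; an edge is the *partial correlation* between two symptoms,
their association conditional on every other symptom in the set. The
collection of edges is a Gaussian graphical model (GGM): if $\Theta =
\Sigma^{-1}$ is the precision matrix of the (latent) item vector, the edge
weight between items $i$ and $j$ is

$$w_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}.$$

Because $\binom{14}{2} = 91$ free edges would overfit, the precision matrix is
estimated by the **graphical lasso**: maximize
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \neq j} |\Theta_{ij}|$
over positive-definite $\Theta$, where $S$ is the item correlation matrix. The
L1 penalty sets small edges to exactly zero. The penalty is not applied to the
diagonal, so at $\lambda = 0$ the estimate is exactly $S^{-1}$ — a limit the
test suite checks against direct matrix inversion, and on three nodes the
penalized optimum is checked against a generic numerical maximizer.

The penalty $\lambda$ is chosen by the **Extended Bayesian Information
Criterion**,

$$\mathrm{EBIC}_\gamma = -2L + E \log n + 4 \gamma E \log p,$$

with $L$ the Gaussian log-likelihood, $E$ the number of nonzero edges, and
$\gamma = 0.5$ the conventional sparsity hyperparameter ($\gamma = 0$ recovers
the BIC). The solver fits a log-spaced path of 100 penalties from
$\lambda_{\max} = \max_{i<j}|S_{ij}|$ down to $0.01\,\lambda_{\max}$ with warm
starts and keeps the EBIC minimizer; exact ties resolve to the sparser model.

### Correlation input for ordinal items

Four-category items are not Gaussian, so the default input is the
**polychoric** correlation: each pair of items is modelled as a discretized
bivariate normal, thresholds are estimated from the marginal category
frequencies, and the latent correlation maximizes the contingency-table
likelihood (a two-step pairwise estimator). The bivariate normal rectangle
probabilities use a Gauss–Legendre quadrature of the tetrachoric integral
(accuracy near 1e-14, tested against an independent integrator). Pearson and
Spearman input are available; Pearson on 0–3 scores attenuates latent
associations by roughly 10–20%, which is why the polychoric default matters
for recovering generator ground truth.

Pairwise-complete observations are the default missing-data policy; an item
with more than 50% missing values or no variance is rejected with an error
naming the item. An indefinite pairwise matrix is repaired by eigenvalue
clipping (singular-but-PSD matrices are left alone).

## Centrality and predictability

* **Expected influence (EI)** of a node is the signed sum of its edge weights
  — the criterion for *central symptoms*. A two-step variant is available but
  the one-step definition is the default.
* **Bridge expected influence (bEI)** is the same sum restricted to edges that
  cross the anxiety/sleep community boundary — the criterion for *bridge
  symptoms*. By construction `bEI + within-community EI = EI` for every node,
  which the tests assert to machine precision. (Verbal definitions of bEI in
  the applied literature sometimes describe the unrestricted sum; the
  cross-community definition is the one that identifies bridges, and is what
  the bridge-symptom figures in outpatient studies require.)
* **Betweenness and closeness** use edge lengths $1/|w|$; closeness defaults
  to the harmonic form so disconnected nodes have a defined value. Both are
  verified against an exhaustive shortest-path enumeration on all small
  fixtures.
* **Predictability** of a node is the $R^2$ of an ordinary least-squares
  regression of the node on its network neighbours, a Gaussian nodewise
  approximation in which items are treated as numeric. It approximates the
  mixed-graphical-model predictability used in the applied literature;
  discretization makes it conservative (the tests compare against the
  analytic latent-scale $R^2$ from the true precision matrix).

## Stability diagnostics

Edge accuracy uses the nonparametric bootstrap: respondents are resampled
with replacement, the full EBIC-glasso pipeline is re-run, and each edge gets
a 95% quantile interval. Pairwise difference tests (between edges, or between
nodes' EI) ask whether the bootstrap interval of the difference excludes
zero, at two-sided $\alpha = 0.05$ without multiplicity correction — the
convention of the bootstrapped-difference plots in this literature.

Centrality stability uses the case-dropping bootstrap: at each drop
proportion in $\{0.10, 0.25, 0.50, 0.75\}$, subsamples are drawn without
replacement and the subsample centrality is correlated with the full-sample
centrality. The **CS-coefficient** is the largest drop proportion at which at
least 95% of subsamples correlate $\geq 0.7$ — read off the grid, so 0.75 (the
grid ceiling) is the best attainable value, and a coefficient of 0 means even
10% dropping destabilizes the ranking. A failed low level breaks the run:
levels above it cannot rescue the coefficient. Undefined subsample
centralities (e.g. an empty network on noise data) are recorded as
correlation 0 rather than being skipped, so noise data are driven to CS = 0.

## Group comparison

The **network comparison test (NCT)** is a permutation test. Both groups'
networks are estimated with identical settings; the observed statistics are
the maximum absolute edge difference $M$ (structure invariance) and the
absolute difference in global strength $S = \bigl|\sum|w^A| -
\sum|w^B|\bigr|$ (strength invariance). Group labels are then shuffled over
the pooled respondents, preserving group sizes, and both networks are
re-estimated per permutation (1,000 by default). The global p-values use the
add-one convention $(1 + \#\{T^{perm} \geq T^{obs}\})/(1 + n_{perm})$, so they
are valid at finite permutation counts and never exactly zero. Each node pair
is also tested against its own permutation distribution, with Holm–Bonferroni
correction over all 91 pairs by default (`edge_family = "observed"` restricts
the family to pairs present in either observed network). The per-edge
p-values are the plain permutation proportion rather than the add-one form:
Holm multiplies the smallest p by the family size, so an add-one floor of
$1/(n_{perm}+1)$ would put the smallest achievable adjusted value at
$91/(n_{perm}+1)$ and the edge tests could never reject at practical
permutation counts. A strong difference can therefore reach an adjusted p of
exactly 0, as in the reference implementation of this test.

Two practical choices: the permutation loop defaults to Pearson input — it
runs in compiled code and the roughly 2,000 re-estimations per test make the
pairwise polychoric likelihood disproportionately costly there, while the
comparison of two groups estimated *the same way* is unaffected by the
uniform attenuation — and group splits require an explicit category-to-arm
mapping (`group_split_arms()`) rather than guessing how published analyses
collapsed their categories, since reported group sizes are not always
reconstructible from the demographic table.

## The synthetic cohort generator

No public outpatient dataset accompanies this class of analyses, so the
package ships a generator that gives every stage a known ground truth. It is
a latent-Gaussian copula: a sparse positive-dominant partial-correlation
matrix over the two communities is converted to its implied latent
correlation matrix, multivariate-normal vectors are drawn, and each
coordinate is discretized at three thresholds into 0–3.

Defaults emulate a large outpatient sleep-clinic cohort:

* **Structure** — within-community chains plus extra edges at density 0.3
  with weights 0.05–0.35, anchored by the strongest associations reported for
  such cohorts (sleep duration–efficiency 0.60; nervousness–uncontrollable
  worry 0.45; sleep quality–latency 0.45) and four cross-community bridge
  edges led by nervousness–daytime dysfunction at 0.16, including one weak
  negative edge (irritability–medication use at −0.07). Edge weights that
  break positive definiteness are shrunk uniformly by 0.95 per iteration (at
  most 50) and the shrink factor is recorded.
* **Marginals** — thresholds are normal quantiles of Binomial(3, m/3)
  category probabilities with target means matching published item
  descriptives (right-skewed anxiety items, means 0.6–1.35; left-skewed sleep
  components, means 1.1–2.1), so simulated items have realistic skew without
  claiming to copy any real dataset's joint distribution.
* **Covariates** — optional demographic columns with outpatient-like
  frequencies, independent of the items by default (the correct null for
  covariate-adjustment tests).
* **Seeding** — one seed per call; two-group sampling derives one substream
  per group so groups are independent yet jointly reproducible.

What passing tests on these data do *not* show: robustness to
informatively-missing responses, to violations of the latent-normal
assumption (e.g. zero-inflated items), or to real covariate–symptom
confounding. The generator's covariate independence makes the
adjusted-vs-unadjusted comparison a null check, not a demonstration of
deconfounding.

## Numerical choices and conventions

* Solver: block coordinate descent over the working covariance; convergence
  when the largest change in a sweep falls below `tol` (1e-4) times the mean
  absolute off-diagonal of $S$; the inner lasso tolerance is a tenth of that.
  Partial correlations below 1e-7 are snapped to exact zero.
* EBIC selection at very large $n$ tends toward the dense end of the path:
  unshrinking strong edges buys more likelihood than small spurious edges
  cost, a known property of path-wise EBIC-glasso. Recovery claims are
  therefore phrased in terms of *sign agreement of strong edges* (≥ 95% at
  $n = 11{,}000$ across 20 seeds), not exact support recovery: at that scale
  a substantial fraction of truly-absent pairs carries a small nonzero weight
  (median |w| ≈ 0.004 in the cohort simulations).
* Prevalence intervals are Wald, $p \pm 1.959964\sqrt{p(1-p)/n}$, clipped to
  $[0,1]$; Wilson is available. Percentages are rounded half-up to two
  decimals. Published tables of this kind mix rounding and truncation in a
  few cells (values ending one unit low); those cells are documented rather
  than replicated.
* PSQI cutoffs: global > 7 flags poor sleep quality; ≥ 10 flags
  clinical-level sleep problems (the operationalization used in the results
  being mirrored; methods prose elsewhere sometimes says "more than 10").
* Tie-breaks: symptom rankings sort descending with alphabetical tie-break;
  EBIC ties resolve to the sparser model.

## Worked example

```{r example, eval = FALSE}
truth <- build_true_network(seed = 1)
cohort <- sample_ordinal(truth, n = 11194, seed = 2)

net <- ebic_glasso(cohort, cor_method = "polychoric")
glance(net)
tidy(net) |> head()

cent <- centrality_table(net, data = cohort)
rank_symptoms(cent, 3)                     # central symptoms by EI
rank_symptoms(cent, 3, by = "bridge_ei")   # bridge symptoms

cs <- case_drop_cs(cohort, indices = "ei", B = 50, cor_method = "pearson")
tidy(cs)

two <- sample_two_groups(truth, set_edge(truth, "GAD.3", "PSQI.3", 0.3),
                         2000, 2000, seed = 3)
nct(two[two$group == "A", 1:14], two[two$group == "B", 1:14],
    n_perm = 1000, seed = 4)
```

The analysis-scale figures quoted in the README (sign agreement, average
predictability, CS-coefficient, NCT p-values) are computed by
`scripts/acceptance.R`, which runs this pipeline end-to-end at the
11,194-respondent cohort size with 1,000 permutations.

## Known limitations

* The polychoric estimator is pairwise two-step, not full-information ML;
  with severely sparse cells its pairwise matrix can be indefinite (then
  repaired by eigenvalue clipping, which perturbs all entries slightly).
* Predictability treats ordinal items as numeric; it underestimates the
  latent-scale variance explained.
* The NCT re-estimates each group with its own EBIC-selected penalty per
  permutation; with very unequal group sizes the sparser small-group network
  inflates $M$ slightly under the null, which the permutation distribution
  absorbs but which makes $M$ itself hard to interpret as an effect size.
* Case-dropping CS is reported on the grid only; 0.75 means "stable up to the
  largest tested drop", not an interpolated breakdown point.
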