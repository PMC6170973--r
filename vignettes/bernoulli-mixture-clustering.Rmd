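---
title: "Clustering component-specific IgE responses: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering component-specific IgE responses: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allergotype)
```

## The analysis problem

Component-resolved diagnostics measures IgE against individual allergenic
proteins. Given per-age panels (children × components, ISAC standardized
units), the questions this package answers are: which components elicit
responses *jointly* at each age (cross-sectional clusters), how those
clusters evolve across childhood (flows), and what sensitization to each
cluster implies for asthma and rhinitis (odds ratios).

The clustered unit is the **component**, not the child: each component is a
binary response profile across the children seen at that age, and
components with similar profiles belong together. Children enter as the
dimensions of that profile, and re-enter later as the unit of analysis for
the outcome models.

## Preprocessing rules

* **Positivity**: IgE ≥ 0.30 ISU, inclusive at the boundary. The threshold
  is a parameter of `binarize_panel()` but the 0.30 convention is the
  default and is also what the synthetic generator inverts exactly.
* **Activity**: a component is active at an age when at least
  `min_positive = 3` present children respond. Counting uses present
  subjects only; a child absent at an age is a missing row and is never
  imputed as zero — per-age denominators therefore vary, as they do in
  real cohort tables.
* **Restriction**: clustering at an age uses the active components and the
  children with ≥1 positive active response. The all-negative children are
  kept aside as the *nonsensitized* group for the outcome stage.
* **Drop-outs**: a component active at one age and inactive at the next is
  a drop-out (not necessarily permanent; re-activation is tracked). A
  drop-out is attributed to *resolution* when every previously positive
  child is still present and now negative, to *attrition* when all of them
  are absent, and left *undetermined* in every mixed situation. With
  realistically sized positive sets, mixed situations dominate, so
  `undetermined` is common on the synthetic presets; the clean categories
  are exercised with small constructed panels in the unit tests.

## The mixture model

Write $X$ for the items × subjects binary matrix ($n$ components, $J$
children), $z$ for the allocation of items to clusters $1..K$, $n_k$ for
cluster sizes and $s_{kj}$ for per-subject positive counts within cluster
$k$. Each cluster has an independent Bernoulli success probability per
subject, $\theta_{kj} \sim \mathrm{Beta}(a, b)$, and the weights carry a
symmetric Dirichlet($\gamma$) prior. Both are integrated out analytically
(`log_marginal_cluster()`, `log_allocation_prior()`), so the sampler moves
only on $(K, z)$:

$$p(K, z \mid X) \;\propto\; p(K)\,
  \frac{\Gamma(K\gamma)}{\Gamma(n+K\gamma)}
  \prod_k \frac{\Gamma(n_k+\gamma)}{\Gamma(\gamma)}
  \prod_{k,j} \frac{B(a+s_{kj},\, b+n_k-s_{kj})}{B(a,b)}.$$

Defaults: $a=b=1$ (uniform), $\gamma=1$, and a truncated Poisson(1) prior
on $K$ over $1..K_{\max}$ (a uniform prior is available). The full model
specification used in the original analyses of this kind is not published
alongside the summary tables, so these are this package's own declared
choices: the flat Beta/Dirichlet pair is the standard non-informative
collapse, and the truncated Poisson(1) is the usual allocation-sampler
convention that mildly favours parsimony. $K_{\max}$ defaults to
$\min(25, n-1)$, mirroring the way an analysis caps the support well above
any plausible number of clusters while keeping the smallest panels (around
ten active components at age 1) from degenerating.

$K$ counts mixture components, and empty components are legal states
mid-chain; reported memberships come from the retained draws conditional
on the modal $K^*$ (ties broken towards the smaller $K$, for parsimony and
determinism).

## The sampler

Each sweep of each chain runs, in order:

1. **Gibbs sweep** — every item reallocated from its full conditional over
   $1..K$; the collapsed predictives reduce to ratios of the form
   $(a+s)/(a+b+n_k)$, which the compiled core evaluates from integer
   lookup tables.
2. **Three Metropolis block moves** (no-ops when $K<2$): a random subset
   exchange between two clusters (symmetric proposal); a binomial mass
   reallocation of one cluster into another, with the subset size drawn
   through $p \sim U(0,1)$ so the proposal mass of a $d$-subset is the
   integrable $1/((n_k+1)\binom{n_k}{d})$; and a sequential reshuffle of
   two clusters from their restricted full conditionals, with the exact
   forward/reverse proposal probabilities in the acceptance ratio.
3. **Eject/absorb** — the trans-dimensional pair. Eject splits a binomial
   subset of a random cluster into a new top-labelled component
   ($K \to K+1$, blocked at $K_{\max}$); absorb merges the top label into
   a chosen lower one ($K \to K-1$, blocked at $K=1$). Restricting absorb
   to the top label makes the two moves exact reverses on labelled states,
   so detailed balance is elementary; mixing over which cluster occupies
   the top label is supplied by the label-permuting moves above.

Chains $c = 1..C$ run at inverse temperatures
$\beta_c = 1/(1+\delta(c-1))$ (defaults $C=4$, $\delta=0.15$), with one
adjacent-pair state swap attempted per sweep and only the cold chain
retained (burn-in 50%, thinning 1 by default). The whole schedule consumes
a single R RNG stream in a fixed interleaved order, so a run is exactly
reproducible from `seed` alone; this is simpler than per-chain child
streams and equally deterministic.

Two numerical safeguards: the per-cluster log marginals and the log
posterior are maintained incrementally (checked against full recomputation
to 1e-8 in the tests) and refreshed from scratch every 512 sweeps so no
drift can accumulate over long runs; and `exact_posterior_small()`, the
exhaustive-enumeration oracle used throughout the test-suite, refuses
instances beyond $K_{\max}^n > 10^7$ allocations.

Correctness is established against that oracle: on small fixed panels the
empirical posterior matches exhaustive enumeration not only over $K$ but
over the full labelled state space $(K, z)$, for every move family run
separately, and the complement symmetry ($a=b$, $X \to 1-X$) holds
exactly.

## Label switching and reported memberships

Retained draws at $K^*$ are relabelled with ECR: the pivot is the MAP draw
among them (earliest draw on ties), and each draw gets the permutation of
$1..K^*$ minimising disagreement with the pivot — an assignment problem on
the $K^* \times K^*$ agreement matrix, solved exhaustively (with
lexicographically-smallest tie-breaking) up to $K^*=7$ and by weighted
bipartite matching (igraph) above. Empty labels within a draw simply carry
zero agreement. Relabelling permutes labels only, so no draw's posterior
mass changes — asserted draw-by-draw in the tests. The reported object is
the component × cluster matrix of assignment fractions with modal
memberships (ties to the lower index).

## Flow semantics

Clusterings at different ages are fit independently; the flow stage is
purely post hoc. Every component of the universe routes through exactly
one edge per transition, components inactive on either side through the
explicit `inactive` node — so out-weights of each node sum to its size, a
conservation law the acceptance checks enforce. Newly active components
thus *enter* from the inactive pool rather than being uncounted; this is a
documented convention, since figure-level counting of newcomers is
ambiguous. Any shared component makes an edge substantial (single-component
moves are narratively meaningful in this field), so: several outgoing
edges = `split`, several incoming = `absorb`, no active source =
`newly-formed`, no active target = `dropout`, and a singleton whose target
is mainly the continuation of some other cluster = `reabsorbed` (the
distinguishing condition from a singleton that simply grows). Cluster
display names are user- or metadata-supplied; the algorithmic layer uses
opaque indices.

## Outcome models

A child is sensitized to a cluster when positive to ≥1 member component;
children positive to no active component form the nonsensitized group and
contribute zeros to every indicator (the reference profile). Univariable
and multiple logistic regressions produce ORs with Wald 95% CIs
($z=1.96$); for a binary exposure the univariable OR equals the 2×2
cross-product ratio, which doubles as its closed-form test. Complete
separation, non-convergence, aliasing and constant columns are flagged in
the result rather than raised; missing outcome or panel data drop the
child from that model only (complete case). No penalised fallback is
applied by default.

## The synthetic cohort generator

The generator plants exactly the structure the model assumes — that is its
point, and its limitation. Each subject carries one latent *family type*
(or `none`); each component belongs to one protein family; each age's
clusters are sets of families. A child responds to components of the
cluster containing its own family with `theta_in`, to other active
components with `theta_out`, and scheduled-inactive components are silent,
so within an age the rows of one cluster are i.i.d. Bernoulli vectors —
the mixture model is true by construction. ISU values are drawn uniformly
from [0.30, 15) for positives and [0, 0.30) for negatives so thresholding
inverts generation exactly.

Fixed study conditions of the presets:

* `s1` (recovery benchmark): one age, 4 clusters of sizes 18/18/17/17 over
  70 components, 400 children in four equal blocks, `theta_in = 0.7`,
  `theta_out = 0.05`; outcome model with baseline prevalence 10% and one
  risk cluster at OR 3.5. `hard` is the same with `theta_in = 0.4`.
* `paperlike`: six ages (1, 3, 5, 8, 11, 16 years) over a 112-component
  universe whose activity schedule realizes 10, 26, 63, 68, 71 and 72
  active components, per-age cohort sizes 226, 248, 588, 543, 461 and 361
  drawn from a 922-child roster (attrition is missing-at-random by
  sampling), and the qualitative flow script of childhood sensitization:
  a persistent broad cluster with drop-outs and re-activations, a
  four-component dust-mite cluster stable from age 3, a grass singleton
  growing into a grass/cat cluster at age 5, a single-component
  *Alternaria* cluster later reabsorbed by the broad cluster, cat and
  PR-10/profilin clusters emerging at age 11, and the latter dividing at
  age 16. Separation uses `theta_in = 0.7` against a low 0.01/0.001
  background so the schedule realizes essentially surely.

Outcome questionnaires are generated so the any-2-of-3 asthma rule holds
*exactly* for the drawn asthma status: status comes from the logistic
model on the realized cluster indicators, then the wheeze / medication /
diagnosis triple is drawn conditional on it (2–3 features when asthmatic,
0–1 otherwise). This keeps planted odds ratios recoverable without
misclassification attenuation, which the 50-replicate unbiasedness check
relies on.

What the generator deliberately does **not** emulate: ISU measurement
error and assay chemistry, cross-reactive epitopes (components of
different families correlating through shared IgE), overdispersed or
subject-correlated responses beyond the block structure, informative
drop-out, and covariate structure (sex, parental atopy). Passing the
recovery tests therefore demonstrates correctness of the machinery under
the model's own assumptions, not robustness to their violation.

## Problem sizes in the tests

The suite checks the sampler against exhaustive enumeration on panels of
5–6 items × 3–4 subjects with $K_{\max}=3$ (729–2 187 allocations per
$K$), where 2×10⁵ sweeps put the total-variation distance around 0.005,
comfortably under the 0.02 bound asserted; the recovery benchmark runs
3 000 sweeps × 4 chains on the 70 × 400 `s1` panel, which takes well under
a minute in the compiled core and recovers the planted partition exactly.
These sizes were chosen so the full suite and the acceptance script each
run in minutes on a single CPU while still exercising every code path at
meaningful scale.

## Known limitations

* No missing-data likelihood inside the clustered matrix: clustering
  requires the complete responders × active submatrix (the preprocessing
  guarantees it).
* The trans-dimensional pair is ejection/absorption only; no further
  split–merge designs, and no EM or variational alternative.
* Flow event labels are deterministic topological heuristics; narrative
  edge cases (a singleton absorbed into a cluster that itself barely
  persists) can be arguable and should be read together with the edge
  list.
* Wald CIs are first-order; near-separation ORs are flagged but not
  penalised by default.
* With realistic numbers of positive children per component, drop-out
  causes are usually `undetermined` under the strict
  resolution/attrition definitions; the clean categories need small
  positive sets.
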