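---
title: "Statistically validated co-occurrence networks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistically validated co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcn)
```

## The inference model

The data are check-in records $(s_z, t_z, l_z)$: subject $s_z$ appeared at
location $l_z$ at time $t_z$. The method assumes that a social tie
manifests as repeated spatio-temporal co-presence, and that coincidental
co-presence is driven by crowding — many people visiting the same popular
places at the same peak hours — rather than by any pairwise coordination.

**Segmentation.** Time is discretized into slots of length $\tau$ seconds
from an origin $t_0$; slot index $= \lfloor (t - t_0)/\tau \rfloor$. A
*segment* is the set of distinct subjects observed at one location in one
slot; repeat check-ins by the same subject inside a segment collapse to
one occurrence. Write $K$ for the number of non-empty segments, $L_k$ for
the size of segment $k$, $M = \sum_k L_k$, and $n_i$ for the number of
segments containing subject $i$.

**Null model.** Each of a subject's $n_i$ occurrences falls into segment
$k$ with probability proportional to the segment's size: $L_k/M$ for the
first subject and, conditional on that, $(L_k - 1)/(M - 1)$ for the
second. Summing the joint probability over all occurrence pairs and
segments gives the expected number of shared segments

$$E(X_{ij}) = \frac{n_i\, n_j}{M (M - 1)} \sum_k L_k (L_k - 1),$$

which is symmetric in $i$ and $j$. Crowding and peak hours enter through
the $L_k$: a co-occurrence in a crowded lunchtime segment is cheap, one in
a deserted segment is informative.

**Test.** When $n_i$ and $n_j$ are small relative to $K$, $X_{ij}$ is
approximately Poisson with mean $E(X_{ij})$, so the p-value of a pair is
the upper tail $P(\mathrm{Poisson}(E(X_{ij})) \ge X_{ij})$. Only pairs
with $X_{ij} \ge 1$ are testable; with $N_T$ tests the Bonferroni-corrected
threshold is $p_b = \alpha_0 / N_T$ and a pair becomes an edge iff
$p < p_b$ (strict, matching "less than the threshold"). The package also
ships a Monte-Carlo implementation of the same null (`mc_null_pvalue`):
both subjects are re-seated by weighted sampling without replacement with
weights $L_k$, giving an independent check on the Poisson approximation.

**Assumptions worth stating.** (1) Appearances of different subjects are
independent under the null — violated if subjects have strong *individual*
location habits beyond what crowd sizes explain, in which case the test is
anti-conservative (see the generator section). (2) The Poisson
approximation needs $n_i, n_j \ll K$; for heavy users of a small system
the Monte-Carlo route is the honest check. (3) A validated edge means
"co-presence beyond chance", which includes genuine social ties *and*
shared behavior patterns; only external reference data can separate the
two, hence the concordance module.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tau` | 300 | seconds | 5-minute slots: long enough to catch a queue together, short enough that a location rarely cycles its whole crowd |
| `alpha0` | 0.01 | — | base significance level before correction |
| `n_t_policy` | `candidate_pairs` | — | $N_T$ = number of testable pairs ($X_{ij} \ge 1$); `all_pairs` ($\binom{N}{2}$) and `explicit` are available because the count of "performed tests" is a reporting convention, not a mathematical necessity |
| `t0_policy` | `midnight_of_first_day` | — | slots align with the wall clock, so daily peaks land in the same slots every day; reproducible without configuration |
| correction | Bonferroni | — | strictest FWER control; the enum leaves room but no other method is implemented |

Ties at the threshold are excluded (strict `<`). The `explicit` policy
exists because published analyses sometimes report an $N_T$ that is
neither the candidate-pair count nor $\binom{N}{2}$; the package never
guesses, it exposes the choice.

## The synthetic world

`gen_population` → `gen_tie_graph` → `gen_events` builds, from one seed, a
population with categorical attributes, a planted tie graph whose dyad
probabilities are multiplied by $\beta_a$ for every shared attribute $a$,
and a check-in stream. Defaults describe a small campus-like world:

* 200 subjects, two attributes (binary gender 0.5/0.5, four grades 0.25
  each);
* tie model $p_\text{base} = 0.01$, $\beta_\text{grade} = 4$ — mean degree
  around 3.5 with planted intra-grade homophily;
* 17 locations (the scale of a campus's canteens and stores);
* per-subject activity rates Gamma(shape 4) around 2.5 visits/day —
  realistic heterogeneity without a heavy tail;
* visit times from a three-bump Gaussian mixture at 07:30, 12:00, 18:30
  (weights 0.25/0.40/0.35, sd 0.6 h), truncated to 05:00–23:30: the
  meal-time peaks that make coincidental co-occurrence frequent;
* per-subject location preferences drawn from a flat Dirichlet(1) over
  locations;
* tied pairs make a synchronized co-visit (same location, same
  $\tau$-slot) with probability $\rho$ per day.

Two generator design points deserve explanation because they were forced
by properties the stated world must have:

**Location-preference concentration.** The Poisson null knows about
crowding but not about individual place loyalty. With strongly
concentrated preferences (e.g. Dirichlet(0.3)), two unrelated subjects who
share a favorite canteen co-occur far beyond the size-weighted
expectation, and the null test produces false edges at a high rate. The
stated world requires family-wise error control ($\le 5\%$ of null runs
with any false edge), so the default is the flat Dirichlet(1): subjects
still differ (the most-preferred location is typically several times more
likely than the least), but diffusely enough that the null stays
approximately calibrated. This is also the honest statement of the
method's operating envelope: on real data with strong individual location
habits, the Poisson null is anti-conservative.

**Synchronization without triadic leakage.** A co-visit overwrites one of
the pair's independently drawn visits (keeping per-subject activity rates
independent of $\rho$), and each subject-day visit may serve at most one
synchronization role; excess syncs are skipped. Without this constraint,
two partners of the same subject repeatedly anchor to the same visit and
co-occur systematically — the generator would plant ties it never recorded
as ground truth, and false-positive accounting against the planted graph
would be meaningless.

What the generator does **not** emulate: seasonal and weekday/weekend
structure, subjects joining or leaving mid-study, location capacity
limits, spatial geometry, tie strength heterogeneity, and any coupling
between attributes and activity levels. A green end-to-end test therefore
establishes that the pipeline recovers planted pairwise synchronization
under calibrated-null conditions — not that the method is robust to every
behavioral confounder in real data.

## Numerical choices

* **Poisson tail.** $P(X \ge x) = P(\Gamma(x,1) \le \mu)$, evaluated as
  `exp(pgamma(mu, x, log.p = TRUE))`: the regularized lower incomplete
  gamma in log space keeps *relative* accuracy down to $\sim 10^{-300}$,
  far below Bonferroni thresholds around $10^{-10}$. Naive series
  summation underflows; the test suite uses an extended-precision series
  in log space as the independent oracle.
* **Truncated power law.** The discrete model
  $p(d) \propto d^{-\alpha} e^{-\lambda d}$, $d \ge d_\text{min}$, is
  normalized by direct summation to $10^5$ terms plus a midpoint-rule tail
  ($\int_{D+1/2}^\infty$, relative error $\sim \alpha(\alpha+1)/(24 D^2)$);
  for $\lambda > 0$ the tail integral uses the substitution $u = \log x$
  to keep `integrate` on a finite, well-behaved range. Fitting maximizes
  the likelihood over $(\alpha, \lambda)$ with `L-BFGS-B`,
  $\lambda \ge 0$, from five dispersed starts (tolerance $\sim 10^{-8}$ on
  the log-likelihood); the boundary $\lambda = 0$ is the pure power law,
  which requires $\alpha > 1$ to normalize. The model is fitted to the
  probability mass function; published parameters obtained by fitting on
  the CCDF axis are therefore treated as simulation truths for recovery
  experiments, never as targets to reproduce from data.
* **Sampler.** Exact inverse-CDF over a table extended until residual
  tail mass $< 10^{-10}$.
* **Assortativity.** All degree-assortativity computations use excess
  degrees (degree − 1 at each edge end); Pearson correlation is
  shift-invariant so raw degrees give the identical value. The universal
  decomposition assigns each edge
  $\rho_e = (j_e - \mu_q)(k_e - \mu_q) / (|E|\,\sigma_q^2)$ with moments
  taken over all $2|E|$ edge ends, which makes
  $\sum_{g \le h} r(g,h) = r$ an exact identity (tested at $10^{-10}$).
  Undefined coefficients (regular graphs, constant attributes) raise a
  classed error — never a silent 0.
* **TFPI normalization.** $s_{ij}$ counts edge ends per group member
  (both ends of an intra-group edge), so $s_i$ is the group's mean degree
  and the rows of $p_{ij} = s_{ij}/s_i$ are probabilities. This is the
  only convention under which the index is a proper row-stochastic
  homophily measure and the matrix can be asymmetric, which the
  male→female vs female→male distinction requires. The published
  verbal null condition ("$p_{ij} = w_i$") contradicts the formula
  $q_{ij} = (p_{ij} - w_j)/(1 - w_j)$, which zeroes at $p_{ij} = w_j$; the
  formula wins.
* **QAP.** One-sided add-one p-value $(1 + \#\{r_\pi \ge r\})/(B+1)$ —
  never exactly zero; rows and columns permuted simultaneously; dyad
  universe = all unordered pairs of the shared node set.
* **Neighborhood function.** $NF(l) = \#\{(u,v): d(u,v) \le l\}$ with
  self-pairs, so $NF(0) = N$; the $\le$ convention is forced by that
  anchor. Exact BFS only — approximate sketches are out of scope at the
  scale this package targets.
* **Clustering.** Mean of local coefficients with degree-$<2$ nodes
  contributing 0. On sparse graphs this differs substantially from
  transitivity (global triangle density); reported values are comparable
  only within one convention.
* **Path length.** Default scope is the giant component (an Erdős–Rényi
  comparison presumes connectedness); `all_connected_pairs` is available.

## Degenerate inputs and tie-breaks

Empty event streams produce an empty, error-free network. Pairs are
ordered lexicographically (`subject_a < subject_b`) everywhere. Segments
never pool across locations. Groups with no edges get `NA` TFPI rows plus
a `defined` flag. `M < 2` makes the expected co-occurrence undefined
(parameter error), as does $\mu \le 0$ for the Poisson tail.

## Known limitations

* The Poisson null does not model per-subject location habits; on data
  where those are strong the method over-validates (demonstrated by the
  generator's concentration experiment above).
* $\tau$ is fixed, not inferred; an ill-chosen slot length either misses
  ties (too short) or drowns them in noise (too long).
* Edges are binary and undirected; no tie strength, no direction, no
  temporal evolution.
* Community *detection* is out of scope — `modularity_score` only scores
  partitions produced elsewhere.
* The truncated power-law machinery compares pure vs truncated fits by
  likelihood only; bootstrap goodness-of-fit p-values are not provided.
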