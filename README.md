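# svcn — statistically validated co-occurrence networks

`svcn` infers social-proximity ties from time-stamped check-in streams
(RFID card scans, badge readers, room logs, animal tag detections, …) and
characterizes the resulting network. The problem it solves: raw
co-occurrence counts are dominated by coincidence, because populations have
shared peak hours of activity — everyone eats lunch at noon. The package
keeps only the pairs whose number of co-occurrences cannot be explained by
chance.

It is intended for researchers working with spatio-temporal contact data:
human social networks from facility logs, animal social network analysis
from detection streams, or epidemiological contact modelling.

## The method

A check-in stream is a set of records (subject *s*, time *t*, location
*l*). Time is cut into slots of length τ (default 300 s); a **segment** is
the set of distinct subjects seen at one location during one slot. Two
subjects **co-occur** when they share a segment; *X*ᵢⱼ counts the shared
segments.

Under the null hypothesis that every appearance is a random draw over
segments (weighted by segment size *L*ₖ), the expected number of shared
segments for subjects with *n*ᵢ and *n*ⱼ occurrences is

    E(X_ij) = n_i n_j / (M (M - 1)) * Σ_k L_k (L_k - 1),   M = Σ_k L_k .

When *n*ᵢ, *n*ⱼ ≪ *K* (the number of segments), *X*ᵢⱼ is approximately
Poisson with mean E(*X*ᵢⱼ), so each candidate pair gets an upper-tail
p-value P(Poisson(E(*X*ᵢⱼ)) ≥ *X*ᵢⱼ). Testing all candidate pairs is a
massive multiple-comparison problem; the Bonferroni correction sets the
acceptance threshold *p*_b = α₀ / *N*_T (α₀ = 0.01 by default). Pairs with
p < *p*_b become edges of the **statistically validated co-occurrence
network (SVCN)**; every observed subject stays in the network, so subjects
with no validated tie are singletons.

The metric stack on top of the inferred network:

* connected-component census, neighborhood function NF(*l*) (ordered pairs
  within *l* hops), average local clustering, path length, and
  Erdős–Rényi G(n, m) nulls — the small-world diagnostics;
* modularity scoring of a supplied partition;
* degree CCDFs and maximum-likelihood fits of the discrete exponentially
  truncated power law p(d) ∝ d^−α e^(−d/d_c);
* degree assortativity (global Pearson over edge ends) and its *universal*
  group-pair decomposition, which conserves the global coefficient;
* attribute assortativity (scalar and categorical) and the **tie formation
  preference index** TFPI, q_ij = (p_ij − w_j)/(1 − w_j), an
  inbreeding-homophily-style index that is 0 under size-proportional
  mixing, 1 when group *i* ties only to group *j*, and is deliberately
  asymmetric;
* concordance with a reference tie network: dyad confusion rates
  (TPR/TNR/FPR/FNR) and QAP permutation correlation;
* a seeded synthetic generator (attributed population → planted tie graph
  → check-in stream with meal-time peaks and heterogeneous activity) for
  end-to-end validation when no real data can be shared.

## Worked example

```r
library(svcn)

pop   <- gen_population(population_spec(150), seed = 1)
ties  <- gen_tie_graph(pop, tie_model(p_base = 0.01, beta = c(grade = 4)),
                       seed = 2)
ev    <- gen_events(pop, ties, checkin_model(n_days = 90, rho = 0.7),
                    seed = 3)
ev
#> <event_stream> 33320 records, 150 subjects, 17 locations

net <- build_svcn(ev, attributes = pop, tau = 300, alpha0 = 0.01)
net
#> <svcn_result> 150 nodes, 232 validated edges (of 3753 candidate pairs)
#>   alpha0=0.01, N_T=3753, p_b=2.665e-06 (bonferroni)

g <- as_igraph(net)
component_summary(g)
#> <component_summary> 5 components over 150 nodes / 232 edges
#>   giant: 146 nodes (97.33%), 232 edges (100.00%); 4 singletons (2.67%)

confusion_rates(g, ties)
#> <dyad_comparison> 150 nodes, 11175 dyads
#>   TP=232 FP=0 TN=10937 FN=6 | TPR=0.975 TNR=1.000

mx <- mixing_summary(g, pop, "grade")
round(mx$tfpi$q, 3)
#>           Freshman Junior Senior Sophomore
#> Freshman     0.272 -0.153  0.009    -0.152
#> Junior      -0.150  0.489 -0.127    -0.171
#> Senior      -0.053 -0.173  0.336    -0.134
#> Sophomore   -0.114 -0.111 -0.049     0.277
```

Reading the output: of 3,753 pairs that ever shared a segment, 232 survive
the Bonferroni-corrected Poisson test — 97.5% of the planted ties, with
zero false dyads. The positive TFPI diagonal recovers the planted
intra-grade homophily (β = 4); off-diagonal entries are negative because
ties preferentially stay within grade.

## Command line

```sh
SVCN=$(Rscript -e 'cat(system.file("cli/svcn", package = "svcn"))')
Rscript $SVCN simulate --out-prefix sim --seed 5 --n 200 --n-days 90 --rho 0.7
Rscript $SVCN infer    --events sim_events.csv --attributes sim_attributes.csv \
                       --out-prefix run
Rscript $SVCN metrics  --network run_network.graphml --out metrics.json
Rscript $SVCN mixing   --network run_network.graphml \
                       --attributes sim_attributes.csv --attribute grade \
                       --out-prefix mix
Rscript $SVCN concord  --inferred run_network.graphml \
                       --reference sim_ties.csv --out concord.json
```

Exit codes: 0 success, 1 usage error, 2 data/parameter error. Every JSON
report embeds a provenance block (config, seed, package version).

## Documentation

The methods vignette (`vignettes/svcn-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
numerical choices (log-space tails, normalization cutoffs, tie-breaks).
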