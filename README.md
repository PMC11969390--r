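# ratchetr

Agent-based simulation of cumulative cultural evolution and **social
ratcheting** — the point at which culturally specialized producers become
irreversibly interdependent. The package is for researchers in cultural
evolution who want to study how individual memory limits and kin-biased
social transmission shape the joint emergence of technological
complexity, specialization, and division of labour in multilevel
societies.

## The model in brief

A population of `n = 300` agents is divided into `M = 15` groups of 20,
each group a complete social graph of four unrelated families (two
parents, three offspring). Every agent starts with the same eight tools:
levels `X_1.1` and `X_1.2` of four technological lineages
`X ∈ {A,B,C,D}`, with baseline fitness 1 and 1.05.

Tool fitness is a deterministic ladder over the within-lineage creation
order `1.1, 1.2, 1.3, 2.1, …`: each incremental level multiplies fitness
by 1.05 and each stage transition doubles it, so
`f(m+1, 1) = 2 f(m, 3)`. New tools arise only from recombination in
dyads:

* *incremental*: the two immediate predecessors of a target tool in one
  lineage (`A_1.1 + A_1.2 → A_1.3`);
* *crossover*: two same-stage level-3 tools of different lineages open
  the next stage in the initiator's lineage (`A_1.3 + B_1.3 → A_2.1`).

Each round every agent picks a partner guided by
`P = (D_b − D_w) / 2`, where `D_w` and `D_b` are its mean Jaccard toolkit
distances `J = 1 − |∩|/|∪|` within and between groups: when `P > 0` it
seeks an out-group partner with probability `P`. Both dyad members draw a
tool with probability proportional to fitness; a recipe hit is adopted by
both and, in transmission scenarios, shared once with all network
neighbours (`P_s = 0.5` spouse/parent/offspring, `0.25` sibling, `0.05`
otherwise). Under limited memory (8 items) adoption evicts the
minimum-fitness tool. Cross-group dyads that create a tool leave
persistent between-group edges.

Two factors — memory (unlimited vs. 8 items) and transmission (off/on) —
define four scenarios `i`–`iv`. The measurement suite covers toolkit
entropy over lineages (specialization), agent- and group-level Jaccard
distances (differentiation), between-group links / path length / global
efficiency (interconnectivity), and ego-network tool coverage
(interdependence). See `vignette("ratchetr-model")` for the full account.

## A worked example

```r
library(ratchetr)
cfg <- scenario_config("iv")      # limited memory, social transmission
res <- run_simulation(cfg, seed = 1)
res
#> ratchetr simulation (scenario iv, 150 rounds, seed 1)
#>   max stage reached: 12; crossover levels: 11
#>   tools ever: 119; tools in final population: 59
#>   between-group links: 370
round(metrics_record(res)$summary[c("mean_entropy_weighted", "agent_jaccard",
                                    "between_group_links", "ego_pool_frac")], 3)
#> mean_entropy_weighted         agent_jaccard   between_group_links
#>                 0.642                 0.828               370.000
#>         ego_pool_frac
#>                 0.474
```

Reading the numbers: tools climbed 11 stage transitions to stage 12 in
150 rounds; 119 distinct tools were ever discovered but only 59 survive
in the capped toolkits. Mean weighted entropy 0.64 (max `log 4 ≈ 1.39`)
says agents are strongly specialized into few lineages; mean agent-pair
Jaccard 0.83 says the specialists are mutually differentiated; each
agent's ego network holds only ~47% of the population's tool pool, so no
neighbourhood can recreate the culture on its own — the division-of-labour
signature. Single runs take a few seconds; `run_batch("iv", base_seed = 1)`
gives 50-replicate means and standard errors, and
`compare_scenarios()` collates the four scenarios.

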