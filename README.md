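# toxorder

Multi-label **order-classification of chemical toxicity** from weighted
chemical-chemical interaction networks.

Early toxicity screening has to cope with compounds that carry several
toxic effects at once. `toxorder` implements a guilt-by-association order
classifier for seven categories — acute toxicity (T1), mutagenicity (T2),
tumorigenicity (T3), skin and eye irritation (T4), reproductive effects
(T5), multiple dose effects (T6) and non-toxicity (T7) — built on the
observation that interactive compounds (same reactions, similar structures
or activities, literature associations) tend to share toxicity profiles.
It is aimed at cheminformaticians and drug-discovery scientists who have a
STITCH-style interaction table and a curated label table and want a ranked
toxicity profile per compound rather than a single yes/no call.

## The method

Given a query compound $c_q$, a training set of labelled compounds, and
confidence scores $Q(c_q, c_i)$ from the interaction network (0 for
unrecorded pairs), the score for toxicity category $T_j$ is the weighted
neighbour vote

$$ S_j(c_q) = \sum_{c_i \in \text{training}} Q(c_q, c_i)\, t_j(c_i), $$

where $t_j(c_i)$ is 1 iff training compound $c_i$ carries $T_j$.
Categories with positive score are reported in descending order (the 1st,
2nd, ... order predictions); zero-score categories are excluded. The
evaluation protocol provides leave-one-out jackknifing, per-order
accuracies $\mathrm{Acc}_j = CT_j/N$, first-$m$ coverage with
$m = \lceil M \rceil$ ($M$ = mean labels per compound), the $M/L$ random
baseline, stratified multi-label train/test groups, and a pairwise
category co-occurrence analysis. A seeded generator of homophilous
labelled networks makes the whole pipeline testable offline.

## Worked example

A non-toxic query (tasosartan, CID000060919) with seven interactive
compounds: five high-confidence non-toxic drugs (scores 679, 670, 669,
667, 658) and two toxic ones (643 with labels T1+T6; 172 with T1+T2).

```r
library(toxorder)

labels <- as_label_table(list(
  CID000060919 = "T7", CID000003749 = "T7", CID000002541 = "T7",
  CID000060921 = "T7", CID000003961 = "T7", CID000060846 = "T7",
  CID000065999 = c("T1", "T6"), CID000054738 = c("T1", "T2")))
network <- as_interaction_network(tibble::tibble(
  compound_a = "CID000060919",
  compound_b = c("CID000003749", "CID000002541", "CID000060921",
                 "CID000003961", "CID000060846", "CID000065999",
                 "CID000054738"),
  score = c(679, 670, 669, 667, 658, 643, 172)))
dataset <- restrict_to_networked(labels, network)

scores <- category_scores("CID000060919",
                          setdiff(dataset$roster, "CID000060919"), dataset)
ordered_prediction(scores)
#> # A tibble: 4 × 3
#>    rank category score
#>   <int> <fct>    <dbl>
#> 1     1 T7        3343
#> 2     2 T1         815
#> 3     3 T6         643
#> 4     4 T2         172
```

The top vote is non-toxicity (3343 = 679+670+669+667+658), correctly
ranked above the residual toxic evidence: T1 scores 815 (= 643 + 172),
ahead of T6 (643) and T2 (172) — the toxic neighbours are outvoted but
still surface as lower-order candidates.

End-to-end on a synthetic homophilous benchmark:

```r
bench <- generate_benchmark(n_compounds = 2000, homophily = 0.9, seed = 42)
report <- evaluate(bench, mode = "jackknife")
report
#> <tox_eval> jackknife evaluation of 2000 compound(s)
#>   Acc: 1:0.8980 2:0.4120 3:0.2425 4:0.1570 5:0.1310 6:0.0745 7:0.0260
#>   M = 1.9485, m = 2, coverage@2 = 0.7516, baseline M/L = 0.2784
```

The first-order accuracy (89.8%) is far above the random baseline
$M/L = 27.8\%$, accuracies decline with order (the ranking is doing its
job), and the first two predictions cover 75% of each compound's true
categories on average. `tidy(report)`, `glance(report)` and
`autoplot(report)` expose the same numbers as tibbles and plots.

A command-line front-end wrapping the same functions (subcommands
`predict`, `evaluate`, `overlap`, `simulate`) is installed at
`system.file("cli", "toxorder.R", package = "toxorder")`.

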