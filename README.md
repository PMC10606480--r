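# hemlink

Link prediction on undirected networks from network-evolution mechanisms.

## The problem

Given an undirected simple graph *G(V, E)*, link prediction ranks the
unobserved node pairs by how likely they are to be missing (or future)
edges. Similarity-based predictors assign each pair *(x, y)* a structural
score *S<sub>xy</sub>* computed from the observed graph. Which statistic
works depends on how the network grew: `hemlink` makes that connection
explicit by pairing three classical evolution mechanisms with three
indices, and blending them into one parametric predictor:

| Index | Score | Mechanism |
|-------|-------|-----------|
| Reg | 1 / (k<sub>x</sub> k<sub>y</sub>) | degree balancing (regular networks) |
| DFPA | max(k<sub>x</sub>, k<sub>y</sub>) / min(k<sub>x</sub>, k<sub>y</sub>) | disassortative preferential attachment (scale-free networks) |
| LW<sub>k</sub> | (A<sup>k</sup> + A<sup>k+1</sup>)<sub>xy</sub> | short walk counts (small-world networks) |
| **HEM** | Reg<sup>α</sup> · DFPA<sup>1−α</sup> · LW<sub>k</sub> | hybrid, α ∈ [0, 1], k ∈ {2, 4, 8} |

A comparison bank of classical indices (CN, Salton, RA, CH, PA, LP/LPK,
Katz, LO) and seeded generators for random regular, Barabási–Albert and
Watts–Strogatz/Newman–Watts networks are included, along with a 10-fold
edge cross-validation harness (exhaustive or sampled AUC, precision@L) and
two diagnostics that identify which factor drives HEM's accuracy on a
given network.

Intended users: network scientists and computational biologists evaluating
link predictors on interaction networks (protein–protein interaction maps,
collaboration graphs, infrastructure networks) or on generated model
networks.

## Worked example

```r
library(hemlink)

# a small-world network, 2000 nodes, ring degree 8, 10% rewiring
g <- gen_ws(2000, 8, p = 0.1, seed = 7)

# cross-validate three indices on identical fold splits
ev <- cross_validate(g, list("cn", list(name = "lw", k = 2),
                             list(name = "hem", alpha = 0.5, k = 2)),
                     folds = 10, seed = 7, metrics = "auc")
sapply(ev, function(e) round(e$mean_auc, 3))
#>          cn         lw2 hem_a0.5_k2
#>       0.942       0.949       0.949
```

The walk-based index beats plain common neighbours because it also counts
paths of length 3, and the hybrid matches it: on a near-lattice network
the walk factor dominates, which is exactly what the factor diagnostics
report:

```r
factor_method1(g, folds = 10, seed = 7)
#> <factor_report: method 1>
#>    reg   dfpa    lw2    lw4    lw8
#> 0.7552 0.5471 0.9486 0.9481 0.9434
#>   main factors: LW2
```

The degree factors trail far behind (the rewired lattice is close to
degree-regular, so Reg retains only the probe-degree signal and DFPA is
near chance), while every LW variant is above 0.94; the selection rule
keeps only the best walk factor.

For one-shot analysis of an edge-list file there is a command-line
front-end:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "hemlink.R", package = "hemlink"))')" \
    report --graph edges.txt --seed 1 --out report.json
```

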