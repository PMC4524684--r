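# dimerflex

Cooperative versus independent domain motions in homodimeric enzymes,
probed from a single structure.

Many enzymes are homodimers with two equivalent active sites in clefts
between a stable core and a small mobile domain. Their catalytic cycles
hinge on opening and closing those clefts, and the functional question —
do the two sites close **together** (symmetric cooperativity), **in
opposition** (anti-symmetric: one closes as the other opens), or
**independently**? — is not answered by crystal structures alone.
`dimerflex` answers it at desk scale by combining:

* **Elastic network normal modes** — one site per Cα, uniform springs
  within a 12 Å cutoff; diagonalizing the 3N×3N Hessian gives 6 trivial
  zero modes and collective modes numbered from 7, plus normalized
  composites such as e₈₊₇ = (e₈+e₇)/√2.
* **Pebble-game rigidity analysis** — covalent, hydrogen-bond (Mayo-style
  distance–angle energies, cutoff −2.0 kcal/mol) and hydrophobic
  constraints matched against degrees of freedom, yielding the floppy mode
  count F, rigid clusters, and locked/variable dihedral labels. Body-bar
  convention for all-atom structures, bar-joint point game for coarse Cα
  networks.
* **Template-based geometric simulation** — overlapping rigid templates
  maintain bonding geometry while steps of ~0.01 Å along a mode direction
  (parallel and antiparallel) plus a random step explore large-amplitude
  flexible motion until it **jams** against the bonding and steric
  constraints.
* **Measures and statistics** — intersite distances d(AB)/d(BA), hinge
  angles, cleft angles ABC/BCD and dihedral ABCD, dRMS; trajectory PCA,
  projections, generalized dot products, cosine contents, windowed Pearson
  correlations, frame clustering.

A seed-deterministic synthetic two-domain dimer with designed hinges,
designated measure sites, and exact open/closed ground truth
(`make_toy_dimer()`, `make_open_closed_pair()`) makes the entire pipeline
testable without downloading anything.

## Worked example

```r
library(dimerflex)
library(dplyr)
library(tidyr)

toy <- make_toy_dimer(seed = 1)
toy
#> <toy_dimer> 2 chains x 88 residues (core 60 / linker 3 / mobile 25), seed 1

measure_sites(toy$atoms, toy$sites$intersite)
#> # A tibble: 2 × 3
#>   model measure value
#>   <int> <chr>   <dbl>
#> 1     1 d_AB     14.1
#> 2     1 d_BA     14.1

net <- build_constraint_network(toy$atoms, domains = toy$domains)
pebble_game(net)
#> <rigid_decomposition> point mode: F = 13, 9 clusters (largest 120 atoms), 750 redundant bars

res <- run_pipeline(toy, mode_list = list(7),
                    config = geosim_config(bias_step = 0.05, random_step = 0.02,
                                           max_steps = 300, save_interval = 20,
                                           seed = 7))
w <- res$runs$mode7_para$measures |>
  filter(measure %in% c("d_AB", "d_BA")) |>
  pivot_wider(names_from = measure, values_from = value)
rbind(head(w, 3), tail(w, 3))
#> # A tibble: 6 × 3
#>   frame  d_AB  d_BA
#>   <int> <dbl> <dbl>
#> 1     1  14.1 14.1
#> 2     2  15.3 13.1
#> 3     3  16.6 12.1
#> 4    14  19.9  5.25
#> 5    15  20.1  5.28
#> 6    16  20.3  5.28
cor(w$d_AB, w$d_BA)
#> [1] -0.942
```

Both clefts start equivalent at 14.1 Å. The rigidity decomposition finds
the designed architecture (the two interlocked cores form the single
120-residue rigid cluster; each mobile domain is its own cluster on a
flexible linker; F = 13 internal floppy modes). Driving the structure
along mode 7 closes one cleft to ~5.3 Å while the other opens past 20 Å —
the strongly anticorrelated signature (R = −0.94) of an anti-symmetric
cooperative motion. The symmetric mode (mode 8) instead moves both
distances together (R ≈ +1), and driving the clefts closed past steric
contact sets the jam flag: the natural amplitude limit of the constraint
network.

`plot_measure_pair()`, `autoplot()` methods, and broom-style
`tidy()`/`glance()` methods are available for every result type;
`write_pipeline()` exports multi-model PDB trajectories with CSV/JSON
sidecars.

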