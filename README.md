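# lshaped: L-shaped max-min selection for multitrait genomic selection

Breeders selecting parents for several traits at once usually collapse the
traits into one score with a weighted sum — *index selection*. That
scalarization has two structural problems: the winning subset can change when
a trait's measurement units change, and whole regions of the Pareto frontier
(non-dominated trade-offs lying in a concavity of the frontier) can never win
for *any* choice of weights.

`lshaped` implements the max-min alternative. With normalized genetic values
`ṽ[i,k] = (v[i,k] − v̲_k) / (v̄_k − v̲_k)` strictly inside (0, 1), the
selected subset of size S maximizes

    max_x  min_k  ( Σ_i x_i ṽ[i,k] / w_k )      s.t.  Σ_i x_i = S,

the smallest weight-deflated normalized trait sum. Its level sets are
L-shaped in two dimensions. Two properties drive the package:

* a weighted-sum optimum under strictly positive weights is always Pareto
  optimal, but only *supported* (convex-hull) solutions are reachable;
* **every** Pareto-optimal subset is a max-min optimum under the constructive
  weights `w_k = Σ_i x̂_i ṽ[i,k]` (its own normalized trait sums), and the
  normalized formulation is invariant to per-trait changes of units.

The package provides, in plain R:

* genetic-value computation `v = G β` from phased biallelic genotypes and
  additive allele effects, trait orientation, and relative-ε normalization
  (`compute_genetic_values`, `orient_traits`, `compute_bounds`,
  `normalize_values`);
* exact solvers `index_select` and `lshaped_select` (subset enumeration),
  `weights_for_solution`, plus frontier utilities `pareto_front`,
  `supported_front` (exact convex-hull / quadratic-program support test) and
  `lshaped_weight_regions`;
* the two population-level performance measures `pareto_optimality_gap` and
  `diversity` over `evaluation_set`s with per-project provenance weights;
* a recurrent breeding simulator (`make_gamete`, `cross`,
  `run_breeding_program`, `run_experiment_grid`) with meiosis under a
  no-interference recombination map;
* synthetic maize-like data generators (`simulate_founders`,
  `simulate_effects` with a tunable genetic correlation, default target
  0.375, `simulate_recomb_map`, `maize_like_data`) and the printed
  four-individual worked example (`example1_fixture`);
* TSV/phased-VCF readers and writers and a CLI (`exec/lshaped`, or
  `cli_main()` from R) with subcommands `simulate-data`, `select`,
  `frontier`, `breed`, `experiment`, `metrics`, `example1`.

## Worked example

The classical illustration: select 2 of 4 individuals (6 candidate crosses,
2 traits). All six crosses are Pareto optimal, but a weighted sum can only
ever return three of them; max-min selection reaches all six.

```r
library(lshaped)
cli_main("example1")
```

```
Individuals (normalized genetic values):
   trait1 trait2
i1   0.05   0.33
i2   0.22   0.22
i3   0.30   0.15
i4   0.44   0.06

Candidate crosses (trait sums):
 cross parents sum1 sum2
    c1   i1+i2 0.27 0.55
    c2   i1+i3 0.35 0.48
    c3   i1+i4 0.49 0.39
    c4   i2+i3 0.52 0.37
    c5   i2+i4 0.66 0.28
    c6   i3+i4 0.74 0.21

Pareto frontier: c1, c2, c3, c4, c5, c6 (6 of 6)
Supported (convex efficient) frontier: c1, c5, c6 (3 of 6)

Max-min weight regions (w1 intervals and optimal cross):
 cross  w1_lo  w1_hi
    c1 0.0000 0.3600
    c2 0.3600 0.4730
    c3 0.4730 0.5698
    c4 0.5698 0.6500
    c5 0.6500 0.7586
    c6 0.7586 1.0000

L-shaped selection, equal weights: {i1, i4}, objective 0.78
```

Reading the output: dominance filtering retains all 6 crosses; the
weighted-sum criterion can only reach the 3 hull vertices c1, c5, c6; the
max-min weight decomposition assigns every cross a nonempty interval of
`w1 ∈ (0, 1)` (`w2 = 1 − w1`), so each is optimal for some weights. With
equal weights the optimum is cross c3 = (i1, i4) with objective
min(0.49, 0.39)/0.5 = 0.78.

A full simulated breeding comparison runs from the shell:

```sh
exec/lshaped simulate-data --preset maize-like --seed 1 --out data/
exec/lshaped experiment --founders data/genotypes.tsv --effects data/effects.tsv \
    --recomb data/recomb.tsv --weight-grid 0.1,0.3,0.5,0.7,0.9 --reps 3 \
    --progeny 100 --generations 5 --seed 42 --out results/
exec/lshaped metrics --set0 results/final_set_index.tsv \
    --set1 results/final_set_lshaped.tsv
```

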