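---
title: "Max-min selection of breeding parents: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Max-min selection of breeding parents: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lshaped)
```

## The selection problem

Multitrait genomic selection chooses `S` breeding parents from a candidate
population using genome-wide additive values `v[i, k] = sum_j G[i, j] beta[j, k]`
(dosage times per-copy allele effect). With several traits this is a
multiobjective subset-selection problem: a subset is *Pareto optimal* when no
other subset is at least as good on every trait sum and strictly better on
one. Three simplifying assumptions frame everything in this package: genotype
and recombination data are known; traits are purely additive (no dominance or
epistasis, no environmental noise); and allele effects are known constants.
Traits to be minimized are oriented by negation (`orient_traits`); traits
that should fall in a range are out of scope (a hook exists via orientation,
nothing more).

Classical **index selection** maximizes `sum_k w_k sum_i x_i v[i, k]`. It is
exactly solvable by truncation on the per-individual score and always returns
a Pareto-optimal subset when all weights are positive, but it has two
structural limitations: the winner can change under a per-trait change of
measurement units, and only *supported* solutions — those on the convex hull
of the subset-sum cloud — are reachable by any weights.

**Max-min (L-shaped) selection** first normalizes values into the open unit
interval and then maximizes `min_k (sum_i x_i vtilde[i, k] / w_k)`. Both
limitations disappear: the normalization makes the solve units-invariant, and
for any Pareto-optimal subset the constructive weights
`w_k = sum_i x_i vtilde[i, k]` make that subset optimal (objective exactly 1),
so the whole frontier is reachable. The package's `lshaped_weight_regions`
makes this concrete for two traits by partitioning `w1 in (0, 1)` into
intervals, each owned by one Pareto-optimal point: the boundary ray between
adjacent frontier points `p` (stronger on trait 2) and `q` (stronger on
trait 1) passes through the corner `(p1, q2)` of the L-shaped level set that
touches both, giving the breakpoint `w1/w2 = p1/q2`. (A weighted-*sum* tie
between the same two points would instead occur at
`w1/w2 = (p2 - q2)/(q1 - p1)`; the two decompositions agree only on which
points are supported, not on where the regions lie.)

## Normalization: the load-bearing step

Bounds per trait are `lower = min - eps`, `upper = max + eps` over a
reference set, with `eps = epsilon_rel * (max - min)` (default
`epsilon_rel = 1e-6`). Making the padding *relative* to the observed range —
rather than an absolute constant — is what gives exact units-invariance: the
bounds then transform along with any per-trait positive affine rescaling and
the normalized values are unchanged. A machine-precision floor
(`4 * .Machine$double.eps` times the bound magnitude) protects the padding
when a trait's range is vanishingly small relative to its magnitude, as
happens in nearly fixed populations; without it the padded bounds can round
onto the extremes and the "strictly inside (0, 1)" guarantee fails. Values
outside the bounds raise an error naming the individual and trait — never a
silent clamp, which would corrupt the max-min objective. A constant
(degenerate) trait is an error unless an explicit absolute fallback range is
configured.

Inside a breeding run the reference set is a genuine design choice, exposed
as `bounds_policy`:

* `"refresh"` (default) recomputes bounds from each generation's candidate
  population. Normalized candidate values then always span (0, 1), so a
  weight ratio keeps its intended meaning — "one percentage point of the
  observed range of trait 1 is worth `w1/w2` points of trait 2". Selection is
  a within-generation comparison, so cross-generation comparability of the
  normalized scale is not needed there.
* `"attainable"` freezes bounds over every genotype reachable from the
  founder alleles (per-locus extreme dosages times effects). These bounds can
  never be violated and are comparable across generations, but realized
  populations occupy a narrow central band of the attainable range, so the
  normalized values compress and the weights lose their percentage-point
  semantics (the min over traits is then decided almost entirely by the
  weights, degenerating toward single-trait selection). Useful when a frozen
  common scale matters more than weight interpretability.
* `"generation0"` freezes the observed founder-value bounds. Transgressive
  progeny — which routinely exceed the founder range after a few generations
  of directional selection — then fail normalization with an error; this
  policy is safest for one-generation selection on a fixed candidate panel.

For the *performance metrics* after a multi-run experiment, comparability is
exactly what matters, so `run_experiment_grid` normalizes all pooled
final-generation values with one set of bounds computed over the union of
every run's finals plus the founders.

## Exactness policy

`lshaped_select` enumerates all `choose(n, S)` subsets when that count is at
most `enumeration_cap` (default `1e6`; two parents from 200 candidates is
19,900 subsets, far below it). Ties on the max-min objective are real — a
max-min optimum can be weakly dominated — and are broken by the largest total
normalized sum, which guarantees the returned subset is itself Pareto
optimal, then by lexicographically smallest index set for reproducibility.
Above the cap the function stops with a capacity error: the exact integer
formulation (maximize `z` s.t. `z <= sum_i x_i vtilde[i,k]/w_k`) needs a MILP
solver, and no approximate fallback is offered because the recovery
guarantees under constructive weights only hold for exact optima.

`supported_front` is exact too: for two traits it takes the strict vertices
of the upper-right convex hull (collinear segment-interior points are weakly
supported — they tie with the segment endpoints at their only supporting
weights — and are excluded unless `include_boundary = TRUE`); for more traits
each Pareto candidate is tested for existence of strictly positive supporting
weights by feasibility of a small strictly convex quadratic program
(`minimize ||w||^2` subject to `w >= 1` and `(p - q) . w >= 1`), which by
homogeneity is equivalent to strict weighted-sum maximization.

## Performance measures

`pareto_optimality_gap(P0, P1)` sums, over the Pareto subset `P0`, the
smallest weighted positive deficit against the competitors in `P1` that
*dominate* each member; an undominated member contributes 0, as does weak
dominance with equality in some trait (an arbitrarily small improvement there
would break the dominance). Restricting the inner minimum to dominating
competitors is deliberate: minimizing over all competitors would let any
non-dominating competitor zero out every term. The weights are each
individual's *provenance* weights — the weight vector of the breeding project
that produced it — because a project's own priorities are the right scale for
judging how badly its output is dominated; external sets without provenance
fall back to uniform weights with a warning. The raw sum is returned (that is
the defining formula), with the per-individual terms and their mean attached,
since summaries are sometimes quoted per individual.

`diversity(P0, w)` is the weighted double sum of squared per-trait
differences over all ordered pairs, divided by `|P0|`. That literal form is
the default; because the quantity is described as an average Euclidean
distance while the printed formula is neither averaged over pairs nor rooted,
the per-pair (`"mean"`) and rooted (`"rms"`) variants are available behind a
flag rather than silently substituted. Pareto subsets are deduplicated by
trait vector first, so overlapping progeny count once.

## The breeding simulator

Meiosis uses a no-interference (Haldane-type) model: one uniform starting
phase, then independent Bernoulli(r) phase switches per adjacent-locus
interval. Chromosome boundaries are intervals with r fixed at exactly 0.5,
which re-randomizes the phase and is distributionally identical to a fresh
uniform start per chromosome — so a genome-length single pass implements
independent assortment exactly. Each generation the simulator selects `S = 2`
distinct parents from the current population only (the distinct-index
constraint of the subset model rules out selfing) and makes one biparental
cross of `N` progeny; selection sees true genetic values, consistent with the
no-noise assumptions. Defaults are `S = 2`, `N = 200`, `T = 5`.

`run_experiment_grid` runs every method x weight x repetition combination
independently (default grid `w1 in {0.1, ..., 0.9}`, `w2 = 1 - w1`, 10
repetitions), deriving one child seed per run from the master seed by seeding
R's generator and drawing the seeds in fixed run order — reproducible,
independent, and documented in the run record. Each pooled final-generation
individual carries its run's weights as provenance for the gap metric.

## What the synthetic data emulate — and what they do not

`maize_like_spec()` mirrors a maize inbred panel: 200 fully homozygous
founders, 10 chromosomes x 100 SNPs, per-locus allele frequencies from
Beta(2, 2), within-chromosome recombination frequencies from an exponential
distribution with mean 0.02 truncated to [0, 0.5] (a dense SNP map on
chromosomes of roughly two Morgans), and two pleiotropic traits whose effects
are drawn from a correlated Gaussian. The genetic correlation is targeted at
the *value* level: because allele frequencies and linkage perturb the
realized correlation of founder genetic values away from the effect-level
correlation, `simulate_effects` tunes the effect correlation by a
deterministic one-dimensional root search (on fixed underlying Gaussian
draws) until the founder-value correlation hits the target, 0.375 by default;
both the effect-level and realized value-level correlations are reported on
the result.

Deliberate simplifications, and what they imply for the tests: founders are
drawn with *independent* loci, so the panel has no linkage disequilibrium
structure beyond what crossing creates; both traits' effects share one scale,
so the synthetic traits are numerically balanced in a way real trait pairs
measured in different units are not — which specifically mutes the
unit-sensitivity handicap of raw-value index selection, one of the two
documented failure modes of that method; and there is no pedigree or
coalescent founder history. Passing tests on these data therefore establish
the solvers' exactness, the simulator's calibration and the metrics'
identities, but the *relative field performance* of the two methods on real,
unit-imbalanced, LD-structured data is not something the synthetic comparison
can certify. At the reduced scale used in the suite (50 founders, 200 loci,
three generations, a 3-weight x 3-repetition grid), the pooled Pareto subsets
hold only a handful of points each; the suite's directional comparison
reflects that the diversity advantage of max-min selection shows through
noisily at this scale, while the pooled gap comparison is variance-dominated
when both traits share a common scale.

## Numerical and degenerate-input choices

* Exact floating-point comparison is used for objective ties; the structured
  worked-example values tie exactly, and random instances tie with
  probability zero. Constructive-weight recovery checks use a `1e-12` slack
  on the maximum only.
* In `"refresh"` mode a trait with zero range among the current candidates
  (a fixed trait) gets a unit fallback range: it cannot discriminate
  candidates, and the fallback keeps the solve well-defined while leaving
  the ranking to the segregating traits (flat contributions tie-break by
  total sum).
* `lshaped_weight_regions` requires strictly positive two-trait points (the
  corner geometry lives in the positive quadrant, where normalized sums are).
* Single-individual populations, single-trait problems (`K = 1`, where both
  methods coincide with truncation), duplicate trait vectors, and weight
  rescaling by a common constant are all covered by explicit contracts and
  tests rather than left to chance.

## Interfaces

Index selection defaults to raw values — its classical form — with
`index_normalize` to run it on the normalized scale; max-min selection always
requires normalized values. Files are tab-separated UTF-8 with mandatory
headers and `#` comments (genotypes as `locus/chrom/<id>_h1/<id>_h2` columns;
effects as `locus/<trait>` columns; recombination maps as
`locus_left/locus_right/r` rows; values as `individual/<trait>` columns with
a `# normalized` marker). Phased VCF 4.x is accepted for genotypes; unphased
or multiallelic records are errors that name the offending record. Every CLI
run writes a JSON run record with the full configuration, seeds and input
digests, sufficient to re-execute the run bit-identically.
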