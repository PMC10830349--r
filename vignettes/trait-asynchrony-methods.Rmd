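---
title: "Linking trait dissimilarity to abundance asynchrony: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking trait dissimilarity to abundance asynchrony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asyntraits)
```

## The question

Communities whose species fluctuate out of step ("asynchronously") are
buffered against environmental perturbations: a bad year for one species
is not a bad year for all. One candidate mechanism is functional trait
diversity — species with different body sizes, phenologies, diets or
habitat uses are exposed to, and respond to, environmental drivers
differently, so their abundances should decouple. `asyntraits`
implements the full statistical pipeline for testing that idea on
annual abundance-index monitoring data: pairwise asynchrony from
interannual changes, Gower trait dissimilarity, phylogenetic distance,
and Mantel permutation inference, together with a synthetic-data
generator whose ground truth makes every stage testable.

## Asynchrony from collated annual indices

The input is a long-format panel of *collated annual abundance indices*
— the standardized log-scale yearly index that monitoring schemes
publish per species (an estimate of the log expected count on a
standardized survey). We difference each species' series,

$$\Delta_{i,t} = \mathrm{index}_{i,t+1} - \mathrm{index}_{i,t},$$

only across consecutive observed years (never across a gap), and for
each species pair compute the Pearson correlation $K_{ij}$ of their
changes over shared intervals (pairwise-complete). Asynchrony is

$$M_{ij} = \frac{1 - K_{ij}}{2} \in [0, 1],$$

so $K = 1 \mapsto M = 0$ (perfect synchrony), $K = 0 \mapsto 0.5$, and
$K = -1 \mapsto 1$. This form maps the correlation onto the same $[0,1]$
scale as the Gower trait dissimilarities it is compared against.

Numerical conventions: pairs sharing fewer than `min_overlap` intervals
(default 5 — a Pearson correlation on fewer points is uninformative) or
with zero variance over the shared intervals are left undefined and
excluded from vectorization, with a reported count. Differencing on the
log scale makes $M$ invariant to multiplying a species' raw abundances
by any positive constant, so differing survey efficiencies across
species are harmless.

## Trait dissimilarity with equal group contribution

Traits are stored as species × *dimension* tables: a continuous trait
(forewing length in mm, dry mass in mg, hostplant number) is one
dimension; a categorical trait is dummy-coded over several binary
dimensions (e.g. 12 monthly presence columns for each life-stage
phenology trait, 8 habitat classes), with 1s in every applicable
column. Gower distance handles the mix:

* continuous trait: $d_{ij} = |x_i - x_j| / \mathrm{range}(x)$, the
  range taken over the analysis species set (so distances are relative
  to the community at hand, which is Gower's definition — the
  species-set dependence is intended);
* multi-dimension binary trait: mean mismatch over mutually observed
  dimensions, rescaled by the maximum observed distance so each trait
  spans $[0, 1]$;
* missing values: pairwise deletion at the dimension level with weight
  renormalization.

Because traits within a functional theme are correlated (three body
size measurements say nearly the same thing), combining all dimensions
with equal weight would over-count themes with many columns. The
combined matrix therefore gives each *trait group* — nesting, body
size, phenology, diet, habitat — a fixed group weight $1/6$, split
equally among the group's traits: a single-trait group like habitat
carries weight 0.167, each of three body-size traits 0.0556, each of
six phenology traits 0.0278. The combined distance is the weighted mean
over traits defined for a pair, renormalized by the sum of their
weights, so the non-unit weight total (five groups × 1/6) is
immaterial. We use these fixed analytic weights rather than an
iterative contribution-optimization: with comparably dispersed group
distances the fixed scheme already equalizes group contributions (the
test suite checks the contribution spread), and it is exactly
reproducible.

## Phylogenetic distance

Related species share evolutionary history and hence traits, so a
trait-asynchrony correlation could be phylogeny in disguise. We take
patristic distances (sum of branch lengths on the tip-to-tip path) from
user-supplied Newick trees; trees must carry branch lengths on every
edge, polytomies are accepted, and internal labels ignored. Species
complexes that field protocols cannot separate (the classic case is a
*Bombus* complex) are collapsed into one operational unit whose
distance to every other species is the arithmetic mean of the members'
distances; the mean can break ultrametricity, so only metric-agnostic
properties (symmetry, nonnegativity, zero diagonal) are guaranteed
afterwards. Collapsing happens before species alignment, so the complex
label in the abundance and trait tables counts as phylogenetically
covered.

## Mantel inference

All hypotheses are about agreement between distance matrices, tested on
vectorized lower triangles:

* **Simple Mantel**: Pearson $r$ between the two vectors; the null
  distribution comes from jointly permuting rows and columns of the
  second matrix, with the one-tailed p-value
  $p = (1 + \#\{r_\pi \ge r_\mathrm{obs}\})/(n_\mathrm{perm} + 1)$ for
  $H_0\!: r \le 0$ (the add-one convention never reports 0). Default
  10,000 permutations.
* **Partial Mantel**: first-order partial correlation
  $r_{AB\cdot C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1 - r_{AC}^2)(1 - r_{BC}^2)}$,
  used as *asynchrony ~ trait dissimilarity, controlling phylogenetic
  distance*. The null permutes the trait matrix and recomputes $r_{AB}$
  and $r_{BC}$ with $r_{AC}$ fixed (raw-matrix permutation,
  Smouse–Long–Sokal style). We chose raw-matrix permutation over
  residual-matrix permutation because it permutes an actual data object
  (the trait matrix) rather than model residuals and matches the
  question "could traits alone explain asynchrony"; the two schemes
  agree asymptotically.
* **Bootstrap 95% CI**: each repeat subsamples 90% of species *without
  replacement* and recomputes $r$ on the induced submatrices;
  with-replacement resampling would duplicate species and create
  artificial zero distances. Degenerate repeats are discarded (error if
  more than half are). Default 10,000 repeats.
* **Exact oracle**: for $n \le 8$ species the test enumerates all $n!$
  simultaneous row/column permutations and returns the exact one-tailed
  p; the Monte-Carlo p must agree with it within Monte-Carlo error,
  which the test suite verifies on twenty random 6-species pairs.

Ties in the permutation count are resolved with a $10^{-12}$ tolerance
so exact duplicates of $r_\mathrm{obs}$ (e.g. under symmetric inputs)
count as "at least as large". No multiple-testing correction is applied
across per-trait tests; results tables report raw one-tailed p-values,
and users comparing many traits should treat marginal p-values
accordingly.

One wrinkle worth naming: the permutation machinery produces a
permutation p-value, and that is what `p_one_tailed` is. Descriptions
of this output elsewhere sometimes call it a one-tailed *t*-test; the
quantity actually computed here (and in the reference R implementation
this mirrors) is the permutation tail probability.

## The synthetic study system

Real monitoring data cannot certify a pipeline — the truth is unknown.
The generator builds a system where it is known:

1. **Tree**: pure-birth (Yule) tree with `n_species` tips
   (`birth_rate` 1 per unit time), via `ape`.
2. **Traits**: continuous traits evolve by Brownian motion (rate 1 per
   unit branch length by default); each binary dimension evolves by a
   symmetric 2-state Mk model (rate 0.3 by default — fast enough to
   vary, slow enough to retain phylogenetic signal on a tree of depth
   $\approx \log n$). The default trait specification mirrors a mixed
   insect trait table: 14 traits over 97 dimensions in five groups.
3. **Abundance**: for year $t$ and driver $d$,
   $e_{t,d} \sim N(0,1)$ shared across species;
   $\Delta_{i,t} = \sum_d w_{i,d}\, e_{t,d} + \varepsilon_{i,t}$ with
   $\varepsilon \sim N(0, \sigma^2)$, and the index is the cumulative
   sum from a species baseline ($N(2, 0.5)$ on the log scale, typical
   of published collated indices). Loadings are
   $w_i = \beta\, g(\mathrm{traits}_i) + (1 - \beta)\, u_i$: $g$
   assigns each trait dimension to a driver cyclically (continuous
   dimensions z-scored, binary as $\pm 1$), sums contributions and
   z-scores each driver column; $u_i$ are iid standard normal
   idiosyncratic loadings. $\beta$ (default 0.8) dials how much of a
   species' driver sensitivity is trait-determined; $\sigma$ (default
   0.5) is annual demographic/observation noise on the change scale.
4. **Missingness**: a fraction (default 5%) of (species, year) cells
   is removed completely at random — the simplest testable mechanism;
   real monitoring gaps are structured (scheme start dates, recorder
   effort), which this does not emulate.

The closed-form oracle makes recovery testable: with those loadings the
population correlation of two species' changes is

$$K_{ij} = \frac{w_i \cdot w_j}{\sqrt{(\lVert w_i \rVert^2 + \sigma^2)(\lVert w_j \rVert^2 + \sigma^2)}},$$

so `expected_asynchrony()` returns $M = (1 - K)/2$ exactly, and the
empirical matrix must converge to it as years accumulate (the suite
checks mean absolute error $< 0.05$ at 2000 years, and that error
decreases over 50 → 500 → 2000 years in a majority of seeds).

A second generator, `simulate_confounded_dataset()`, builds the
adversarial case for the partial test: abundance driven only by hidden
Brownian traits (one per driver; defaults: 40 species, 200 years, four
hidden drivers, $\sigma = 0.3$), while the *measured* traits are
independent Brownian traits on the same tree. Any simple
trait-asynchrony correlation is then pure phylogenetic confounding, and
conditioning on patristic distance should push $r$ toward zero — the
suite requires the mean $r$ to be attenuated by more than half over ten
seeds.

Randomness uses one root seed per dataset with documented per-stage
sub-seeds (tree, traits, abundance, missingness), so each stage is
independently reproducible and panels are bit-identical under a fixed
seed.

## What the tests do and do not show

Problem sizes were chosen to make Monte-Carlo error small relative to
the assertion being made: parameter recovery uses 20 runs of 60 species
× 40 years (the regime where the association is decisively detectable);
null calibration uses 300 datasets of 25 species × 25 years with
$\beta = 0$ and 500 independent-matrix replicates at 30 species; oracle
agreement uses 100,000 permutations against full enumeration at 6
species. Passing these certifies the *machinery* — the statistics, their
null distributions, and the generator's internal consistency. It does
not certify that real moth or bumblebee communities behave like the
generator: real indices have estimation error correlated across
species, structured missingness, density dependence and observation
models that the Gaussian-change simulation deliberately omits.
Conclusions about real data rest on the pipeline being correct, which
is what is tested, not on the synthetic world being realistic.

## Known limitations

* Continuous traits are range-scaled on the analysis species set, so
  adding or removing species changes single-trait distances slightly;
  this is inherent to Gower scaling.
* No log-transform is applied to body mass or hostplant number by
  default; supply transformed columns if skewness is a concern.
* The iterative contribution-optimizing variant of group weighting is
  not implemented; the fixed Table-of-weights scheme is used.
* Partial Mantel tests with raw-matrix permutation can be slightly
  liberal when the conditioning matrix is strongly structured; the
  residual-permutation alternative is not currently exposed.
* `collapse_complex()` averages distances at the matrix level (not by
  re-deriving a pruned tree); the two differ when the complex is not
  monophyletic.
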