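# asyntraits

Do species with more dissimilar functional traits fluctuate more
asynchronously in abundance? Interspecific asynchrony buffers
communities against environmental perturbations, and trait diversity —
differences in body size, phenology, diet, habitat use — is a leading
candidate mechanism. `asyntraits` implements the complete statistical
pipeline for testing this on annual abundance-index monitoring data
(and on synthetic data with known ground truth), aimed at quantitative
community ecologists working with scheme-style species × year index
panels.

## What it computes

* **Abundance asynchrony.** From a long panel of collated annual
  log-scale indices, interannual changes
  Δᵢ,ₜ = indexᵢ,ₜ₊₁ − indexᵢ,ₜ (never across gaps), then for each
  species pair the Pearson correlation K of changes over shared
  intervals, mapped to M = (1 − K)/2 ∈ [0, 1] (0 = synchronous,
  0.5 = uncorrelated, 1 = anticorrelated).
* **Trait dissimilarity.** Gower distances for mixed
  binary-dummy-coded and continuous traits, per trait and combined
  with *equal group contribution*: each trait group (nesting, body
  size, phenology, diet, habitat) gets weight 1/6 split equally among
  its traits (0.167 for a 1-trait group, 0.0556 for 3, 0.0278 for 6),
  with renormalization over traits defined per pair.
* **Phylogenetic distance.** Patristic distances from Newick trees,
  with species complexes collapsed by averaging member distances.
* **Mantel inference.** Simple and partial Mantel permutation tests
  (partial r_AB·C = (r_AB − r_AC·r_BC)/√((1−r_AC²)(1−r_BC²)),
  conditioning on phylogeny), one-tailed permutation p with the
  add-one convention, bootstrap 95% CIs by species subsampling, and an
  exact n! enumeration oracle for n ≤ 8.
* **Synthetic data.** Pure-birth trees, Brownian/Mk trait evolution,
  and trait-driven abundance panels whose expected asynchrony is known
  in closed form — so recovery, null calibration and confounding are
  all testable.

## Worked example

The `analysis/` scripts run the pipeline end to end on a simulated
60-species, 40-year community (run them in order from the repository
root; outputs land in `results/`):

```sh
Rscript analysis/01_simulate.R      # tree, traits, abundance panel
Rscript analysis/02_asynchrony.R    # interannual changes -> M
Rscript analysis/03_distances.R     # Gower + patristic matrices
Rscript analysis/04_mantel.R        # simple + partial Mantel tables
Rscript analysis/05_series_length.R # effect of series length
```

The same analysis in R:

```r
library(asyntraits)

ds  <- simulate_dataset(sim_config(n_species = 60, n_years = 40,
                                   beta = 0.8, seed = 20260901))
asy <- asynchrony_matrix(interannual_change(ds$panel), min_overlap = 5)
sp  <- rownames(asy$M)
D   <- combined_trait_distance(ds$traits$values[sp, ], ds$traits$meta)
P   <- patristic_matrix(ds$tree)[sp, sp]

mantel_test(asy$M, D, n_perm = 10000, n_boot = 10000, seed = 20260904)
partial_mantel(asy$M, D, P, n_perm = 10000, n_boot = 10000, seed = 20260904)
```

On this simulated community the pipeline prints (from
`analysis/04_mantel.R`):

```
Combined traits: simple r = 0.168 (p = 0.0001), partial r = 0.121 —
trait dissimilarity is positively associated with asynchrony
```

Read: species pairs with more dissimilar trait profiles changed
abundance more asynchronously (r > 0, one-tailed p ≪ 0.05), and the
association survives conditioning on phylogenetic distance (partial r
still positive), as it should here — the generator made traits drive
the dynamics (β = 0.8). `analysis/05_series_length.R` shows r rising
and stabilizing as the series lengthens (r = 0.14 at 20 years → 0.17
at 40), because longer series estimate each pairwise correlation with
less noise.

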