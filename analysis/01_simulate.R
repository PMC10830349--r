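#!/usr/bin/env Rscript
# Generate the synthetic study system: a pure-birth phylogeny, traits
# evolved on it (binary Mk dimensions + Brownian continuous traits), and
# a trait-driven abundance panel with known expected asynchrony.
# Writes all inputs the downstream steps read, under results/.

library(asyntraits)
library(ape)

outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

cfg <- sim_config(n_species = 60, n_years = 40, beta = 0.8, seed = 20260901)
ds <- simulate_dataset(cfg)

write.csv(ds$panel, file.path(outdir, "panel.csv"), row.names = FALSE)
write.csv(data.frame(species = rownames(ds$traits$values), ds$traits$values,
                     check.names = FALSE),
          file.path(outdir, "traits.csv"), row.names = FALSE)
write.csv(ds$traits$meta, file.path(outdir, "trait_meta.csv"), row.names = FALSE)
write.tree(ds$tree, file.path(outdir, "tree.nwk"))
write_matrix(ds$truth$expected_asynchrony,
             file.path(outdir, "expected_asynchrony.csv"))

cat("Simulated", cfg$n_species, "species x", cfg$n_years, "years;",
    nrow(ds$panel), "observed (species, year) cells after",
    100 * cfg$missing_fraction, "% MCAR missingness.\n")
cat("Traits:", length(unique(ds$traits$meta$trait)), "traits over",
    ncol(ds$traits$values), "dimensions in",
    length(unique(ds$traits$meta$group)), "groups.\n")
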