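#!/usr/bin/env Rscript
# The headline analysis: simple and partial Mantel tests of abundance
# asynchrony against combined and per-trait dissimilarity, conditioning
# the partial tests on phylogenetic distance. Produces the per-trait
# results table (r, one-tailed p, bootstrap 95% CI).

library(asyntraits)

panel <- read_panel("results/panel.csv")
values <- as.matrix(read.csv("results/traits.csv", row.names = 1,
                             check.names = FALSE))
meta <- read.csv("results/trait_meta.csv", stringsAsFactors = FALSE)
tree <- parse_newick(path = "results/tree.nwk")

run <- run_analysis(panel, list(values = values, meta = meta), tree,
                    which_traits = c("H", "AS", "FMA", "V"),
                    n_perm = 10000, n_boot = 10000, seed = 20260904)

write.csv(run$results, "results/mantel_results.csv", row.names = FALSE)
print(run)

comb <- run$results[run$results$trait == "combined", ]
cat(sprintf("\nCombined traits: simple r = %.3f (p = %.2g), partial r = %.3f — %s\n",
            comb$r_obs[comb$test == "simple"],
            comb$p_one_tailed[comb$test == "simple"],
            comb$r_obs[comb$test == "partial"],
            if (comb$p_one_tailed[comb$test == "simple"] < 0.05)
              "trait dissimilarity is positively associated with asynchrony"
            else "no significant association in this run"))
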