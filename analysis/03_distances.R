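#!/usr/bin/env Rscript
# Trait dissimilarity (combined, equal group contribution) and patristic
# distance matrices for the simulated community.

library(asyntraits)

values <- as.matrix(read.csv("results/traits.csv", row.names = 1,
                             check.names = FALSE))
meta <- read.csv("results/trait_meta.csv", stringsAsFactors = FALSE)

w <- group_weights(meta)
cat("Per-trait weights (equal group contribution, group weight 1/6):\n")
print(signif(w, 3))

D <- combined_trait_distance(values, meta)
write_matrix(D, "results/trait_distance_combined.csv")
for (t in c("H", "AS", "FMA")) {
  Dt <- suppressWarnings(single_trait_distance(values, meta, t))
  write_matrix(Dt, file.path("results", paste0("trait_distance_", t, ".csv")))
}

tree <- parse_newick(path = "results/tree.nwk")
P <- patristic_matrix(tree)
write_matrix(P, "results/phylo_distance.csv")

cat(sprintf("Combined trait distances span [%.3f, %.3f]; patristic span [%.2f, %.2f].\n",
            min(D[lower.tri(D)], na.rm = TRUE), max(D[lower.tri(D)], na.rm = TRUE),
            min(P[lower.tri(P)]), max(P[lower.tri(P)])))
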