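test_that("binary trait distance is mean mismatch rescaled to span [0,1]", {
  toy <- toy_traits()
  D <- single_trait_distance(toy$values, toy$meta, "H")
  # a vs b and a vs c mismatch on 2/8 dims (raw 0.25), b vs c identical;
  # the observed maximum raw distance is 0.25, so rescaled to 1
  expect_equal(D["a", "b"], 1)
  expect_equal(D["a", "c"], 1)
  expect_equal(D["b", "c"], 0)
  expect_equal(diag(D), setNames(rep(0, 3), rownames(toy$values)))
})

test_that("continuous trait distance is range-normalized absolute difference", {
  toy <- toy_traits()
  D <- single_trait_distance(toy$values, toy$meta, "FMA")
  # forewings 10, 15, 20 mm: range 10
  expect_equal(D["a", "c"], 1)
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["b", "c"], 0.5)
})

test_that("zero-range continuous traits give zero distances with a warning", {
  toy <- toy_traits()
  toy$values[, "FMA"] <- 12
  expect_warning(D <- single_trait_distance(toy$values, toy$meta, "FMA"),
                 "zero range")
  expect_true(all(D == 0))
})

test_that("unknown traits and malformed tables are rejected", {
  toy <- toy_traits()
  expect_error(single_trait_distance(toy$values, toy$meta, "nope"), "unknown trait")
  bad <- toy$values; bad[1, 1] <- 2
  expect_error(check_traits(bad, toy$meta), "binary")
  allna <- toy$values; allna["a", ] <- NA
  expect_error(check_traits(allna, toy$meta), "all trait dimensions missing")
})

test_that("group weights implement the equal-group-contribution scheme", {
  spec <- default_trait_spec()
  w <- group_weights(spec)
  expect_equal(signif(w[["H"]], 3), 0.167)    # habitat: single-trait group
  expect_equal(signif(w[["PH"]], 3), 0.167)   # nesting: single-trait group
  expect_equal(signif(w[["FMI"]], 3), 0.0556) # body size: 3 traits
  expect_equal(signif(w[["ES"]], 3), 0.0278)  # phenology: 6 traits
  expect_equal(signif(w[["HC"]], 3), 0.0556)  # diet: 3 traits
  # every group's weights sum to the group weight
  by_group <- tapply(w[spec$trait], spec$group, sum)
  expect_true(all(abs(by_group - 1 / 6) < 1e-12))
})

test_that("combined distance is the weight-renormalized mean of single traits", {
  toy <- toy_traits()
  toy$values[, "FMA"] <- c(15, 10, 20)  # b-c spans the range: distance 1
  # pair (b, c): single distances (H = 0, FMA = 1) with weights
  # (0.167, 0.0278) combine to 0.0278 / 0.1948
  w <- c(H = 0.167, FMA = 0.0278)
  D <- combined_trait_distance(toy$values, toy$meta, weights = w)
  expect_equal(D["b", "c"], 0.0278 / (0.167 + 0.0278), tolerance = 1e-12)
  # all-zero and all-one single distances are weight-independent
  Dh <- single_trait_distance(toy$values, toy$meta, "H")
  Df <- single_trait_distance(toy$values, toy$meta, "FMA")
  expect_equal(D["a", "c"],
               (w[["H"]] * Dh["a", "c"] + w[["FMA"]] * Df["a", "c"]) / sum(w))
})

test_that("combined distance is a convex combination of single-trait distances", {
  set.seed(501)
  tree <- simulate_tree(12, seed = 77)
  traits <- simulate_traits(tree, default_trait_spec(), seed = 78)
  singles <- lapply(unique(traits$meta$trait), function(t)
    suppressWarnings(single_trait_distance(traits$values, traits$meta, t)))
  D <- combined_trait_distance(traits$values, traits$meta)
  lo <- Reduce(pmin, singles); hi <- Reduce(pmax, singles)
  lt <- lower.tri(D)
  expect_true(all(D[lt] >= lo[lt] - 1e-12 & D[lt] <= hi[lt] + 1e-12))
  expect_true(all(D[lt] >= 0 & D[lt] <= 1))
})

test_that("package Gower matches the double-loop oracle, with missing data", {
  set.seed(502)
  for (rep_i in 1:3) {
    tree <- simulate_tree(10, seed = 600 + rep_i)
    traits <- simulate_traits(tree, default_trait_spec(), seed = 700 + rep_i)
    vals <- traits$values
    vals[sample(length(vals), floor(0.1 * length(vals)))] <- NA
    vals <- vals[rowSums(!is.na(vals)) > 0, , drop = FALSE]
    w <- group_weights(traits$meta)
    for (t in c("H", "FMA", "AS")) {
      expect_equal(suppressWarnings(single_trait_distance(vals, traits$meta, t)),
                   oracle_gower_single(vals, traits$meta, t),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_equal(suppressWarnings(combined_trait_distance(vals, traits$meta, w)),
                 oracle_gower_combined(vals, traits$meta, w),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("groups contribute comparably to the combined matrix on balanced tables", {
  # five structurally identical groups (one 6-dimension binary trait each):
  # the correlation between each group's own distance matrix and the
  # combined matrix should be nearly equal across groups
  spec <- data.frame(trait = paste0("T", 1:5), group = paste0("g", 1:5),
                     type = "binary", n_dim = 6L, rate = 1,
                     stringsAsFactors = FALSE)
  tree <- simulate_tree(50, seed = 81)
  for (s in c(82, 182)) {
    traits <- simulate_traits(tree, spec, seed = s)
    D <- combined_trait_distance(traits$values, traits$meta)
    sds <- vapply(spec$trait, function(t) {
      Dt <- single_trait_distance(traits$values, traits$meta, t)
      sd(Dt[lower.tri(Dt)])
    }, numeric(1))
    # premise: the per-group distances are comparably dispersed
    expect_lt(max(sds) / min(sds), 1.15)
    contrib <- vapply(spec$trait, function(t) {
      Dt <- single_trait_distance(traits$values, traits$meta, t)
      cor(Dt[lower.tri(Dt)], D[lower.tri(D)])
    }, numeric(1))
    expect_lt(diff(range(contrib)), 0.1)
  }
})
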