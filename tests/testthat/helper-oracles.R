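# Independent brute-force oracles used across the suite. Each is written
# as a literal transcription of the definition, with explicit loops, so
# that agreement with the vectorized package code is a genuine two-route
# check.

# Asynchrony oracle: for every species pair, Pearson correlation of
# interannual changes over shared intervals, M = (1 - K)/2; undefined
# below min_overlap or at zero variance.
oracle_asynchrony <- function(changes, min_overlap = 5L) {
  species <- sort(unique(changes$species))
  n <- length(species)
  M <- matrix(NA_real_, n, n, dimnames = list(species, species))
  diag(M) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      di <- changes[changes$species == species[i], ]
      dj <- changes[changes$species == species[j], ]
      shared <- intersect(di$year, dj$year)
      if (length(shared) < min_overlap) next
      xi <- di$delta[match(shared, di$year)]
      xj <- dj$delta[match(shared, dj$year)]
      if (sd(xi) == 0 || sd(xj) == 0) next
      M[i, j] <- M[j, i] <- (1 - cor(xi, xj)) / 2
    }
  }
  M
}

# Gower oracle: double loop over species pairs and trait list, following
# the definition dimension by dimension.
oracle_gower_single <- function(values, meta, trait_id) {
  dims <- meta$dimension[meta$trait == trait_id]
  type <- unique(meta$type[meta$trait == trait_id])
  n <- nrow(values)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(values), rownames(values)))
  diag(D) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ds <- numeric(0)
      for (d in dims) {
        xi <- values[i, d]; xj <- values[j, d]
        if (is.na(xi) || is.na(xj)) next
        if (type == "continuous") {
          rng <- diff(range(values[, d], na.rm = TRUE))
          ds <- c(ds, if (rng == 0) 0 else abs(xi - xj) / rng)
        } else {
          ds <- c(ds, abs(xi - xj))
        }
      }
      if (length(ds)) D[i, j] <- D[j, i] <- mean(ds)
    }
  }
  if (type == "binary") {
    dmax <- suppressWarnings(max(D[upper.tri(D)], na.rm = TRUE))
    if (is.finite(dmax) && dmax > 0) {
      D <- D / dmax
      diag(D) <- 0
    }
  }
  D
}

oracle_gower_combined <- function(values, meta, weights) {
  trait_ids <- unique(meta$trait)
  n <- nrow(values)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(values), rownames(values)))
  diag(D) <- 0
  singles <- lapply(trait_ids, function(t) oracle_gower_single(values, meta, t))
  names(singles) <- trait_ids
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (t in trait_ids) {
        dt <- singles[[t]][i, j]
        if (!is.na(dt)) {
          num <- num + weights[[t]] * dt
          den <- den + weights[[t]]
        }
      }
      if (den > 0) D[i, j] <- D[j, i] <- num / den
    }
  }
  D
}

# Patristic oracle: all-pairs shortest paths on the weighted tree graph.
oracle_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  tips <- as.character(seq_along(tree$tip.label))
  D <- igraph::distances(g, v = tips, to = tips)
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# Exact Mantel oracle, independent of the package's enumeration: builds
# permutations by filtering expand.grid and recomputes r with cor() on
# fully permuted matrices.
oracle_exact_mantel <- function(A, B) {
  n <- nrow(A)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1, function(p) length(unique(p)) == n), , drop = FALSE]
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  r_all <- apply(perms, 1, function(p) {
    Bp <- B[p, p]
    cor(A[lt], Bp[lt])
  })
  sum(r_all >= r_obs - 1e-12) / nrow(perms)
}

# Random Euclidean distance matrix from iid points, labelled.
random_dist <- function(n, dim = 2, labels = sprintf("sp%03d", seq_len(n))) {
  pts <- matrix(runif(n * dim), n, dim)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(labels, labels)
  D
}

# Toy 3-species trait fixture used by several Gower tests.
toy_traits <- function() {
  values <- rbind(
    a = c(1, 0, 0, 0, 0, 0, 0, 0, 10),
    b = c(0, 1, 0, 0, 0, 0, 0, 0, 15),
    c = c(0, 1, 0, 0, 0, 0, 0, 0, 20)
  )
  colnames(values) <- c(paste0("H_", 1:8), "FMA")
  meta <- data.frame(
    dimension = colnames(values),
    trait = c(rep("H", 8), "FMA"),
    group = c(rep("habitat", 8), "body_size"),
    type = c(rep("binary", 8), "continuous"),
    stringsAsFactors = FALSE
  )
  list(values = values, meta = meta)
}

# Panel whose interannual changes equal the given per-species delta
# vectors (years consecutive from 2001).
panel_from_deltas <- function(deltas) {
  rows <- lapply(names(deltas), function(s) {
    idx <- cumsum(c(2, deltas[[s]]))
    data.frame(species = s, year = seq(2001, by = 1, length.out = length(idx)),
               index = idx, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
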