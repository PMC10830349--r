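#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree with `n_species` tips, labelled
#' `sp001 ... spNNN`, standing in for an empirical phylogeny so that
#' traits evolved on it carry phylogenetic signal.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate (> 0), default 1 per unit time.
#' @param seed integer seed.
#' @return an [ape::phylo] ultrametric tree.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop("`n_species` must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("`birth_rate` must be > 0", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Default trait specification
#'
#' One row per trait: trait id, group, type, number of dimensions and
#' evolution rate. The default mirrors the structure of a mixed
#' insect-trait table: five groups (nesting, body size, phenology, diet,
#' habitat); categorical traits dummy-coded over several binary
#' dimensions (e.g. 12 monthly presence dimensions for each life-stage
#' phenology trait, 8 habitat classes), continuous traits (forewing
#' lengths, dry mass, hostplant number) as single dimensions.
#'
#' @param rate_binary Mk transition rate for binary dimensions.
#' @param rate_continuous Brownian-motion rate (variance per unit branch
#'   length) for continuous traits.
#' @return data.frame with columns `trait`, `group`, `type`, `n_dim`,
#'   `rate`.
#' @export
default_trait_spec <- function(rate_binary = 0.3, rate_continuous = 1) {
  spec <- data.frame(
    trait = c("PH", "FMI", "FMA", "EDM", "V", "ES", "PS", "LS", "AS", "OS",
              "HN", "HS", "HC", "H"),
    group = c("nesting", "body_size", "body_size", "body_size",
              "phenology", "phenology", "phenology", "phenology", "phenology",
              "phenology", "diet", "diet", "diet", "habitat"),
    type = c("binary", "continuous", "continuous", "continuous",
             "binary", "binary", "binary", "binary", "binary", "binary",
             "continuous", "binary", "binary", "binary"),
    n_dim = c(8L, 1L, 1L, 1L, 3L, 12L, 12L, 12L, 12L, 4L, 1L, 4L, 18L, 8L),
    stringsAsFactors = FALSE
  )
  spec$rate <- ifelse(spec$type == "binary", rate_binary, rate_continuous)
  spec
}

#' Simulation configuration
#'
#' Bundles the parameters of the trait-driven abundance simulation.
#' Year-to-year changes are driven by `n_drivers` shared standard-normal
#' environmental drivers with species loadings
#' `w_i = beta * g(traits_i) + (1 - beta) * u_i` (`g` the deterministic
#' trait-to-loading map, `u_i` iid standard-normal idiosyncratic
#' loadings), plus independent Gaussian noise with sd `noise_sd`.
#'
#' @param n_species,n_years,n_drivers simulation sizes (>= 3, >= 3, >= 1).
#' @param beta trait effect size in [0, 1]: 0 = loadings independent of
#'   traits, 1 = fully trait-determined.
#' @param noise_sd sd of the species-specific annual noise (> 0).
#' @param birth_rate tree speciation rate.
#' @param trait_spec trait specification ([default_trait_spec()]).
#' @param missing_fraction fraction of (species, year) cells set missing
#'   completely at random, in [0, 1).
#' @param seed root seed; per-stage sub-seeds are derived from it.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 60L, n_years = 40L, n_drivers = 3L,
                       beta = 0.8, noise_sd = 0.5, birth_rate = 1,
                       trait_spec = default_trait_spec(),
                       missing_fraction = 0.05, seed = 1L) {
  if (n_species < 3) stop("`n_species` must be >= 3", call. = FALSE)
  if (n_years < 3) stop("`n_years` must be >= 3", call. = FALSE)
  if (n_drivers < 1) stop("`n_drivers` must be >= 1", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species), n_years = as.integer(n_years),
                 n_drivers = as.integer(n_drivers), beta = beta,
                 noise_sd = noise_sd, birth_rate = birth_rate,
                 trait_spec = trait_spec,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve traits on a phylogeny
#'
#' Continuous traits evolve by Brownian motion (variance `rate` per unit
#' branch length); each binary dimension evolves independently under a
#' symmetric 2-state Mk model with transition rate `rate`, started from
#' a random root state. Closely related tips are therefore more similar
#' in expectation — the phylogenetic signal the downstream analysis
#' assumes.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param trait_spec data.frame as from [default_trait_spec()].
#' @param seed integer seed.
#' @return list with `values` (species x dimension numeric matrix) and
#'   `meta` (dimension, trait, group, type) suitable for the Gower
#'   functions.
#' @export
simulate_traits <- function(tree, trait_spec = default_trait_spec(), seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!nrow(trait_spec)) stop("`trait_spec` is empty", call. = FALSE)
  bad <- setdiff(trait_spec$type, c("binary", "continuous"))
  if (length(bad)) stop("unknown trait type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n <- length(tree$tip.label)
  with_seed(seed, {
    cols <- list(); meta <- list()
    for (i in seq_len(nrow(trait_spec))) {
      tr <- trait_spec[i, ]
      for (d in seq_len(tr$n_dim)) {
        dim_id <- if (tr$n_dim == 1L) tr$trait else paste0(tr$trait, "_", d)
        if (tr$type == "continuous") {
          v <- if (tr$rate == 0) rep(0, n) else
            ape::rTraitCont(tree, model = "BM", sigma = sqrt(tr$rate))
        } else {
          if (tr$rate == 0) {
            v <- rep(stats::rbinom(1, 1, 0.5), n)
          } else {
            root <- sample(c("0", "1"), 1)
            v <- as.numeric(as.character(
              ape::rTraitDisc(tree, model = "ER", rate = tr$rate, k = 2,
                              states = c("0", "1"), root.value = match(root, c("0", "1")))))
          }
        }
        cols[[dim_id]] <- unname(v)
        meta[[dim_id]] <- data.frame(dimension = dim_id, trait = tr$trait,
                                     group = tr$group, type = tr$type,
                                     stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- tree$tip.label
    list(values = values, meta = do.call(rbind, c(meta, make.row.names = FALSE)))
  })
}

# Deterministic trait-to-loading map g: dimension k is assigned to driver
# ((k - 1) mod n_drivers) + 1; continuous dimensions enter z-scored,
# binary dimensions as +/-1; each driver column is then z-scored across
# species so trait-similar species get similar loadings at a common scale.
trait_loading_map <- function(values, meta, n_drivers) {
  n <- nrow(values)
  G <- matrix(0, n, n_drivers)
  dims <- colnames(values)
  for (k in seq_along(dims)) {
    v <- values[, k]
    type <- meta$type[match(dims[k], meta$dimension)]
    v[is.na(v)] <- mean(v, na.rm = TRUE)  # neutral fill for the map only
    contrib <- if (type == "continuous") {
      if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, n)
    } else {
      2 * v - 1
    }
    d <- ((k - 1L) %% n_drivers) + 1L
    G[, d] <- G[, d] + contrib
  }
  for (d in seq_len(n_drivers)) {
    if (stats::sd(G[, d]) > 0) G[, d] <- (G[, d] - mean(G[, d])) / stats::sd(G[, d])
  }
  rownames(G) <- rownames(values)
  G
}

#' Analytically expected asynchrony from known loadings
#'
#' With interannual change `delta_i,t = sum_d w_i,d e_t,d + eps_i,t`,
#' shared drivers `e ~ N(0, 1)` and noise `eps ~ N(0, sigma^2)`, the
#' population correlation of two species' changes is
#' `corr_ij = (w_i . w_j) / sqrt((|w_i|^2 + sigma^2)(|w_j|^2 + sigma^2))`
#' and the expected asynchrony is `M = (1 - corr) / 2`. This closed form
#' is the oracle that empirical asynchrony must converge to as the
#' series lengthens.
#'
#' @param loadings species x driver loading matrix `w`.
#' @param noise_sd noise sd `sigma` (> 0).
#' @return symmetric matrix in [0, 1] with zero diagonal.
#' @export
expected_asynchrony <- function(loadings, noise_sd) {
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  w <- as.matrix(loadings)
  cross <- tcrossprod(w)
  pow <- diag(cross) + noise_sd^2
  corr <- cross / sqrt(outer(pow, pow))
  M <- (1 - corr) / 2
  diag(M) <- 0
  dimnames(M) <- list(rownames(w), rownames(w))
  M
}

#' Simulate a trait-driven abundance panel
#'
#' Each year-to-year change is a species-specific linear combination of
#' shared environmental drivers plus independent Gaussian noise; the
#' collated log-scale index is the cumulative sum of changes from a
#' species baseline. A `missing_fraction` of (species, year) cells is
#' removed completely at random.
#'
#' @param traits trait list from [simulate_traits()] (`values` + `meta`).
#' @param cfg a [sim_config()].
#' @return list with `panel` (an `abundance_panel`) and `truth` (list:
#'   `loadings`, `expected_asynchrony`, `drivers`).
#' @export
simulate_abundance <- function(traits, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  values <- traits$values
  n <- nrow(values); ny <- cfg$n_years; nd <- cfg$n_drivers
  G <- trait_loading_map(values, traits$meta, nd)
  W <- with_seed(stage_seed(cfg$seed, "abundance"), {
    U <- matrix(stats::rnorm(n * nd), n, nd)
    W <- cfg$beta * G + (1 - cfg$beta) * U
    rownames(W) <- rownames(values)
    E <- matrix(stats::rnorm((ny - 1) * nd), ny - 1, nd)
    eps <- matrix(stats::rnorm(n * (ny - 1), sd = cfg$noise_sd), n, ny - 1)
    delta <- W %*% t(E) + eps                 # species x intervals
    baseline <- stats::rnorm(n, mean = 2, sd = 0.5)
    idx_mat <- cbind(baseline, baseline + t(apply(delta, 1, cumsum)))
    list(W = W, idx = idx_mat)
  })
  idx_mat <- W$idx; loadings <- W$W
  years <- seq_len(ny) + 2000L  # calendar-style years
  panel <- data.frame(species = rep(rownames(values), times = ny),
                      year = rep(years, each = n),
                      index = as.vector(idx_mat),
                      stringsAsFactors = FALSE)
  if (cfg$missing_fraction > 0) {
    panel <- with_seed(stage_seed(cfg$seed, "missing"), {
      drop <- sample.int(nrow(panel), floor(cfg$missing_fraction * nrow(panel)))
      if (length(drop)) panel$index[drop] <- NA_real_
      panel
    })
  }
  panel <- panel[!is.na(panel$index), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("abundance_panel", "data.frame")
  list(panel = panel,
       truth = list(loadings = loadings,
                    expected_asynchrony = expected_asynchrony(loadings, cfg$noise_sd)))
}

#' Simulate a complete synthetic dataset
#'
#' Tree, traits evolved on it, and a trait-driven abundance panel, with
#' the ground truth needed to test parameter recovery. Stages draw from
#' sub-seeds derived from `cfg$seed`, so each stage is independently
#' reproducible.
#'
#' @param cfg a [sim_config()].
#' @return list: `tree`, `traits` (values + meta), `panel`, `truth`
#'   (loadings, expected_asynchrony), `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  tree <- simulate_tree(cfg$n_species, cfg$birth_rate,
                        seed = stage_seed(cfg$seed, "tree"))
  traits <- simulate_traits(tree, cfg$trait_spec,
                            seed = stage_seed(cfg$seed, "traits"))
  ab <- simulate_abundance(traits, cfg)
  list(tree = tree, traits = traits, panel = ab$panel, truth = ab$truth,
       cfg = cfg)
}

#' Simulate a phylogeny-confounded dataset
#'
#' Abundance dynamics are driven solely by *hidden* traits evolved by
#' Brownian motion on the tree (one per environmental driver); the
#' measured traits are independent Brownian traits on the same tree and
#' have no causal effect on abundance. Any simple Mantel association
#' between measured-trait distance and asynchrony is then pure
#' phylogenetic confounding, and the partial Mantel test conditioning on
#' patristic distance should attenuate it toward zero.
#'
#' @param n_species,n_years,noise_sd,birth_rate simulation parameters.
#' @param n_hidden number of hidden driver traits (= number of drivers).
#' @param n_neutral number of measured (neutral) continuous traits.
#' @param seed root seed.
#' @return list: `tree`, `traits`, `panel`, `truth` (as in
#'   [simulate_dataset()], loadings from the hidden traits).
#' @export
simulate_confounded_dataset <- function(n_species = 40L, n_years = 200L,
                                        noise_sd = 0.3, birth_rate = 1,
                                        n_hidden = 4L, n_neutral = 6L,
                                        seed = 1L) {
  tree <- simulate_tree(n_species, birth_rate, seed = stage_seed(seed, "tree"))
  hidden <- with_seed(stage_seed(seed, "traits"),
                      vapply(seq_len(n_hidden),
                             function(i) ape::rTraitCont(tree, model = "BM", sigma = 1),
                             numeric(n_species)))
  spec <- data.frame(trait = paste0("N", seq_len(n_neutral)),
                     group = paste0("g", seq_len(n_neutral)),
                     type = "continuous", n_dim = 1L, rate = 1,
                     stringsAsFactors = FALSE)
  traits <- simulate_traits(tree, spec, seed = stage_seed(seed, "missing"))
  cfg <- sim_config(n_species = n_species, n_years = n_years,
                    n_drivers = as.integer(n_hidden),
                    beta = 1, noise_sd = noise_sd, birth_rate = birth_rate,
                    trait_spec = spec, missing_fraction = 0, seed = seed)
  # reuse the abundance machinery with loadings fixed to the hidden traits
  hidden_names <- paste0("hidden", seq_len(n_hidden))
  dimnames(hidden) <- list(tree$tip.label, hidden_names)
  fake_traits <- list(values = hidden,
                      meta = data.frame(dimension = hidden_names,
                                        trait = hidden_names,
                                        group = "hidden", type = "continuous",
                                        stringsAsFactors = FALSE))
  ab <- simulate_abundance(fake_traits, cfg)
  list(tree = tree, traits = traits, panel = ab$panel, truth = ab$truth,
       cfg = cfg)
}
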