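#' Align species across abundance, trait and phylogeny inputs
#'
#' Only species present in all supplied sources enter the pairwise
#' distance matrices. Dropped species are reported per source.
#'
#' @param panel an `abundance_panel`.
#' @param traits trait list (`values` + `meta`) or species x dimension
#'   matrix with row names.
#' @param phylo optional phylogenetic source: an [ape::phylo] tree or a
#'   character vector of species covered by the phylogenetic distance
#'   matrix (after any species-complex collapsing); `NULL` to skip.
#' @return list: `species` (common ordering, sorted), `dropped` (named
#'   list per source).
#' @export
align_species <- function(panel, traits, phylo = NULL) {
  sp_panel <- unique(panel$species)
  values <- if (is.list(traits) && !is.data.frame(traits)) traits$values else traits
  sp_traits <- rownames(values)
  sets <- list(abundance = sp_panel, traits = sp_traits)
  if (!is.null(phylo)) {
    sets$phylogeny <- if (inherits(phylo, "phylo")) phylo$tip.label else phylo
  }
  common <- Reduce(intersect, sets)
  if (length(common) < 3) {
    cov <- vapply(sets, length, 1L)
    stop("fewer than 3 species shared across sources (",
         paste(names(cov), cov, sep = ": ", collapse = ", "),
         "; intersection: ", length(common), ")", call. = FALSE)
  }
  common <- sort(common)
  dropped <- lapply(sets, function(s) setdiff(s, common))
  list(species = common, dropped = dropped)
}

#' Run the full trait-asynchrony analysis
#'
#' End-to-end pipeline: align species across sources; build the
#' asynchrony matrix from interannual changes; build the combined and
#' per-trait Gower distance matrices; build the patristic matrix when a
#' tree is supplied (collapsing any species complexes); then run a
#' simple Mantel test (asynchrony ~ trait distance) and, with a tree, a
#' partial Mantel test conditioning on phylogenetic distance, for the
#' combined matrix and each requested trait. Two extra rows test
#' phylogenetic distance itself against asynchrony and against combined
#' trait distance.
#'
#' @param panel an `abundance_panel` (long: species, year, index).
#' @param traits trait list with `values` and `meta`.
#' @param tree optional [ape::phylo] tree; `NULL` skips all
#'   phylogeny-dependent rows.
#' @param complexes optional list of `list(label =, members =)` species
#'   complexes collapsed in the patristic matrix.
#' @param which_traits character vector of trait ids, or `"all"`.
#' @param min_overlap minimum shared intervals per species pair.
#' @param n_perm,n_boot,frac Mantel permutation / bootstrap settings.
#' @param group_weight per-group weight for the combined distance.
#' @param seed integer seed (permutations and bootstrap).
#' @return list of class `"asyntraits_run"`: `results` (data.frame with
#'   columns label, trait, test, r_obs, p_one_tailed, ci_low, ci_high,
#'   n_species, n_perm, n_boot, seed), `matrices` (asynchrony, combined,
#'   per-trait, phylogeny), `species`, `dropped`.
#' @export
run_analysis <- function(panel, traits, tree = NULL, complexes = NULL,
                         which_traits = "all", min_overlap = 5L,
                         n_perm = 10000L, n_boot = 10000L, frac = 0.9,
                         group_weight = 1 / 6, seed = 1L) {
  P <- NULL
  if (!is.null(tree)) {
    # collapse complexes before alignment so their labels count as
    # phylogenetic coverage
    P <- patristic_matrix(tree)
    for (cx in complexes) P <- collapse_complex(P, cx$members, cx$label)
  }
  al <- align_species(panel, traits, if (is.null(P)) NULL else rownames(P))
  sp <- al$species
  panel <- panel[panel$species %in% sp, , drop = FALSE]
  meta <- traits$meta

  asy <- asynchrony_matrix(interannual_change(panel), min_overlap = min_overlap)
  sp <- intersect(sp, rownames(asy$M))  # species can drop out with < 2 usable years
  if (length(sp) < 3) stop("fewer than 3 species with usable change series",
                           call. = FALSE)
  M <- asy$M[sp, sp]
  values <- traits$values[sp, , drop = FALSE]
  if (!is.null(P)) P <- P[sp, sp]

  trait_ids <- unique(meta$trait[meta$dimension %in% colnames(values)])
  if (!identical(which_traits, "all")) {
    missing_tr <- setdiff(which_traits, trait_ids)
    if (length(missing_tr)) stop("unknown trait(s): ",
                                 paste(missing_tr, collapse = ", "), call. = FALSE)
    trait_ids <- which_traits
  }

  D_list <- list(combined = combined_trait_distance(values, meta,
                                                    group_weight = group_weight))
  for (t in trait_ids) {
    D_list[[t]] <- suppressWarnings(single_trait_distance(values, meta, t))
  }

  rows <- list()
  add_row <- function(label, test, fit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      trait = label, test = test, r_obs = fit$r_obs,
      p_one_tailed = fit$p_one_tailed, ci_low = fit$ci_low,
      ci_high = fit$ci_high, n_species = fit$n_species,
      n_perm = fit$n_perm, n_boot = fit$n_boot, stringsAsFactors = FALSE)
  }
  for (nm in names(D_list)) {
    fit <- mantel_test(M, D_list[[nm]], n_perm = n_perm, n_boot = n_boot,
                       frac = frac, seed = seed)
    add_row(nm, "simple", fit)
    if (!is.null(P)) {
      pfit <- partial_mantel(M, D_list[[nm]], P, n_perm = n_perm,
                             n_boot = n_boot, frac = frac, seed = seed)
      add_row(nm, "partial", pfit)
    }
  }
  if (!is.null(P)) {
    add_row("phylogeny_vs_asynchrony", "simple",
            mantel_test(M, P, n_perm = n_perm, n_boot = n_boot, frac = frac,
                        seed = seed))
    add_row("phylogeny_vs_traits", "simple",
            mantel_test(D_list$combined, P, n_perm = n_perm, n_boot = n_boot,
                        frac = frac, seed = seed))
  }
  results <- do.call(rbind, rows)
  results$seed <- as.integer(seed)
  structure(list(results = results,
                 matrices = c(list(asynchrony = M, phylogeny = P), D_list),
                 species = sp, dropped = al$dropped),
            class = "asyntraits_run")
}

#' @export
print.asyntraits_run <- function(x, ...) {
  cat("Trait-asynchrony analysis over", length(x$species), "species\n")
  print(x$results[c("trait", "test", "r_obs", "p_one_tailed")], digits = 3)
  invisible(x)
}

#' Effect of time-series length on the trait-asynchrony correlation
#'
#' Truncates the abundance panel to its first `length` years for each
#' requested length and reruns the combined-trait simple Mantel test,
#' returning the correlation and whether it is significant at
#' `alpha`. Longer series estimate each pairwise correlation with less
#' noise, so under trait-driven dynamics the mean r is expected to rise
#' with series length.
#'
#' @param panel,traits,tree,min_overlap,n_perm,seed as in
#'   [run_analysis()].
#' @param lengths integer vector of series lengths (years, each >= 5).
#' @param alpha significance level for the rejection indicator.
#' @return data.frame: `length`, `r_obs`, `p_one_tailed`, `reject`.
#' @export
experiment_series_length <- function(panel, traits, lengths, tree = NULL,
                                     min_overlap = 5L, n_perm = 999L,
                                     alpha = 0.05, seed = 1L) {
  if (any(lengths < 5)) stop("series lengths must be >= 5", call. = FALSE)
  years <- sort(unique(panel$year))
  out <- lapply(lengths, function(L) {
    keep <- years[seq_len(min(L, length(years)))]
    sub <- panel[panel$year %in% keep, , drop = FALSE]
    run <- run_analysis(sub, traits, tree = tree,
                        min_overlap = min_overlap, n_perm = n_perm,
                        n_boot = 0L, seed = seed)
    r <- run$results[run$results$trait == "combined" &
                       run$results$test == "simple", ]
    data.frame(length = L, r_obs = r$r_obs, p_one_tailed = r$p_one_tailed,
               reject = r$p_one_tailed < alpha)
  })
  do.call(rbind, out)
}
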