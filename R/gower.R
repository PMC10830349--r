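#' Validate a species-by-dimension trait table against its metadata
#'
#' Traits are stored as a numeric matrix/data.frame with species as row
#' names and one column per trait *dimension* (a continuous trait has one
#' dimension; a categorical trait is dummy-coded over several binary
#' dimensions, value 1 when the species shows that category). The
#' companion metadata table maps each dimension to its trait, trait group
#' and type.
#'
#' @param traits numeric matrix or data.frame, species x dimensions.
#' @param meta data.frame with columns `dimension`, `trait`, `group`,
#'   `type` (`"binary"` or `"continuous"`).
#' @return the trait table as a numeric matrix (invisibly checked).
#' @export
check_traits <- function(traits, meta) {
  m <- as.matrix(traits)
  if (!is.numeric(m)) stop("trait table must be numeric", call. = FALSE)
  if (is.null(rownames(m))) stop("trait table needs species row names", call. = FALSE)
  need <- c("dimension", "trait", "group", "type")
  if (!all(need %in% names(meta))) {
    stop("trait metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(colnames(m) %in% meta$dimension)) {
    stop("dimensions missing from metadata: ",
         paste(setdiff(colnames(m), meta$dimension), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$dimension)) stop("duplicated dimension ids in metadata",
                                          call. = FALSE)
  if (!all(meta$type %in% c("binary", "continuous"))) {
    stop("unknown trait type(s): ",
         paste(setdiff(meta$type, c("binary", "continuous")), collapse = ", "),
         call. = FALSE)
  }
  bin_dims <- meta$dimension[meta$type == "binary"]
  bin_dims <- intersect(bin_dims, colnames(m))
  bad <- !(m[, bin_dims, drop = FALSE] %in% c(0, 1, NA))
  if (any(bad)) stop("binary dimensions must contain only 0, 1 or NA", call. = FALSE)
  all_missing <- rownames(m)[rowSums(!is.na(m)) == 0]
  if (length(all_missing)) {
    stop("species with all trait dimensions missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

#' Gower distance matrix for a single trait
#'
#' For a continuous (single-dimension) trait, the distance between two
#' species is `|x_i - x_j| / range(x)` with the range taken over the
#' species in the table. For a multi-dimension binary (dummy-coded) trait,
#' the raw distance is the mean absolute difference over mutually
#' non-missing dimensions, then rescaled by the maximum observed raw
#' distance so the trait spans [0, 1]. Pairs with no shared non-missing
#' dimension are undefined (`NA`).
#'
#' @inheritParams check_traits
#' @param trait_id trait name (a value of `meta$trait`).
#' @return symmetric numeric matrix in [0, 1], zero diagonal, `NA` where
#'   undefined, with a `"provenance"` attribute naming the trait.
#' @export
single_trait_distance <- function(traits, meta, trait_id) {
  m <- check_traits(traits, meta)
  dims <- meta$dimension[meta$trait == trait_id]
  dims <- intersect(dims, colnames(m))
  if (!length(dims)) stop("unknown trait: ", trait_id, call. = FALSE)
  type <- unique(meta$type[meta$trait == trait_id])
  x <- m[, dims, drop = FALSE]
  if (sum(rowSums(!is.na(x)) > 0) < 2) {
    stop("fewer than 2 species with data for trait ", trait_id, call. = FALSE)
  }
  n <- nrow(x)
  if (type == "continuous") {
    # range-scale each dimension on the analysis species set, then average
    d_sum <- matrix(0, n, n); d_cnt <- matrix(0L, n, n)
    for (k in seq_along(dims)) {
      v <- x[, k]
      rng <- diff(range(v, na.rm = TRUE))
      if (rng == 0) {
        warning("zero range for continuous trait ", trait_id,
                "; distances are 0", call. = FALSE)
        dk <- matrix(0, n, n)
        ok <- outer(!is.na(v), !is.na(v), `&`)
      } else {
        dk <- abs(outer(v, v, `-`)) / rng
        ok <- !is.na(dk)
        dk[!ok] <- 0
      }
      d_sum <- d_sum + dk
      d_cnt <- d_cnt + ok
    }
    D <- d_sum / d_cnt
    D[d_cnt == 0] <- NA_real_
  } else {
    # mean mismatch over mutually observed dims, rescaled to span [0,1]
    obs <- !is.na(x)
    x0 <- x; x0[!obs] <- 0
    shared <- tcrossprod(obs * 1)
    both1 <- tcrossprod(x0)              # shared dims where both are 1
    both0 <- tcrossprod((1 - x0) * obs)  # shared dims where both are 0
    mism <- shared - both1 - both0
    D <- mism / shared
    D[shared == 0] <- NA_real_
    dmax <- max(D[upper.tri(D)], na.rm = TRUE)
    if (is.finite(dmax) && dmax > 0) D <- D / dmax
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "provenance") <- trait_id
  D
}

#' Equal-group-contribution trait weights
#'
#' Each trait group receives a fixed `group_weight`, split equally among
#' its member traits, so every group contributes equally to the combined
#' dissimilarity: a single-trait group like habitat gets the full 0.167
#' (at the default 1/6), a 3-trait group 0.0556 per trait, a 6-trait
#' group 0.0278 per trait. The weight total need not be 1; the combined
#' distance renormalises by the sum of weights over defined traits.
#'
#' @param meta trait metadata (see [check_traits()]).
#' @param group_weight weight assigned to each group (default 1/6).
#' @return named numeric vector of per-trait weights.
#' @export
group_weights <- function(meta, group_weight = 1 / 6) {
  tr <- unique(meta[c("trait", "group")])
  if (anyDuplicated(tr$trait)) {
    stop("trait assigned to more than one group", call. = FALSE)
  }
  n_in_group <- table(tr$group)
  if (any(n_in_group == 0)) stop("empty trait group", call. = FALSE)
  w <- group_weight / as.numeric(n_in_group[tr$group])
  names(w) <- tr$trait
  w
}

#' Combined (multi-trait) Gower distance matrix
#'
#' Weighted mean of the single-trait distance matrices,
#' `D_ij = sum_t w_t d_t,ij / sum_t w_t`, where the sums run over traits
#' defined for the pair (i, j) — so missing traits shrink a pair's weight
#' total rather than its distance, and a non-unit weight total is
#' immaterial.
#'
#' @inheritParams check_traits
#' @param weights named per-trait weights; default [group_weights()] with
#'   `group_weight`.
#' @param group_weight passed to [group_weights()] when `weights` is NULL.
#' @return symmetric numeric matrix in [0, 1] with `"provenance"`
#'   attribute `"combined"`.
#' @export
combined_trait_distance <- function(traits, meta, weights = NULL,
                                    group_weight = 1 / 6) {
  m <- check_traits(traits, meta)
  if (is.null(weights)) weights <- group_weights(meta, group_weight)
  trait_ids <- unique(meta$trait[meta$dimension %in% colnames(m)])
  if (!all(trait_ids %in% names(weights))) {
    stop("weights missing for trait(s): ",
         paste(setdiff(trait_ids, names(weights)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(m)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (t in trait_ids) {
    Dt <- suppressWarnings(single_trait_distance(m, meta, t))
    ok <- !is.na(Dt)
    num[ok] <- num[ok] + weights[[t]] * Dt[ok]
    den[ok] <- den[ok] + weights[[t]]
  }
  D <- num / den
  D[den == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "provenance") <- "combined"
  D
}
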