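#' Vectorize a pair of aligned distance matrices
#'
#' Lower-triangle entries of two distance matrices over the same species
#' set, in identical pair order. `B` is reordered to `A`'s labels;
#' differing label sets are an error naming the difference. Entries
#' undefined (`NA`) in either matrix are excluded pairwise and the count
#' reported.
#'
#' @param A,B labelled square distance matrices over the same species.
#' @return list with `a`, `b` (equal-length numeric vectors),
#'   `n_excluded`, and `labels` (the common species ordering).
#' @export
vectorize_pair <- function(A, B) {
  check_square_matrix(A)
  B <- align_matrices(A, check_square_matrix(B), "A", "B")
  idx <- lower_pairs(nrow(A))
  a <- A[idx]; b <- B[idx]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 usable species pairs", call. = FALSE)
  list(a = a[ok], b = b[ok], n_excluded = sum(!ok), labels = rownames(A))
}

# Pearson r with a degeneracy check shared by all Mantel paths.
pearson_r <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate distance matrix: zero variance among pairwise entries",
         call. = FALSE)
  }
  stats::cor(a, b)
}

# First-order partial correlation r_AB.C with collinearity guard.
partial_r <- function(r_ab, r_ac, r_bc, guard = TRUE) {
  if (guard && (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)) {
    stop("collinear matrices: |r| = 1 with the conditioning matrix", call. = FALSE)
  }
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

# Null correlations of a (fixed) with B under n_perm joint row/column
# permutations of B. Fast path exploits that permuting a symmetric
# matrix's rows and columns only permutes its off-diagonal multiset, so
# mean and sd of the vectorized triangle are permutation-invariant.
perm_null_r <- function(a, B, n_perm) {
  n <- nrow(B)
  idx <- lower_pairs(n)
  b0 <- B[idx]
  if (anyNA(a) || anyNA(b0)) {  # slow path with pairwise exclusion
    r <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      b <- B[cbind(p[idx[, 1]], p[idx[, 2]])]
      ok <- !is.na(a) & !is.na(b)
      r[k] <- stats::cor(a[ok], b[ok])
    }
    return(r)
  }
  m <- length(a)
  a_c <- a - mean(a)
  den <- sqrt(sum(a_c^2)) * sqrt(sum((b0 - mean(b0))^2))
  mb_term <- m * mean(a_c) * mean(b0)  # zero by centering; kept for clarity
  ii <- idx[, 1]; jj <- idx[, 2]
  r <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    b <- B[cbind(p[ii], p[jj])]
    r[k] <- (sum(a_c * b) - mb_term) / den
  }
  r
}

#' Simple Mantel permutation test
#'
#' Pearson correlation between the vectorized lower triangles of two
#' distance matrices, with a permutation null built by jointly permuting
#' the rows and columns of `B` and a one-tailed p-value for H0: r <= 0,
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`. A bootstrap 95%
#' confidence interval is attached via [bootstrap_ci()] when
#' `n_boot > 0`.
#'
#' @param A,B labelled square distance matrices over the same species.
#' @param n_perm number of permutations (default 10000).
#' @param n_boot bootstrap repeats for the CI (default 10000; 0 skips it).
#' @param frac fraction of species kept in each bootstrap subsample.
#' @param seed integer seed for permutations and bootstrap.
#' @return object of class `"mantel_result"`: `r_obs`, `p_one_tailed`,
#'   `ci_low`, `ci_high`, `n_species`, `n_perm`, `n_boot`, `seed`.
#' @export
mantel_test <- function(A, B, n_perm = 10000L, n_boot = 10000L, frac = 0.9,
                        seed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  v <- vectorize_pair(A, B)
  r_obs <- pearson_r(v$a, v$b)
  B_al <- align_matrices(A, B)
  a_full <- A[lower_pairs(nrow(A))]  # unfiltered; perm_null_r masks NAs per draw
  res <- with_seed(seed, {
    r_null <- perm_null_r(a_full, B_al, n_perm)
    p <- (1 + sum(r_null >= r_obs - 1e-12, na.rm = TRUE)) / (n_perm + 1)
    ci <- if (n_boot > 0) {
      bootstrap_ci(A, B_al, n_boot = n_boot, frac = frac, seed = NULL)
    } else c(NA_real_, NA_real_)
    list(p = p, ci = ci)
  })
  structure(list(r_obs = r_obs, p_one_tailed = res$p,
                 ci_low = res$ci[[1]], ci_high = res$ci[[2]],
                 n_species = nrow(A), n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 method = "simple"),
            class = "mantel_result")
}

#' Exact Mantel test by full enumeration
#'
#' Enumerates all n! joint row/column permutations (identity included)
#' and returns the exact one-tailed p-value
#' `p = #\{pi : r_pi >= r_obs\} / n!`. Feasible only for small matrices;
#' refuses n > 8. Serves as the ground-truth oracle for the Monte-Carlo
#' permutation p of [mantel_test()].
#'
#' @inheritParams mantel_test
#' @return list with `r_obs`, `p_exact`, `n_perm_total`.
#' @export
exact_mantel <- function(A, B) {
  n <- nrow(check_square_matrix(A))
  if (n > 8) stop("exact enumeration refused for n > 8 (n! too large)",
                  call. = FALSE)
  B <- align_matrices(A, check_square_matrix(B))
  v <- vectorize_pair(A, B)
  r_obs <- pearson_r(v$a, v$b)
  idx <- lower_pairs(n)
  a <- A[idx]
  perms <- all_permutations(n)
  r_all <- vapply(perms, function(p) {
    b <- B[cbind(p[idx[, 1]], p[idx[, 2]])]
    stats::cor(a, b)
  }, numeric(1))
  list(r_obs = r_obs,
       p_exact = sum(r_all >= r_obs - 1e-12) / length(perms),
       n_perm_total = length(perms))
}

# All permutations of 1..n as a list (n <= 8 guard upstream).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Partial Mantel test
#'
#' First-order partial correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`
#' on vectorized lower triangles, testing the A-B association while
#' controlling for C (here: asynchrony ~ trait dissimilarity, controlling
#' phylogenetic distance). The null permutes `B`'s rows/columns jointly
#' and recomputes `r_AB` and `r_BC` (with `r_AC` fixed) before re-forming
#' the partial correlation (raw-matrix permutation, Smouse-Long-Sokal
#' style).
#'
#' @inheritParams mantel_test
#' @param C conditioning distance matrix.
#' @return object of class `"mantel_result"` (method `"partial"`).
#' @export
partial_mantel <- function(A, B, C, n_perm = 10000L, n_boot = 10000L,
                           frac = 0.9, seed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  check_square_matrix(A)
  B <- align_matrices(A, check_square_matrix(B), "A", "B")
  C <- align_matrices(A, check_square_matrix(C), "A", "C")
  n <- nrow(A)
  idx <- lower_pairs(n)
  a <- A[idx]; b <- B[idx]; cc <- C[idx]
  ok <- !is.na(a) & !is.na(b) & !is.na(cc)
  if (sum(ok) < 3) stop("fewer than 3 usable species pairs", call. = FALSE)
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]
  r_ab <- pearson_r(a, b); r_ac <- pearson_r(a, cc); r_bc <- pearson_r(b, cc)
  r_obs <- partial_r(r_ab, r_ac, r_bc)
  ii <- idx[ok, 1]; jj <- idx[ok, 2]
  res <- with_seed(seed, {
    r_null <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      bp <- B[cbind(p[ii], p[jj])]
      okp <- !is.na(bp)
      r_null[k] <- partial_r(stats::cor(a[okp], bp[okp]),
                             r_ac,
                             stats::cor(bp[okp], cc[okp]),
                             guard = FALSE)
    }
    p_val <- (1 + sum(r_null >= r_obs - 1e-12, na.rm = TRUE)) / (n_perm + 1)
    ci <- if (n_boot > 0) {
      bootstrap_ci(A, B, C = C, n_boot = n_boot, frac = frac, seed = NULL)
    } else c(NA_real_, NA_real_)
    list(p = p_val, ci = ci)
  })
  structure(list(r_obs = r_obs, p_one_tailed = res$p,
                 ci_low = res$ci[[1]], ci_high = res$ci[[2]],
                 n_species = n, n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 method = "partial"),
            class = "mantel_result")
}

#' Bootstrap confidence interval for a Mantel correlation
#'
#' Each repeat subsamples `ceiling(frac * n)` species without replacement
#' (with-replacement resampling would create artificial zero distances
#' between duplicated species), recomputes the (partial) Mantel r on the
#' induced submatrices, and the 2.5th and 97.5th percentiles of the
#' replicate correlations form the 95% interval. Degenerate repeats
#' (zero variance in a subsample) are discarded; more than 50% discarded
#' is an error.
#'
#' @inheritParams partial_mantel
#' @param C optional conditioning matrix: when supplied the partial
#'   correlation is bootstrapped.
#' @param n_boot number of repeats.
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(A, B, C = NULL, n_boot = 10000L, frac = 0.9,
                         seed = NULL) {
  if (frac <= 0 || frac > 1) stop("`frac` must be in (0, 1]", call. = FALSE)
  check_square_matrix(A)
  B <- align_matrices(A, check_square_matrix(B), "A", "B")
  if (!is.null(C)) C <- align_matrices(A, check_square_matrix(C), "A", "C")
  n <- nrow(A)
  k <- ceiling(frac * n)
  if (choose(k, 2) < 3) stop("subsample too small for >= 3 pairs", call. = FALSE)
  with_seed(seed, {
    r_boot <- rep(NA_real_, n_boot)
    for (rep_i in seq_len(n_boot)) {
      s <- sample.int(n, k)
      idx <- lower_pairs(k)
      a <- A[s, s][idx]; b <- B[s, s][idx]
      ok <- !is.na(a) & !is.na(b)
      if (!is.null(C)) {
        cc <- C[s, s][idx]
        ok <- ok & !is.na(cc)
      }
      if (sum(ok) < 3) next
      a <- a[ok]; b <- b[ok]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      if (is.null(C)) {
        r_boot[rep_i] <- stats::cor(a, b)
      } else {
        cc <- cc[ok]
        if (stats::sd(cc) == 0) next
        r_ac <- stats::cor(a, cc); r_bc <- stats::cor(b, cc)
        if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) next
        r_boot[rep_i] <- partial_r(stats::cor(a, b), r_ac, r_bc, guard = FALSE)
      }
    }
    n_bad <- sum(is.na(r_boot))
    if (n_bad > 0.5 * n_boot) {
      stop("more than 50% of bootstrap repeats degenerate", call. = FALSE)
    }
    if (n_bad > 0) message(n_bad, " degenerate bootstrap repeat(s) discarded")
    unname(stats::quantile(r_boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  })
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, one-tailed p = %.4g (n = %d species, %d permutations)\n",
              if (x$method == "partial") "Partial" else "Simple",
              x$r_obs, x$p_one_tailed, x$n_species, x$n_perm))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f] (%d repeats)\n",
                x$ci_low, x$ci_high, x$n_boot))
  }
  invisible(x)
}
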