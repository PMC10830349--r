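#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded package functions never disturb the session stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage sub-seed from one root seed, so each simulation
# stage (tree, traits, abundance, ...) is independently reproducible.
# Stages are numbered; the map stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(tree = 11L, traits = 23L, abundance = 37L, missing = 53L,
               mantel = 67L, boot = 79L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# Validate a labelled square distance-like matrix; returns it with
# dimnames guaranteed.
check_square_matrix <- function(D, arg = deparse(substitute(D))) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("`", arg, "` must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(D)) || is.null(colnames(D))) {
    stop("`", arg, "` must have species labels as dimnames", call. = FALSE)
  }
  if (!identical(rownames(D), colnames(D))) {
    stop("`", arg, "` row and column labels differ", call. = FALSE)
  }
  D
}

# Reorder B's rows/columns to match A's labels; error if label sets differ.
align_matrices <- function(A, B, nameA = "A", nameB = "B") {
  a <- rownames(A); b <- rownames(B)
  if (!setequal(a, b)) {
    only_a <- setdiff(a, b); only_b <- setdiff(b, a)
    stop("species labels differ between ", nameA, " and ", nameB, ": ",
         if (length(only_a)) paste0("only in ", nameA, ": ",
                                    paste(utils::head(only_a, 5), collapse = ", ")) else "",
         if (length(only_a) && length(only_b)) "; " else "",
         if (length(only_b)) paste0("only in ", nameB, ": ",
                                    paste(utils::head(only_b, 5), collapse = ", ")) else "",
         call. = FALSE)
  }
  B[a, a, drop = FALSE]
}

# Lower-triangle (i > j) index pairs of an n x n matrix, in column-major
# order, as a 2-column integer matrix.
lower_pairs <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[, c("row", "col"), drop = FALSE]
}
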