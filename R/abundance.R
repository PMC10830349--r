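#' Read a collated abundance-index panel from CSV
#'
#' Long-format CSV with columns `species`, `year`, `index`; one row per
#' species-year. Indices are taken to be on the log scale already (the
#' collated index of monitoring schemes); set `log10 = TRUE` for raw-scale
#' inputs.
#'
#' @param path CSV file path.
#' @param log10 if `TRUE`, apply `log10()` to the index column (raw-scale
#'   inputs); default `FALSE`.
#' @return a data.frame with columns `species` (character), `year`
#'   (integer), `index` (numeric), class `"abundance_panel"`.
#' @export
read_panel <- function(path, log10 = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "year", "index")
  if (!all(need %in% names(df))) {
    stop("panel CSV must have columns species, year, index; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  if (!is.numeric(df$index)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$index))) & !is.na(df$index))
    stop("non-numeric index value(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[c("species", "year")])
  if (any(dup)) {
    stop("duplicate (species, year) row(s) at: ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  df$species <- as.character(df$species)
  df$year <- as.integer(df$year)
  if (log10) df$index <- log10(df$index)
  class(df) <- c("abundance_panel", "data.frame")
  df
}

#' Construct an abundance panel from in-memory data
#'
#' @param species,year,index parallel vectors (one element per
#'   species-year observation).
#' @return an `abundance_panel` data.frame.
#' @export
abundance_panel <- function(species, year, index) {
  df <- data.frame(species = as.character(species), year = as.integer(year),
                   index = as.numeric(index), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("species", "year")])) {
    stop("duplicate (species, year) pairs", call. = FALSE)
  }
  class(df) <- c("abundance_panel", "data.frame")
  df
}

#' Interannual abundance change
#'
#' Differences each species' collated annual index: change over the
#' interval starting in year t is index(t+1) - index(t). Changes are only
#' formed where both bounding years are observed; no change spans a gap.
#' Species with fewer than two observed years are dropped with a warning.
#'
#' @param panel an `abundance_panel` (long data.frame: species, year, index).
#' @return data.frame with columns `species`, `year` (start year of the
#'   interval), `delta`; class `"change_panel"`.
#' @export
interannual_change <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("species", "year", "index") %in% names(panel)))
  panel <- panel[!is.na(panel$index), , drop = FALSE]
  sp_split <- split(panel, panel$species)
  too_short <- names(sp_split)[vapply(sp_split, nrow, 1L) < 2L]
  if (length(too_short)) {
    warning("dropping species with < 2 observed years: ",
            paste(too_short, collapse = ", "), call. = FALSE)
    sp_split <- sp_split[!names(sp_split) %in% too_short]
  }
  out <- lapply(sp_split, function(d) {
    d <- d[order(d$year), , drop = FALSE]
    consec <- which(diff(d$year) == 1L)
    if (!length(consec)) return(NULL)
    data.frame(species = d$species[consec], year = d$year[consec],
               delta = d$index[consec + 1L] - d$index[consec],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(species = character(), year = integer(),
                                      delta = numeric())
  rownames(out) <- NULL
  class(out) <- c("change_panel", "data.frame")
  out
}

#' Pairwise abundance asynchrony matrix
#'
#' For each species pair, the Pearson correlation K of interannual changes
#' over their shared intervals (pairwise-complete) is mapped to the
#' asynchrony scale M = (1 - K) / 2, so perfectly synchronous pairs score
#' 0, uncorrelated pairs 0.5, and perfectly anticorrelated pairs 1.
#'
#' Pairs sharing fewer than `min_overlap` intervals, or with zero variance
#' in either change series over the shared intervals, are left undefined
#' (`NA`). The diagonal is 0 by convention.
#'
#' @param changes a `change_panel` from [interannual_change()].
#' @param min_overlap minimum number of shared intervals per pair
#'   (default 5; a correlation on fewer points is uninformative).
#' @return list of class `"asynchrony_matrix"`: `M` (symmetric numeric
#'   matrix, zero diagonal, `NA` where undefined) and `n_overlap`
#'   (symmetric integer matrix of shared-interval counts).
#' @export
asynchrony_matrix <- function(changes, min_overlap = 5L) {
  stopifnot(is.data.frame(changes), all(c("species", "year", "delta") %in% names(changes)))
  if (min_overlap < 3L) stop("`min_overlap` must be >= 3", call. = FALSE)
  species <- sort(unique(changes$species))
  years <- sort(unique(changes$year))
  W <- matrix(NA_real_, length(years), length(species),
              dimnames = list(as.character(years), species))
  W[cbind(match(changes$year, years), match(changes$species, species))] <- changes$delta
  obs <- !is.na(W)
  n_overlap <- crossprod(obs)
  storage.mode(n_overlap) <- "integer"
  K <- suppressWarnings(stats::cor(W, use = "pairwise.complete.obs"))
  # zero-variance pairs come back NA from cor(); also drop thin overlaps
  K[n_overlap < min_overlap] <- NA_real_
  M <- (1 - K) / 2
  diag(M) <- 0
  n_undef <- sum(is.na(M[lower.tri(M)]))
  if (n_undef == length(species) * (length(species) - 1) / 2 && length(species) > 1) {
    stop("insufficient overlap: all species pairs undefined", call. = FALSE)
  }
  if (n_undef > 0) {
    message(n_undef, " species pair(s) undefined (overlap < ", min_overlap,
            " or zero variance)")
  }
  structure(list(M = M, n_overlap = n_overlap, min_overlap = as.integer(min_overlap)),
            class = "asynchrony_matrix")
}

#' @export
print.asynchrony_matrix <- function(x, ...) {
  n <- nrow(x$M)
  cat("Asynchrony matrix: ", n, " species, ",
      sum(!is.na(x$M[lower.tri(x$M)])), "/", n * (n - 1) / 2,
      " pairs defined (min overlap ", x$min_overlap, ")\n", sep = "")
  invisible(x)
}

#' Write / read a labelled square matrix as CSV
#'
#' Plain CSV with species labels in the first column and as the header,
#' so `read_matrix(write_matrix(D, f))` round-trips exactly.
#'
#' @param D labelled square numeric matrix.
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` the matrix.
#' @export
write_matrix <- function(D, path) {
  check_square_matrix(D)
  df <- data.frame(species = rownames(D), D, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "species") stop("matrix CSV must start with a species column",
                                      call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix CSV labels are not symmetric", call. = FALSE)
  }
  m
}
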