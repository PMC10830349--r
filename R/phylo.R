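#' Parse a Newick tree with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]. Polytomies and
#' quoted labels are accepted; internal node labels are ignored. Every
#' edge must carry a nonnegative branch length — patristic distances are
#' undefined without them — and tip labels must be unique after
#' normalisation (whitespace trimmed, underscores read as spaces, as in
#' standard Newick).
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path file path (used when `text` is `NULL`).
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply `text` or `path`", call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')", call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  tree$tip.label <- trimws(gsub("_", " ", tree$tip.label))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
                        call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    missing_edge <- if (is.null(tree$edge.length)) "all edges" else {
      kids <- tree$edge[is.na(tree$edge.length), 2]
      tips <- kids[kids <= length(tree$tip.label)]
      if (length(tips)) paste("edge above", paste(tree$tip.label[tips], collapse = ", "))
      else "internal edge(s)"
    }
    stop("missing branch length(s): ", missing_edge, call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length(s)", call. = FALSE)
  tree
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique tip-to-tip path, for every pair
#' of tips, computed with the cophenetic method for `phylo` objects.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric numeric matrix, zero diagonal, labelled by tip, with
#'   `"provenance"` attribute `"phylogeny"`.
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  D <- stats::cophenetic(tree)
  D <- D[tree$tip.label, tree$tip.label]
  attr(D, "provenance") <- "phylogeny"
  D
}

#' Collapse a species complex to a single operational unit
#'
#' Replaces the member tips of a species complex (e.g. taxa that cannot
#' be separated in the field) by one row/column whose distance to every
#' other species is the arithmetic mean of the members' distances to that
#' species.
#'
#' @param D labelled square distance matrix.
#' @param members character vector of member labels (>= 2) present in `D`.
#' @param label label for the collapsed unit.
#' @return distance matrix with members replaced by `label`.
#' @export
collapse_complex <- function(D, members, label) {
  check_square_matrix(D)
  if (length(members) < 2) stop("a species complex needs >= 2 members", call. = FALSE)
  absent <- setdiff(members, rownames(D))
  if (length(absent)) stop("complex member(s) absent from matrix: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  keep <- setdiff(rownames(D), members)
  d_new <- colMeans(D[members, keep, drop = FALSE])
  out <- rbind(cbind(D[keep, keep, drop = FALSE], d_new),
               c(d_new, 0))
  rownames(out)[nrow(out)] <- label
  colnames(out)[ncol(out)] <- label
  attr(out, "provenance") <- attr(D, "provenance")
  out
}
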