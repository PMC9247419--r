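#' Read a phylogenetic tree from Newick text or a file
#'
#' Parses a rooted phylogeny with branch lengths in the units of the source
#' tree (million years for time-calibrated consensus trees). Polytomies are
#' permitted. The returned object is an \code{ape} \code{"phylo"} tree,
#' validated for the invariants the comparative analyses rely on: unique leaf
#' labels, non-negative branch lengths, and a branch length on every edge.
#'
#' @param source Newick string (must contain \code{";"} or parentheses) or a
#'   path to a Newick file.
#' @param fill_missing_lengths if \code{TRUE}, edges without a branch length
#'   are assigned length 1; otherwise missing lengths are an error.
#' @return An object of class \code{"phylo"}.
#' @examples
#' tr <- read_phylo_tree("((A:1,B:1):1,C:2);")
#' @export
read_phylo_tree <- function(source, fill_missing_lengths = FALSE) {
  stopifnot(is.character(source), length(source) == 1L)
  is_text <- grepl("[();]", source)
  txt <- if (is_text) source else paste(readLines(source, warn = FALSE), collapse = "")
  .check_newick_balance(txt)
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop_("failed to parse Newick input (not a well-formed tree)")
  }
  if (is.null(tr$edge.length)) {
    if (!fill_missing_lengths) {
      stop_("tree has no branch lengths; set fill_missing_lengths = TRUE to assume 1.0")
    }
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (!fill_missing_lengths) {
      stop_("tree has edges with missing branch lengths; set fill_missing_lengths = TRUE to assume 1.0")
    }
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  validate_phylo_tree(tr)
  tr
}

# Report the position of the first unbalanced parenthesis so parse errors
# point at the offending character.
.check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L) {
    stop_("malformed Newick: ", depth, " unclosed '(' (input ends at position ",
          length(chars), ")")
  }
  invisible(TRUE)
}

#' Validate tree invariants for comparative analysis
#'
#' Checks that leaf labels are unique, branch lengths are non-negative, and
#' every leaf is reachable from the root.
#'
#' @param tree a \code{"phylo"} tree.
#' @return The tree, invisibly.
#' @export
validate_phylo_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop_("leaf labels must be unique")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop_("branch lengths must be non-negative")
  }
  n_tip <- length(tree$tip.label)
  if (n_tip >= 2L) {
    # every leaf reachable from the root: each tip must appear as an edge child
    children <- tree$edge[, 2]
    if (!all(seq_len(n_tip) %in% children)) stop_("tree has unreachable leaves")
  }
  invisible(tree)
}

#' Write a tree as Newick text
#'
#' @param tree a \code{"phylo"} tree.
#' @param file optional path; if \code{NULL} the Newick string is returned.
#' @return Newick string (invisibly when writing to a file).
#' @export
write_phylo_tree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Brownian-motion trait covariance from a tree
#'
#' Under Brownian trait evolution, the expected covariance between two
#' species equals the branch length they share on the path from the root:
#' \eqn{C_{ij}} is the depth of their most recent common ancestor and
#' \eqn{C_{ii}} the root-to-tip depth of species \eqn{i}. Phylogenies need
#' not be binary; polytomies enter the covariance naturally.
#'
#' @param tree a \code{"phylo"} tree with at least two leaves.
#' @return An object of class \code{"cov_model"}: a list with the covariance
#'   matrix \code{C} (species in \code{tree$tip.label} order), the
#'   \code{lambda} applied so far (1 = untransformed Brownian), and the model
#'   kind.
#' @examples
#' C <- brownian_covariance(read_phylo_tree("((A:1,B:1):1,C:2);"))
#' @export
brownian_covariance <- function(tree) {
  validate_phylo_tree(tree)
  if (length(tree$tip.label) < 2L) stop_("need at least 2 leaves for a covariance model")
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop_("degenerate covariance: tree has zero depth")
  structure(list(C = C, lambda = 1, kind = "brownian"), class = "cov_model")
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of the covariance by \code{lambda},
#' leaving the diagonal untouched. \code{lambda = 1} keeps the full
#' Brownian-motion covariance; \code{lambda = 0} removes all phylogenetic
#' signal, leaving independent residuals.
#'
#' @param cov a \code{"cov_model"} (or bare covariance matrix).
#' @param lambda real in \eqn{[0, 1]}.
#' @return A \code{"cov_model"} with the transformed matrix.
#' @export
lambda_transform <- function(cov, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (is.na(lambda) || lambda < 0 || lambda > 1) {
    stop_("lambda must lie in [0, 1], got ", lambda)
  }
  C <- if (inherits(cov, "cov_model")) cov$C else as.matrix(cov)
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  structure(list(C = C, lambda = lambda, kind = "brownian"), class = "cov_model")
}
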