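# Neighbour-joining trees, patristic distances, bootstrap support and
# newick interchange.  Tree construction is delegated to the reference NJ
# implementation in ape; the wrapper adds the two-taxon case, non-negative
# branch lengths (required downstream by weighted UniFrac) and bookkeeping
# of the clamped deficit.

#' Neighbour-joining tree from a distance matrix
#'
#' Negative estimated branch lengths (a known NJ artefact on non-additive
#' matrices) are clamped to zero; the total clamped deficit is recorded in
#' the `"clamped"` attribute.  For two taxa the tree is the single edge
#' with two pendant branches of length d/2.
#'
#' @param matrix symmetric labelled distance matrix.
#' @return an [ape::phylo] tree whose tip set equals the matrix ids.
#' @export
nj_tree <- function(matrix) {
  check_dist_matrix(matrix)
  n <- nrow(matrix)
  if (n < 2L) stop("neighbour joining needs at least 2 taxa")
  if (n == 2L) {
    d <- matrix[1, 2]
    tr <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
               edge.length = c(d / 2, d / 2),
               tip.label = rownames(matrix), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    attr(tr, "clamped") <- 0
    return(tr)
  }
  tr <- ape::nj(matrix)
  neg <- tr$edge.length < 0
  attr(tr, "clamped") <- sum(-tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Patristic (path-length) distances between the leaves of a tree
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric labelled matrix of leaf-to-leaf path lengths.
#' @export
patristic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Midpoint-root a tree
#'
#' Weighted UniFrac needs a rooted tree; when an unrooted NJ tree is
#' supplied the midpoint root is applied.
#'
#' @param tree an [ape::phylo] tree.
#' @return a rooted tree.
#' @export
midpoint_root <- function(tree) {
  if (ape::is.rooted(tree)) return(tree)
  phangorn::midpoint(tree)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and reports, for each internal edge of the point-estimate
#' tree, the fraction of replicates containing the same bipartition.
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_replicates number of bootstrap replicates (1000 in the classic
#'   protocol; reduce for quick checks).
#' @param seed integer seed for the resampling.
#' @param model,gap_policy passed to [distance_matrix()].
#' @return list with `tree` (the point-estimate tree, node labels set to
#'   support values) and `support` (numeric vector over internal nodes, in
#'   `[0, 1]`).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              model = c("jukes_cantor", "p"),
                              gap_policy = "pairwise") {
  model <- match.arg(model)
  x <- char_matrix(alignment)
  if (ncol(x) < 2L) stop("alignment too short to resample (< 2 columns)")
  build <- function(mat) nj_tree(distance_matrix(mat, model = model))
  phy <- build(x)
  set.seed(seed)
  counts <- ape::boot.phylo(phy, x, build, B = n_replicates,
                            quiet = TRUE, trees = FALSE)
  # trivial bipartitions (the root split of an unrooted tree) come back
  # NA from the bipartition counter; they are present in every replicate
  counts[is.na(counts)] <- n_replicates
  support <- counts / n_replicates
  phy$node.label <- format(support, digits = 3)
  list(tree = phy, support = support)
}

#' Parse a newick string
#' @param text newick text (must end with `;`).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick: ", substr(text, 1, 60))
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  tr
}

#' Serialize a tree to newick
#' @param tree an [ape::phylo] tree.
#' @param digits significant digits for branch lengths (default 6).
#' @return newick string.
#' @export
write_newick <- function(tree, digits = 6) {
  ape::write.tree(tree, digits = digits)
}
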