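# Abundance-weighted UniFrac between communities on a shared tree, and
# principal coordinate analysis of the resulting distance matrix.

# Per-edge descendant-fraction matrix: rows = edges of the rooted tree,
# columns = communities.  profiles is a leaf x community matrix of
# relative abundances.
edge_fractions <- function(tree, profiles) {
  tree <- midpoint_root(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nnode, ncol(profiles))
  acc[seq_len(ntip), ] <- profiles[tree$tip.label, , drop = FALSE]
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  for (e in seq_along(child))
    acc[parent[e], ] <- acc[parent[e], ] + acc[child[e], ]
  list(frac = acc[child, , drop = FALSE], length = tree$edge.length)
}

check_profile <- function(p, tree, name) {
  if (is.null(names(p))) stop("profile ", name, " must be named by leaf")
  absent <- setdiff(names(p), tree$tip.label)
  if (length(absent))
    stop("profile ", name, " references leaves absent from the tree: ",
         paste(absent, collapse = ", "))
  if (any(p < 0)) stop("profile ", name, " has negative abundances")
  if (abs(sum(p) - 1) > 1e-9)
    stop("profile ", name, " is not normalized (sums to ", sum(p), ")")
  full <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
  full[names(p)] <- p
  full
}

#' Abundance-weighted UniFrac distance between two communities
#'
#' \eqn{d = \sum_i b_i |A_i - B_i|} over the branches of the (rooted) tree,
#' where \eqn{A_i} and \eqn{B_i} are the fractions of each community
#' descending from branch i and \eqn{b_i} the branch length.  With
#' `normalized = TRUE` the sum is divided by \eqn{\sum_i b_i (A_i + B_i)},
#' scaling the distance into `[0, 1]`.  Unrooted trees are midpoint-rooted
#' first.
#'
#' @param tree an [ape::phylo] tree whose leaves cover both profiles.
#' @param a,b named numeric vectors of relative abundances (each summing
#'   to 1; leaves may be omitted when absent).
#' @param normalized divide by the abundance-weighted total branch length.
#' @return a single non-negative distance; 0 iff the profiles coincide.
#' @export
weighted_unifrac <- function(tree, a, b, normalized = FALSE) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  pa <- check_profile(a, tree, "a")
  pb <- check_profile(b, tree, "b")
  ef <- edge_fractions(tree, cbind(A = pa, B = pb))
  raw <- sum(ef$length * abs(ef$frac[, 1] - ef$frac[, 2]))
  if (!normalized) return(raw)
  denom <- sum(ef$length * (ef$frac[, 1] + ef$frac[, 2]))
  if (denom == 0) return(0)
  raw / denom
}

#' Weighted UniFrac distance matrix over the libraries of an OTU table
#'
#' Each library's counts are converted to relative abundances on the tree
#' leaves via `leaf_map` (OTU id -> leaf label; defaults to identity).
#'
#' @param tree an [ape::phylo] tree.
#' @param table an `otu_table_bs`.
#' @param leaf_map named character vector OTU -> leaf; by default OTU ids
#'   are assumed to be leaf labels.
#' @param normalized see [weighted_unifrac()].
#' @return symmetric labelled distance matrix over libraries.
#' @export
unifrac_matrix <- function(tree, table, leaf_map = NULL, normalized = FALSE) {
  otus <- rownames(table$counts)
  leaf_map <- leaf_map %||% setNames(otus, otus)
  miss <- setdiff(otus, names(leaf_map))
  if (length(miss))
    stop("OTU(s) missing from leaf map: ", paste(head(miss, 5), collapse = ", "))
  absent <- setdiff(leaf_map[otus], tree$tip.label)
  if (length(absent))
    stop("leaf(s) absent from tree: ", paste(head(absent, 5), collapse = ", "))
  frac <- otu_fractions(table)
  profiles <- matrix(0, length(tree$tip.label), ncol(frac),
                     dimnames = list(tree$tip.label, colnames(frac)))
  profiles[leaf_map[otus], ] <- frac
  ef <- edge_fractions(tree, profiles)
  nlib <- ncol(profiles)
  d <- matrix(0, nlib, nlib, dimnames = list(colnames(frac), colnames(frac)))
  for (i in seq_len(nlib - 1)) {
    for (j in seq(i + 1, nlib)) {
      raw <- sum(ef$length * abs(ef$frac[, i] - ef$frac[, j]))
      if (normalized) {
        denom <- sum(ef$length * (ef$frac[, i] + ef$frac[, j]))
        raw <- if (denom == 0) 0 else raw / denom
      }
      d[i, j] <- d[j, i] <- raw
    }
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of \eqn{-D^2/2},
#' eigendecomposition, coordinates scaled by the square root of the
#' positive eigenvalues.  Negative eigenvalues (possible for non-Euclidean
#' distances such as UniFrac) are reported but excluded from the
#' coordinates and from the percent-variance denominator; no Lingoes or
#' Cailliez correction is applied.  Eigenvector signs are fixed by making
#' the largest-magnitude loading of each axis positive.
#'
#' @param matrix symmetric labelled distance matrix.
#' @return object of class `pcoa_ordination`: list with `coordinates`
#'   (libraries x axes), `eigenvalues` (all, decreasing) and
#'   `percent_explained` (over positive eigenvalues).
#' @export
pcoa_ordination <- function(matrix) {
  check_dist_matrix(matrix)
  n <- nrow(matrix)
  d2 <- matrix^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% d2 %*% j
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values), 1)
  pos <- which(eig$values > tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), length(pos))
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(matrix),
                           paste0("Axis", seq_along(pos)))
  structure(list(coordinates = coords,
                 eigenvalues = eig$values,
                 percent_explained = 100 * eig$values[pos] /
                   sum(eig$values[pos])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- min(3, length(x$percent_explained))
  cat("PCoA:", nrow(x$coordinates), "points;",
      paste0("Axis", seq_len(k), " = ",
             sprintf("%.1f%%", x$percent_explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}
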