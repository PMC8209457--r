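# Rank-level taxonomic composition tables and the exact two-library
# frequency comparison.

TAXONOMIC_RANKS <- c("phylum", "class", "order", "family", "genus")

# assignments: long data frame (sequence_id, rank, taxon, confidence).
# Returns, for every sequence, its label at `rank`: the assigned taxon
# when its confidence clears the threshold, otherwise "unclassified
# <deepest confident parent>" ("unclassified Root" when nothing clears).
rank_labels <- function(assignments, rank, min_confidence,
                        ranks = TAXONOMIC_RANKS) {
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  keep <- assignments$rank %in% ranks
  a <- assignments[keep, , drop = FALSE]
  a$depth <- match(a$rank, ranks)
  target <- match(rank, ranks)
  ids <- unique(assignments$sequence_id)
  lab <- setNames(rep("unclassified Root", length(ids)), ids)
  at <- a[a$depth == target & a$confidence >= min_confidence, ]
  lab[at$sequence_id] <- at$taxon
  todo <- setdiff(ids, at$sequence_id)
  if (length(todo)) {
    anc <- a[a$sequence_id %in% todo & a$depth < target &
               a$confidence >= min_confidence, ]
    if (nrow(anc)) {
      anc <- anc[order(anc$sequence_id, -anc$depth), ]
      deepest <- anc[!duplicated(anc$sequence_id), ]
      lab[deepest$sequence_id] <- paste("unclassified", deepest$taxon)
    }
  }
  lab
}

#' Aggregate taxonomy assignments into a composition table
#'
#' Sequences whose confidence at the requested rank is below
#' `min_confidence` (the classic 80\% classifier threshold) are rolled up
#' into an `"unclassified <parent>"` row named after the deepest rank that
#' does clear the threshold.  Percentages are computed against the library
#' size, so each column sums to 100.
#'
#' @param assignments long data frame with columns `sequence_id`, `rank`,
#'   `taxon`, `confidence` (ranks phylum...genus).
#' @param metadata data frame with columns `sequence_id`, `library_id`.
#' @param rank rank at which to aggregate.
#' @param min_confidence confidence threshold in `[0, 1]` (default 0.8).
#' @return object of class `composition_table`: list with `percent` and
#'   `counts` matrices (taxon x library) and the `libraries` vector.
#' @export
aggregate_composition <- function(assignments, metadata, rank,
                                  min_confidence = 0.8) {
  miss <- setdiff(unique(assignments$sequence_id), metadata$sequence_id)
  if (length(miss))
    stop("sequence(s) without metadata: ", paste(head(miss, 5), collapse = ", "))
  lab <- rank_labels(assignments, rank, min_confidence)
  lib <- setNames(metadata$library_id, metadata$sequence_id)[names(lab)]
  libs <- unique(metadata$library_id)
  counts <- table(factor(lab), factor(lib, levels = libs))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), libs))
  sizes <- colSums(counts)
  pct <- sweep(counts, 2, pmax(sizes, 1L), "/") * 100
  structure(list(percent = pct, counts = counts, libraries = libs,
                 rank = rank, min_confidence = min_confidence),
            class = "composition_table")
}

#' Exact two-library frequency comparison
#'
#' Tests whether a taxon observed `x` times in a library of size `nx` and
#' `y` times in a library of size `ny` differs in frequency, using the
#' exact tail of \deqn{P(y \mid x) = (N_y/N_x)^y \frac{(x+y)!}{x!\,y!\,
#' (1 + N_y/N_x)^{x+y+1}}} (the posterior predictive of a Poisson rate
#' under a flat prior, equivalently a negative binomial).  The reported
#' p-value doubles the smaller tail, capped at 1, and is symmetrized by
#' taking the minimum over the two library orderings so that swapping the
#' libraries leaves it unchanged.
#'
#' @param x,nx taxon count and library size for the first library.
#' @param y,ny taxon count and library size for the second library.
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' compare_two_libraries(10, 100, 0, 100)
compare_two_libraries <- function(x, nx, y, ny) {
  if (any(c(x, y) < 0)) stop("negative counts")
  if (any(c(nx, ny) <= 0)) stop("library sizes must be positive")
  if (x > nx || y > ny) stop("count exceeds library size")
  one_dir <- function(x, nx, y, ny) {
    # y | x ~ NegBinom(size = x + 1, prob = nx / (nx + ny))
    pr <- nx / (nx + ny)
    lower <- pnbinom(y, size = x + 1, prob = pr)
    upper <- if (y > 0) 1 - pnbinom(y - 1, size = x + 1, prob = pr) else 1
    min(1, 2 * min(lower, upper))
  }
  min(one_dir(x, nx, y, ny), one_dir(y, ny, x, nx))
}

#' Composition report with significance flags against a reference library
#'
#' Builds per-rank composition tables and flags, for every taxon and
#' library, a significant frequency difference (`p < alpha`) from the
#' same-tissue reference library — by default the NPK clone library of the
#' library's tissue, mirroring the shaded cells of printed composition
#' tables.  Libraries whose tissue has no reference (e.g. isolate
#' collections when restricted to clone references) get `NA` flags.  No
#' multiple-testing correction is applied across taxa (by design; the
#' `note` element records this).
#'
#' @param assignments,metadata see [aggregate_composition()].
#' @param library_meta data frame with `library_id`, `tissue`, `condition`,
#'   `provenance` used to locate reference libraries.
#' @param ranks ranks to report (default phylum...genus).
#' @param min_confidence classifier confidence threshold.
#' @param alpha significance level for the two-library test (default 0.05).
#' @param reference_map optional named character vector tissue ->
#'   reference library id, overriding the NPK-clone default.
#' @return list of per-rank data frames (`taxon`, `library_id`, `percent`,
#'   `count`, `p_value`, `significant`), plus a `note` attribute.
#' @export
composition_report <- function(assignments, metadata, library_meta,
                               ranks = TAXONOMIC_RANKS,
                               min_confidence = 0.8, alpha = 0.05,
                               reference_map = NULL) {
  if (is.null(reference_map)) {
    ref <- library_meta[library_meta$condition == "NPK" &
                          library_meta$provenance == "clone", ]
    reference_map <- setNames(ref$library_id, ref$tissue)
  }
  out <- lapply(ranks, function(rk) {
    comp <- aggregate_composition(assignments, metadata, rk, min_confidence)
    sizes <- colSums(comp$counts)
    rows <- list()
    for (lib in comp$libraries) {
      tis <- library_meta$tissue[library_meta$library_id == lib]
      refl <- if (length(tis)) reference_map[tis] else NA_character_
      for (tx in rownames(comp$counts)) {
        p <- NA_real_
        if (!is.na(refl) && refl %in% comp$libraries && lib != refl)
          p <- compare_two_libraries(comp$counts[tx, lib], sizes[lib],
                                     comp$counts[tx, refl], sizes[refl])
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = tx, library_id = lib, percent = comp$percent[tx, lib],
          count = comp$counts[tx, lib], p_value = p,
          significant = if (is.na(p)) NA else p < alpha,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  names(out) <- ranks
  attr(out, "note") <-
    "p-values are per taxon; no multiple-testing correction is applied"
  out
}
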