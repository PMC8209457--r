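# Agglomerative OTU clustering and the OTU x library count table.

#' Cluster sequences into OTUs at a distance threshold
#'
#' Standard agglomerative clustering on a precomputed distance matrix.
#' Merging stops when the smallest inter-cluster linkage distance exceeds
#' `threshold`; under the default furthest-neighbour (complete) linkage
#' this guarantees that no OTU contains a pair of sequences more distant
#' than the threshold — the classic 97\%-identity OTU definition when
#' `threshold = 0.03` on p-distances.  Ties are broken deterministically:
#' smallest linkage distance first, then the pair whose smallest member ids
#' sort first.  OTU ids are assigned by decreasing OTU size, then smallest
#' member id.
#'
#' @param matrix symmetric labelled distance matrix (see
#'   [distance_matrix()]).
#' @param threshold distance cutoff in `[0, 1]`; 0.03 corresponds to 97\%
#'   sequence identity.
#' @param linkage `"furthest"` (default), `"nearest"` or `"average"`.
#' @return an object of class `otu_partition`: list with `assignment`
#'   (named character, sequence id -> OTU id), `otus` (list of member id
#'   vectors), `threshold` and `linkage`.
#' @export
cluster_otus <- function(matrix, threshold = 0.03,
                         linkage = c("furthest", "nearest", "average")) {
  linkage <- match.arg(linkage)
  check_dist_matrix(matrix)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ids <- rownames(matrix)
  n <- length(ids)
  if (n == 0L) stop("empty distance matrix")

  D <- matrix
  diag(D) <- Inf
  active <- rep(TRUE, n)
  members <- as.list(ids)
  sizes <- rep(1L, n)
  minid <- ids  # smallest member id per cluster

  while (sum(active) > 1L) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    m <- min(sub)
    if (!is.finite(m) || m > threshold) break
    cand <- which(sub <= m + 1e-15 & upper.tri(sub), arr.ind = TRUE)
    a <- idx[cand[, 1]]
    b <- idx[cand[, 2]]
    lo <- pmin(minid[a], minid[b])
    hi <- pmax(minid[a], minid[b])
    pick <- order(lo, hi)[1L]
    i <- a[pick]; j <- b[pick]

    di <- D[i, ]; dj <- D[j, ]
    merged <- switch(linkage,
      furthest = pmax(di, dj),
      nearest  = pmin(di, dj),
      average  = (sizes[i] * di + sizes[j] * dj) / (sizes[i] + sizes[j]))
    D[i, ] <- merged
    D[, i] <- merged
    D[i, i] <- Inf
    D[j, ] <- Inf
    D[, j] <- Inf
    active[j] <- FALSE
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    minid[i] <- min(minid[i], minid[j])
  }

  keep <- which(active)
  ord <- keep[order(-sizes[keep], minid[keep])]
  otus <- lapply(members[ord], sort)
  names(otus) <- paste0("OTU-", seq_along(otus))
  assignment <- setNames(rep(names(otus), lengths(otus)),
                         unlist(otus, use.names = FALSE))
  assignment <- assignment[ids]
  structure(list(assignment = assignment, otus = otus,
                 threshold = threshold, linkage = linkage),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat("OTU partition:", length(x$otus), "OTUs from",
      length(x$assignment), "sequences\n")
  cat("threshold:", x$threshold, " linkage:", x$linkage, "\n")
  invisible(x)
}

#' Build the OTU x library count table
#'
#' @param partition an `otu_partition` (or a named character vector mapping
#'   sequence id to OTU id).
#' @param seq_library named character vector mapping sequence id to library
#'   id.
#' @param libraries data frame of per-library metadata with columns
#'   `library_id`, `tissue`, `condition`, `provenance` (`"clone"` or
#'   `"isolate"`) and `medium` (NA for clone libraries).
#' @return an object of class `otu_table_bs`: list with integer `counts`
#'   (OTU x library), `libraries` (metadata with a `size` column),
#'   `members` (list of member sequence ids per OTU) and `seq_library`.
#' @export
build_otu_table <- function(partition, seq_library, libraries) {
  assignment <- if (inherits(partition, "otu_partition"))
    partition$assignment else partition
  need <- c("library_id", "tissue", "condition", "provenance", "medium")
  miss <- setdiff(need, names(libraries))
  if (length(miss))
    stop("libraries metadata lacks column(s): ", paste(miss, collapse = ", "))
  unmapped <- setdiff(names(assignment), names(seq_library))
  if (length(unmapped))
    stop("sequence id(s) missing from the library map: ",
         paste(head(unmapped, 5), collapse = ", "))
  libs <- seq_library[names(assignment)]
  unknown <- setdiff(unique(libs), libraries$library_id)
  if (length(unknown))
    stop("library id(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  otu_levels <- unique(assignment)
  otu_levels <- otu_levels[order_otu_ids(otu_levels)]
  counts <- table(factor(assignment, levels = otu_levels),
                  factor(libs, levels = libraries$library_id))
  counts <- matrix(as.integer(counts), nrow = length(otu_levels),
                   dimnames = list(otu_levels, libraries$library_id))
  libraries <- as.data.frame(libraries)
  libraries$size <- colSums(counts)
  members <- split(names(assignment), assignment)[otu_levels]
  structure(list(counts = counts, libraries = libraries,
                 members = members, seq_library = seq_library),
            class = "otu_table_bs")
}

#' @export
print.otu_table_bs <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "libraries (",
      sum(x$counts), "sequences )\n")
  invisible(x)
}

#' Relative abundances (fractions) of an OTU table
#' @param table an `otu_table_bs`.
#' @return matrix of per-library fractions; columns sum to 1.
#' @export
otu_fractions <- function(table) {
  sweep(table$counts, 2, pmax(table$libraries$size, 1L), "/")
}

#' Classify OTUs by provenance of their member sequences
#'
#' Counts OTUs composed only of isolates, of both clones and isolates, or
#' only of clones, optionally restricted to OTUs present in a subset of
#' libraries (e.g. all lateral-root libraries and collections).
#'
#' @param table an `otu_table_bs`.
#' @param libraries optional character vector of library ids; default all.
#' @return named integer vector `c(isolate_only, both, clone_only)`.
#' @export
classify_otus_by_provenance <- function(table, libraries = NULL) {
  libs <- libraries %||% table$libraries$library_id
  bad <- setdiff(libs, table$libraries$library_id)
  if (length(bad)) stop("unknown library id(s): ", paste(bad, collapse = ", "))
  sub <- table$counts[, libs, drop = FALSE]
  present <- rowSums(sub) > 0
  prov <- table$libraries$provenance[match(libs, table$libraries$library_id)]
  iso <- rowSums(sub[, prov == "isolate", drop = FALSE]) > 0
  clo <- rowSums(sub[, prov == "clone", drop = FALSE]) > 0
  c(isolate_only = sum(present & iso & !clo),
    both = sum(present & iso & clo),
    clone_only = sum(present & !iso & clo))
}

#' Pick the representative sequence of an OTU
#'
#' For selection purposes one isolate represents each candidate OTU.  Under
#' `rule = "most_abundant_isolate"` the representative is drawn from the
#' isolate collection in which the OTU is most abundant (ties: first
#' collection in table order), taking the lexicographically smallest
#' sequence id; `rule = "smallest_id"` simply takes the smallest member id
#' among isolates (or among all members when `require_isolate = FALSE`).
#'
#' @param table an `otu_table_bs`.
#' @param otu OTU id.
#' @param rule `"most_abundant_isolate"` or `"smallest_id"`.
#' @param require_isolate error (class `beetscreen_no_isolate`) if the OTU
#'   contains no isolate sequence (default TRUE).
#' @return a sequence id.
#' @export
otu_representative <- function(table, otu,
                               rule = c("most_abundant_isolate", "smallest_id"),
                               require_isolate = TRUE) {
  rule <- match.arg(rule)
  if (!otu %in% names(table$members)) stop("unknown OTU: ", otu)
  mem <- table$members[[otu]]
  lib_of <- table$seq_library[mem]
  prov <- table$libraries$provenance[match(lib_of, table$libraries$library_id)]
  iso_mem <- mem[prov == "isolate"]
  if (length(iso_mem) == 0L) {
    if (require_isolate)
      stop(errorCondition(paste0("OTU ", otu, " contains no isolate"),
                          class = c("beetscreen_no_isolate", "error",
                                    "condition")))
    iso_mem <- mem
  }
  if (rule == "smallest_id") return(sort(iso_mem)[1])
  iso_libs <- table$seq_library[iso_mem]
  tab <- table(iso_libs)
  best_lib <- names(tab)[tab == max(tab)]
  best_lib <- intersect(table$libraries$library_id, best_lib)[1]
  sort(iso_mem[iso_libs == best_lib])[1]
}
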