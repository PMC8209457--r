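# Loaders for the printed study tables shipped with the package: the
# per-library alpha diversity block, the per-OTU abundance profiles of the
# growth-promoting/-inhibiting isolates, and their BLAST best hits.  These
# are inputs (transcribed published tables), used by the consistency
# checks and worked examples.

#' Printed per-library alpha diversity statistics
#'
#' The published statistics block for the 12 clone libraries and 4
#' isolate collections: library sizes, observed OTUs, singleton counts,
#' coverage and diversity indices as printed (one decimal).
#'
#' @return data frame, one row per library/collection.
#' @export
table1_alpha <- function() {
  read.delim(system.file("extdata", "table1_alpha.tsv",
                         package = "beetscreen", mustWork = TRUE),
             stringsAsFactors = FALSE, na.strings = "")
}

#' Printed clone-library abundance profiles of the tested isolates
#'
#' Relative abundance (percent) of the 14 growth-promoting or
#' growth-inhibiting OTUs across the 12 clone libraries, plus the isolate
#' representing each OTU.
#'
#' @return data frame, one row per OTU.
#' @export
table5_profiles <- function() {
  read.delim(system.file("extdata", "table5_profiles.tsv",
                         package = "beetscreen", mustWork = TRUE),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Printed best-hit identities of the tested isolates
#'
#' BLAST best hits (closest known species and percent identity of the
#' near-full-length 16S rRNA gene) for the 14 tested isolates.
#'
#' @return data frame, one row per OTU.
#' @export
table4_best_hits <- function() {
  read.delim(system.file("extdata", "table4_best_hits.tsv",
                         package = "beetscreen", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Selection evidence from the printed isolate tables
#'
#' Combines the clone-library abundance profiles with the best-hit
#' identities into an `otu_evidence` object.  Every row of the profile
#' table names a cultured isolate, so `has_isolate` is TRUE throughout;
#' presence is encoded as count 1 wherever the printed abundance is
#' nonzero (the isolate-collection columns of the original study are not
#' published, so this evidence covers the clone libraries only).
#'
#' @return an `otu_evidence` over the 14 tested OTUs.
#' @export
table5_evidence <- function() {
  prof <- table5_profiles()
  hits <- table4_best_hits()
  t1 <- table1_alpha()
  lib_ids <- t1$library_id[t1$provenance == "clone"]
  libraries <- t1[t1$provenance == "clone",
                  c("library_id", "tissue", "condition", "provenance",
                    "medium")]
  libraries$size <- t1$n_sequences[t1$provenance == "clone"]
  pct <- as.matrix(prof[, lib_ids])
  rownames(pct) <- prof$otu_id
  i <- match(prof$otu_id, hits$otu_id)
  info <- data.frame(otu_id = prof$otu_id, has_isolate = TRUE,
                     best_hit_identity = hits$identity_pct[i] / 100,
                     best_hit_taxon = hits$closest_species[i],
                     stringsAsFactors = FALSE)
  structure(list(info = info, counts = (pct > 0) + 0L, frac = pct / 100,
                 libraries = libraries),
            class = "otu_evidence")
}
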