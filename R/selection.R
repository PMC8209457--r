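# Rule-based candidate-PGPB selection: the screening logic at the heart of
# the package.  An OTU becomes a candidate when it satisfies at least one
# positive criterion —
#   novelty:            < 97% identity to the closest known species,
#   tissue specificity: present only in below-ground tissues,
#   persistence:        present in a below-ground tissue under every
#                       fertilization condition,
#   abundance:          > 1% relative abundance in some below-ground
#                       library or collection,
#   known PGPB:         best hit in a curated genus list —
# AND has at least one cultured isolate AND is not excluded by the
# pathogen list.  "Presence" means a raw count of at least one; the
# identity and abundance thresholds are strict inequalities ("less than" /
# "more than").

BELOW_GROUND_TISSUES <- c("taproot", "lateral_root")

#' Default selection configuration
#'
#' Thresholds and the curated reference lists (known sugar-beet PGPB
#' genera; plant/animal/human pathogen taxa) shipped as editable JSON in
#' `inst/extdata/selection_config.json`.
#'
#' @param path optional path to an alternative JSON config.
#' @return list with `novelty_threshold`, `abundance_threshold`,
#'   `target_tissues`, `known_pgpb_genera`, `pathogen_taxa`,
#'   `pathogen_match`.
#' @export
default_selection_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "selection_config.json",
                                package = "beetscreen", mustWork = TRUE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$novelty_threshold <- cfg$novelty_threshold %||% 0.97
  cfg$abundance_threshold <- cfg$abundance_threshold %||% 0.01
  cfg$target_tissues <- cfg$target_tissues %||% BELOW_GROUND_TISSUES
  cfg$pathogen_match <- cfg$pathogen_match %||% "species"
  cfg
}

#' Assemble per-OTU selection evidence from an OTU table and best hits
#'
#' @param table an `otu_table_bs`.
#' @param best_hits data frame with columns `otu_id`, `identity` (fraction
#'   in `[0, 1]`) and `closest_taxon`; OTUs absent from it get `NA`
#'   identity (excluded from the novelty criterion with a warning).
#' @return object of class `otu_evidence`: list with `info` (per-OTU data
#'   frame: `otu_id`, `has_isolate`, `best_hit_identity`,
#'   `best_hit_taxon`), `counts`, `frac` and `libraries`.
#' @export
build_otu_evidence <- function(table, best_hits = NULL) {
  otus <- rownames(table$counts)
  prov <- table$libraries$provenance
  iso_libs <- table$libraries$library_id[prov == "isolate"]
  has_iso <- rowSums(table$counts[, iso_libs, drop = FALSE]) > 0
  info <- data.frame(otu_id = otus, has_isolate = unname(has_iso),
                     best_hit_identity = NA_real_,
                     best_hit_taxon = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(best_hits)) {
    i <- match(info$otu_id, best_hits$otu_id)
    info$best_hit_identity <- best_hits$identity[i]
    info$best_hit_taxon <- best_hits$closest_taxon[i]
    if (any(!is.na(info$best_hit_identity) &
              (info$best_hit_identity < 0 | info$best_hit_identity > 1)))
      stop("best-hit identities must be fractions in [0, 1]")
  }
  structure(list(info = info, counts = table$counts,
                 frac = otu_fractions(table), libraries = table$libraries),
            class = "otu_evidence")
}

#' Phylogenetic novelty criterion
#'
#' TRUE iff the best-hit identity is strictly below the threshold (default
#' 0.97, i.e. "less than 97\% identity with the closest known species").
#' Missing identities yield `NA` with a warning: the OTU is excluded from
#' this criterion, not failed or passed.
#'
#' @param identity numeric vector of best-hit identities in `[0, 1]`.
#' @param threshold strict cutoff (default 0.97).
#' @return logical vector (with `NA` for missing identities).
#' @export
flag_novelty <- function(identity, threshold = 0.97) {
  if (any(is.na(identity)))
    warning(sum(is.na(identity)),
            " OTU(s) lack a best-hit identity; excluded from the novelty",
            " criterion")
  identity < threshold
}

#' Tissue-specificity criterion
#'
#' TRUE iff the OTU is present (count >= 1) in at least one target-tissue
#' library or collection and absent from every non-target-tissue library.
#'
#' @param counts OTU x library count matrix (single OTUs may be passed as
#'   a 1-row matrix or named vector).
#' @param libraries library metadata (`library_id`, `tissue`).
#' @param target_tissues default taproot and lateral root.
#' @return logical vector over OTUs.
#' @export
flag_tissue_specificity <- function(counts, libraries,
                                    target_tissues = BELOW_GROUND_TISSUES) {
  counts <- rbind(counts)[, libraries$library_id, drop = FALSE]
  target <- libraries$tissue %in% target_tissues
  present <- counts >= 1
  rowSums(present[, !target, drop = FALSE]) == 0 &
    rowSums(present[, target, drop = FALSE]) > 0
}

#' Persistence criterion
#'
#' TRUE iff, for at least one below-ground tissue, the OTU is present
#' (count >= 1) under every fertilization condition observed for that
#' tissue, pooling clone libraries and isolate collections per condition
#' ("stable presence regardless of fertilizer application conditions").
#'
#' @inheritParams flag_tissue_specificity
#' @param tissues tissues over which persistence may be established.
#' @return logical vector over OTUs.
#' @export
flag_persistence <- function(counts, libraries,
                             tissues = BELOW_GROUND_TISSUES) {
  counts <- rbind(counts)[, libraries$library_id, drop = FALSE]
  out <- rep(FALSE, nrow(counts))
  for (tis in tissues) {
    sel <- libraries$tissue == tis
    if (!any(sel)) next
    conds <- unique(libraries$condition[sel])
    ok <- rep(TRUE, nrow(counts))
    for (cc in conds) {
      cols <- sel & libraries$condition == cc
      ok <- ok & rowSums(counts[, cols, drop = FALSE] >= 1) > 0
    }
    out <- out | ok
  }
  out
}

#' Abundance criterion
#'
#' TRUE iff the OTU exceeds the threshold (strictly; default 1\%) in at
#' least one single below-ground library or collection.
#'
#' @param frac OTU x library matrix of relative abundances (fractions).
#' @param libraries library metadata.
#' @param threshold strict relative-abundance cutoff (default 0.01).
#' @param tissues libraries considered (default below-ground).
#' @return logical vector over OTUs.
#' @export
flag_abundance <- function(frac, libraries, threshold = 0.01,
                           tissues = BELOW_GROUND_TISSUES) {
  frac <- rbind(frac)[, libraries$library_id, drop = FALSE]
  cols <- libraries$tissue %in% tissues
  rowSums(frac[, cols, drop = FALSE] > threshold) > 0
}

#' Reference-list criteria: known PGPB inclusion and pathogen exclusion
#'
#' The PGPB list is matched at the genus level (first word of the best-hit
#' taxon).  The pathogen list is matched per entry: single-word entries
#' match the genus, two-word entries the full species name
#' (`pathogen_match = "genus"` forces genus-level matching throughout).
#' OTUs without a best hit are neither included nor excluded.
#'
#' @param best_hit_taxon character vector of best-hit taxon names
#'   ("Genus species" or "Genus").
#' @param known_pgpb_genera character vector of PGPB genera.
#' @param pathogen_taxa character vector of pathogen species or genera.
#' @param pathogen_match `"species"` (default) or `"genus"`.
#' @return data frame with logical columns `known_pgpb` and
#'   `pathogen_excluded` (TRUE = safe to keep).
#' @export
flag_reference_lists <- function(best_hit_taxon,
                                 known_pgpb_genera = character(),
                                 pathogen_taxa = character(),
                                 pathogen_match = c("species", "genus")) {
  pathogen_match <- match.arg(pathogen_match)
  genus <- sub("\\s.*$", "", best_hit_taxon)
  known <- !is.na(genus) & genus %in% known_pgpb_genera
  pg_genus <- sub("\\s.*$", "", pathogen_taxa)
  single <- pathogen_taxa == pg_genus
  if (pathogen_match == "genus") {
    hit <- !is.na(genus) & genus %in% pg_genus
  } else {
    hit <- (!is.na(best_hit_taxon) & best_hit_taxon %in% pathogen_taxa) |
      (!is.na(genus) & genus %in% pg_genus[single])
  }
  data.frame(known_pgpb = known, pathogen_excluded = !hit)
}

#' Evaluate all selection criteria over an evidence set
#'
#' @param evidence an `otu_evidence` (see [build_otu_evidence()]).
#' @param config selection configuration (see
#'   [default_selection_config()]).
#' @return data frame (one row per OTU) with the individual criterion
#'   flags, `has_isolate`, `pathogen_excluded`, the combined `selected`
#'   flag and a `rationale` string listing the satisfied criteria.
#' @export
evaluate_selection <- function(evidence, config = default_selection_config()) {
  info <- evidence$info
  novelty <- suppressWarnings(
    flag_novelty(info$best_hit_identity, config$novelty_threshold))
  if (any(is.na(novelty)))
    warning(sum(is.na(novelty)), " OTU(s) lack a best-hit identity; ",
            "excluded from the novelty criterion")
  tissue <- flag_tissue_specificity(evidence$counts, evidence$libraries,
                                    config$target_tissues)
  persistence <- flag_persistence(evidence$counts, evidence$libraries,
                                  config$target_tissues)
  abundance <- flag_abundance(evidence$frac, evidence$libraries,
                              config$abundance_threshold,
                              config$target_tissues)
  refs <- flag_reference_lists(info$best_hit_taxon,
                               config$known_pgpb_genera,
                               config$pathogen_taxa,
                               config$pathogen_match)
  novelty_eff <- !is.na(novelty) & novelty
  any_criterion <- novelty_eff | tissue | persistence | abundance |
    refs$known_pgpb
  selected <- any_criterion & info$has_isolate & refs$pathogen_excluded
  crit <- cbind(novelty = novelty_eff, tissue_specificity = tissue,
                persistence = persistence, abundance = abundance,
                known_pgpb = refs$known_pgpb)
  rationale <- apply(crit, 1, function(r)
    paste(colnames(crit)[r], collapse = "+"))
  out <- data.frame(otu_id = info$otu_id, novelty = novelty,
                    tissue_specificity = tissue, persistence = persistence,
                    abundance = abundance, known_pgpb = refs$known_pgpb,
                    pathogen_excluded = refs$pathogen_excluded,
                    has_isolate = info$has_isolate, selected = selected,
                    rationale = rationale, stringsAsFactors = FALSE)
  out[order_otu_ids(out$otu_id), , drop = FALSE]
}

#' Select candidate PGPB isolates
#'
#' Applies [evaluate_selection()] and returns the selected OTUs, each with
#' one representative isolate (see [otu_representative()]) and its
#' rationale.  An empty candidate set is a valid result.
#'
#' @param table an `otu_table_bs` (needed for representative picking; may
#'   be omitted when `evidence` is given and representatives are not
#'   required).
#' @param best_hits best-hit data frame (see [build_otu_evidence()]).
#' @param config selection configuration.
#' @param evidence optionally a prebuilt `otu_evidence`.
#' @param representative_rule passed to [otu_representative()].
#' @return data frame of selected OTUs sorted by OTU id, with columns of
#'   [evaluate_selection()] plus `representative_isolate`.
#' @export
select_candidates <- function(table = NULL, best_hits = NULL,
                              config = default_selection_config(),
                              evidence = NULL,
                              representative_rule = "most_abundant_isolate") {
  evidence <- evidence %||% build_otu_evidence(table, best_hits)
  flags <- evaluate_selection(evidence, config)
  cand <- flags[flags$selected, , drop = FALSE]
  cand$representative_isolate <- NA_character_
  if (!is.null(table) && nrow(cand) > 0)
    cand$representative_isolate <- vapply(
      cand$otu_id, function(o)
        otu_representative(table, o, representative_rule), character(1))
  rownames(cand) <- NULL
  cand
}
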