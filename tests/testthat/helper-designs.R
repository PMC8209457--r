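# Shared fixtures: scaled-down study designs (full default sizes are used
# in the acceptance script; tests use smaller communities at the same
# per-library depths, which the selection guarantees require).

small_design <- function(seed = 1, ...) {
  study_design(n_otus = 40, n_planted_per_role = 2,
               depth_range = c(150, 180), template_length = 600,
               seed = seed, ...)
}

# two tissues / two conditions: small enough to run the clustering stages
tiny_seq_design <- function(seed = 1) {
  study_design(tissues = c("leaf_blade", "lateral_root"),
               conditions = c("NPK", "PK"), collection_conditions = "PK",
               media = c("R2A", "TSA"), n_otus = 15,
               n_planted_per_role = 1, depth_range = c(105, 120),
               template_length = 600, seed = seed)
}

# minimal hand-built ground truth for exercising the samplers directly
toy_truth <- function(weights,
                      tissues = c("leaf_blade", "lateral_root"),
                      conditions = "NPK", media = "R2A",
                      affinity = NULL, culturability = NULL) {
  n <- length(weights)
  ids <- names(weights) %||% paste0("T", seq_len(n))
  aff <- affinity %||% matrix(1, n, length(tissues),
                              dimnames = list(ids, tissues))
  cult <- culturability %||% matrix(1, n, length(media),
                                    dimnames = list(ids, media))
  structure(list(
    otus = data.frame(otu_id = ids, role = "background",
                      base_abundance = unname(weights),
                      identity = 0.99,
                      best_hit_taxon = "Rhizobium soli",
                      stringsAsFactors = FALSE),
    tissue_affinity = aff,
    condition_stability = matrix(1, n, length(conditions),
                                 dimnames = list(ids, conditions)),
    culturability = cult,
    design = list(tissues = tissues, conditions = conditions,
                  media = media)),
    class = "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
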