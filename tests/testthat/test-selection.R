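# The candidate-PGPB selection engine.

clone_libs <- function() {
  t1 <- table1_alpha()
  libs <- t1[t1$provenance == "clone",
             c("library_id", "tissue", "condition", "provenance", "medium")]
  libs$size <- t1$n_sequences[t1$provenance == "clone"]
  libs
}

test_that("novelty is a strict identity threshold", {
  expect_false(flag_novelty(0.98))   # e.g. 98% best hit
  expect_true(flag_novelty(0.96))
  expect_false(flag_novelty(0.97))   # exactly at threshold: not novel
  expect_warning(out <- flag_novelty(c(0.5, NA)), "excluded")
  expect_true(out[1]); expect_true(is.na(out[2]))
})

test_that("tissue specificity requires below-ground-only presence", {
  libs <- clone_libs()
  ev <- table5_evidence()
  expect_true(flag_tissue_specificity(ev$counts["OTU-87", ], libs))
  # OTU-86 is present in leaf blades -> not tissue-specific
  expect_false(flag_tissue_specificity(ev$counts["OTU-86", ], libs))
  none <- setNames(rep(0, nrow(libs)), libs$library_id)
  expect_false(flag_tissue_specificity(none, libs))
})

test_that("persistence means presence under every condition somewhere below", {
  libs <- clone_libs()
  ev <- table5_evidence()
  # OTU-87: taproot 2.6/1.2/0.6 across NPK/PK/K
  expect_true(flag_persistence(ev$counts["OTU-87", ], libs))
  only_npk <- setNames(rep(0, nrow(libs)), libs$library_id)
  only_npk[c("TR-NPK", "LR-NPK")] <- 3
  expect_false(flag_persistence(only_npk, libs))
  # presence in LR under all three conditions via mixed sources
  lr_all <- setNames(rep(0, nrow(libs)), libs$library_id)
  lr_all[c("LR-NPK", "LR-PK", "LR-K")] <- 1
  expect_true(flag_persistence(lr_all, libs))
})

test_that("abundance is a strict >1% single-library criterion below ground", {
  libs <- clone_libs()
  ev <- table5_evidence()
  expect_true(flag_abundance(ev$frac["OTU-87", ], libs))    # 3.3% in LR-K
  uniform <- setNames(rep(0.005, nrow(libs)), libs$library_id)
  expect_false(flag_abundance(uniform, libs))
  exactly_one <- setNames(rep(0, nrow(libs)), libs$library_id)
  exactly_one["LR-K"] <- 0.01
  expect_false(flag_abundance(exactly_one, libs))  # strict inequality
  # above-ground abundance does not count
  above_only <- setNames(rep(0, nrow(libs)), libs$library_id)
  above_only["LB-NPK"] <- 0.2
  expect_false(flag_abundance(above_only, libs))
})

test_that("reference lists include PGPB genera and exclude pathogens", {
  refs <- flag_reference_lists(
    c("Pseudomonas soli", "Pantoea ananatis", "Rhizobium betae", NA),
    known_pgpb_genera = c("Pseudomonas", "Bacillus"),
    pathogen_taxa = c("Pantoea ananatis"))
  expect_equal(refs$known_pgpb, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(refs$pathogen_excluded, c(TRUE, FALSE, TRUE, TRUE))
  # species-level matching spares congeners; genus-level removes them
  sp <- flag_reference_lists("Pseudomonas fluorescens", character(),
                             "Pseudomonas syringae", "species")
  expect_true(sp$pathogen_excluded)
  gn <- flag_reference_lists("Pseudomonas fluorescens", character(),
                             "Pseudomonas syringae", "genus")
  expect_false(gn$pathogen_excluded)
  none <- flag_reference_lists("Rhizobium soli")
  expect_false(none$known_pgpb); expect_true(none$pathogen_excluded)
})

test_that("selection recovers the planted truth exactly over 20 seeds", {
  for (s in 1:20) {
    st <- simulate_study(small_design(seed = s), noiseless = TRUE,
                         sequences = FALSE)
    tab <- truth_otu_table(st)
    cand <- suppressWarnings(select_candidates(tab, st$best_hits))
    planted <- planted_candidates(st$truth)
    expect_setequal(cand$otu_id, planted)
    # every candidate carries a representative isolate and a rationale
    expect_false(any(is.na(cand$representative_isolate)))
    expect_true(all(nchar(cand$rationale) > 0))
    # pathogen-like OTUs are never selected
    bad <- st$truth$otus$otu_id[st$truth$otus$role == "pathogen_like"]
    expect_length(intersect(cand$otu_id, bad), 0)
  }
})

test_that("an OTU meeting every criterion but lacking an isolate is dropped", {
  st <- simulate_study(small_design(seed = 3), noiseless = TRUE,
                       sequences = FALSE)
  tab <- truth_otu_table(st)
  ev <- build_otu_evidence(tab, st$best_hits)
  # make one selected OTU clone-only: erase its collection counts
  flags <- suppressWarnings(evaluate_selection(ev))
  pick <- flags$otu_id[flags$selected][1]
  iso_cols <- tab$libraries$library_id[tab$libraries$provenance == "isolate"]
  tab$counts[pick, iso_cols] <- 0L
  ev2 <- build_otu_evidence(tab, st$best_hits)
  flags2 <- suppressWarnings(evaluate_selection(ev2))
  expect_false(flags2$selected[flags2$otu_id == pick])
  expect_false(flags2$has_isolate[flags2$otu_id == pick])
})

test_that("raising thresholds never adds candidates (monotonicity)", {
  st <- simulate_study(small_design(seed = 9), noiseless = TRUE,
                       sequences = FALSE)
  ev <- build_otu_evidence(truth_otu_table(st), st$best_hits)
  cfg <- default_selection_config()
  base <- suppressWarnings(evaluate_selection(ev, cfg))
  for (delta in list(c("abundance_threshold", 0.02),
                     c("novelty_threshold", 0.95))) {
    cfg2 <- cfg
    cfg2[[delta[1]]] <- as.numeric(delta[2])
    tighter <- suppressWarnings(evaluate_selection(ev, cfg2))
    expect_true(all(tighter$otu_id[tighter$selected] %in%
                      base$otu_id[base$selected]))
  }
})

test_that("each criterion depends only on its declared evidence", {
  ev <- table5_evidence()
  base <- suppressWarnings(evaluate_selection(ev))
  prof_cols <- c("tissue_specificity", "persistence", "abundance")
  # mutating best hits must leave the profile-based flags unchanged
  ev2 <- ev
  ev2$info$best_hit_identity <- rep(0.5, nrow(ev2$info))
  ev2$info$best_hit_taxon <- "Rhizobium soli"
  mut <- suppressWarnings(evaluate_selection(ev2))
  expect_identical(mut[prof_cols], base[prof_cols])
  # mutating the abundance profile must leave novelty and the reference
  # flags unchanged
  ev3 <- ev
  ev3$counts[] <- 0L; ev3$frac[] <- 0
  mut3 <- suppressWarnings(evaluate_selection(ev3))
  ref_cols <- c("novelty", "known_pgpb", "pathogen_excluded")
  expect_identical(mut3[ref_cols], base[ref_cols])
})
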