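# End-to-end pipeline over a (synthetic) study: simulate -> distances ->
# cluster -> alpha -> tree -> UniFrac/PCoA -> composition -> selection ->
# inoculation, with per-stage outputs, skip/resume on existing files and a
# provenance manifest.

#' Build a pipeline configuration
#'
#' @param out_dir output directory.
#' @param design a [study_design()] describing the synthetic study.
#' @param threshold,linkage clustering parameters (see [cluster_otus()]).
#' @param model,gap_policy distance parameters; the default p-distance
#'   carries the 97\%-identity threshold semantics.
#' @param normalized_unifrac normalize weighted UniFrac distances.
#' @param ranks ranks for the composition report.
#' @param selection selection configuration (see
#'   [default_selection_config()]).
#' @param noiseless use deterministic expected counts in the simulation.
#' @param write_distances also write the full read distance matrix
#'   (PHYLIP; large) next to the partition.
#' @return classed configuration list.
#' @export
pipeline_config <- function(out_dir, design = study_design(),
                            threshold = 0.03, linkage = "furthest",
                            model = "p", gap_policy = "pairwise",
                            normalized_unifrac = FALSE,
                            ranks = c("phylum", "genus"),
                            selection = default_selection_config(),
                            noiseless = FALSE, write_distances = FALSE) {
  stopifnot(inherits(design, "study_design"),
            threshold >= 0, threshold <= 1,
            linkage %in% c("furthest", "nearest", "average"),
            model %in% c("p", "jukes_cantor"))
  structure(list(out_dir = out_dir, design = design, threshold = threshold,
                 linkage = linkage, model = model, gap_policy = gap_policy,
                 normalized_unifrac = normalized_unifrac, ranks = ranks,
                 selection = selection, noiseless = noiseless,
                 write_distances = write_distances),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Stages are skipped when their outputs already exist and no upstream
#' stage was rerun; deleting an intermediate file therefore reruns only
#' that stage and everything downstream.  A `manifest.json` with the
#' configuration, seed, stage status and output checksums is written at
#' the end; all outputs are a pure function of configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param force rerun every stage regardless of existing outputs.
#' @return invisibly, a list with the in-memory stage results (`study`,
#'   `partition`, `table`, `alpha`, `tree`, `unifrac`, `pcoa`,
#'   `composition`, `candidates`, `effects`) and the manifest.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(
    df, file.path(out, name), sep = "\t", quote = FALSE, row.names = FALSE)
  have <- function(...) all(file.exists(file.path(out, c(...))))
  ran <- c()

  # simulate ----------------------------------------------------------
  study <- simulate_study(config$design, noiseless = config$noiseless)
  sim_files <- c("sequences.fasta", "metadata.tsv", "counts.tsv",
                 "libraries.tsv", "best_hits.tsv", "inoculation.tsv",
                 "taxonomy.tsv", "truth.json")
  if (force || !have(sim_files)) {
    write_study(study, out)
    ran["simulate"] <- TRUE
  } else ran["simulate"] <- FALSE

  # distances + clustering -------------------------------------------
  clu_files <- c("partition.tsv", "otutable.tsv")
  if (force || ran["simulate"] || !have(clu_files)) {
    d <- distance_matrix(study$sequences, model = config$model,
                         gap_policy = config$gap_policy)
    if (config$write_distances)
      write_phylip_square(d, file.path(out, "dist.phylip"))
    partition <- cluster_otus(d, threshold = config$threshold,
                              linkage = config$linkage)$assignment
    tsv(data.frame(sequence_id = names(partition),
                   otu_id = unname(partition)), "partition.tsv")
    ran["cluster"] <- TRUE
  } else {
    p <- read.delim(file.path(out, "partition.tsv"),
                    stringsAsFactors = FALSE)
    partition <- setNames(p$otu_id, p$sequence_id)
    ran["cluster"] <- FALSE
  }
  table <- build_otu_table(partition, study$seq_library, study$libraries)
  if (ran["cluster"] || force || !have("otutable.tsv"))
    tsv(data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE), "otutable.tsv")

  # alpha diversity ---------------------------------------------------
  alpha <- alpha_summary(table)
  if (force || ran["cluster"] || !have("alpha.tsv")) {
    tsv(alpha, "alpha.tsv")
    ran["alpha"] <- TRUE
  } else ran["alpha"] <- FALSE

  # representative tree ----------------------------------------------
  reps <- vapply(names(table$members), function(o)
    otu_representative(table, o, "smallest_id", require_isolate = FALSE),
    character(1))
  if (force || ran["cluster"] || !have("tree.nwk")) {
    dr <- distance_matrix(setNames(study$sequences[reps],
                                   names(reps)),
                          model = config$model)
    tree <- midpoint_root(nj_tree(dr))
    cat(write_newick(tree), "\n", sep = "", file = file.path(out, "tree.nwk"))
    ran["tree"] <- TRUE
  } else {
    tree <- read_newick(paste(readLines(file.path(out, "tree.nwk")),
                              collapse = ""))
    ran["tree"] <- FALSE
  }

  # beta diversity ----------------------------------------------------
  uf <- unifrac_matrix(tree, table,
                       normalized = config$normalized_unifrac)
  ord <- pcoa_ordination(uf)
  if (force || ran["tree"] || !have("pcoa_coordinates.tsv")) {
    write_phylip_square(uf, file.path(out, "unifrac.phylip"))
    tsv(data.frame(library_id = rownames(ord$coordinates),
                   ord$coordinates, check.names = FALSE),
        "pcoa_coordinates.tsv")
    tsv(data.frame(axis = seq_along(ord$percent_explained),
                   percent_explained = ord$percent_explained),
        "pcoa_eigen.tsv")
    ran["pcoa"] <- TRUE
  } else ran["pcoa"] <- FALSE

  # composition -------------------------------------------------------
  metadata <- data.frame(sequence_id = names(study$seq_library),
                         library_id = unname(study$seq_library),
                         stringsAsFactors = FALSE)
  comp <- composition_report(study$taxonomy, metadata, study$libraries,
                             ranks = config$ranks)
  comp_files <- paste0("composition_", config$ranks, ".tsv")
  if (force || ran["simulate"] || !have(comp_files)) {
    for (rk in config$ranks)
      tsv(comp[[rk]], paste0("composition_", rk, ".tsv"))
    ran["composition"] <- TRUE
  } else ran["composition"] <- FALSE

  # selection ---------------------------------------------------------
  # best hits are known per ground-truth OTU; map them onto the
  # clustered OTUs through their member sequences
  hit_of <- function(o) {
    gt <- unique(study$seq_otu[table$members[[o]]])
    study$best_hits[match(gt[1], study$best_hits$otu_id), ]
  }
  bh <- do.call(rbind, lapply(names(table$members), hit_of))
  bh$otu_id <- names(table$members)
  candidates <- suppressWarnings(
    select_candidates(table, bh, config$selection))
  if (force || ran["cluster"] || !have("candidates.tsv")) {
    tsv(candidates, "candidates.tsv")
    ran["selection"] <- TRUE
  } else ran["selection"] <- FALSE

  # inoculation -------------------------------------------------------
  effects <- evaluate_inoculation(study$inoculation)
  if (force || ran["simulate"] || !have("effects.tsv")) {
    tsv(effects, "effects.tsv")
    ran["inoculation"] <- TRUE
  } else ran["inoculation"] <- FALSE

  files <- setdiff(list.files(out), "manifest.json")
  manifest <- list(package = "beetscreen",
                   version = as.character(utils::packageVersion("beetscreen")),
                   seed = config$design$seed,
                   stages_rerun = as.list(ran),
                   config = list(threshold = config$threshold,
                                 linkage = config$linkage,
                                 model = config$model,
                                 normalized_unifrac =
                                   config$normalized_unifrac),
                   md5 = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(study = study, partition = partition, table = table,
                 alpha = alpha, tree = tree, unifrac = uf, pcoa = ord,
                 composition = comp, candidates = candidates,
                 effects = effects, manifest = manifest))
}
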