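# Synthetic-study generator with planted ground truth.  Emulates the
# design of the field study this package operationalises: 12 clone
# libraries (4 tissues x 3 fertilization plots) and 4 lateral-root isolate
# collections (2 plots x 2 media), with tissue-structured and
# condition-structured OTU abundances, medium-dependent culturability bias,
# and planted OTUs constructed to satisfy each selection criterion (or to
# satisfy none, for background OTUs) so that pipeline recovery can be
# scored exactly.

TISSUE_ABBREV <- c(leaf_blade = "LB", petiole = "PE",
                   taproot = "TR", lateral_root = "LR")

CANDIDATE_ROLES <- c("novel", "tissue_specific", "persistent",
                     "abundant", "known_pgpb")

# genus -> lineage pool used for synthetic taxonomy.  "pool" marks whether
# the genus may be used for background OTUs ("neutral"), is reserved for
# planted known-PGPB OTUs ("pgpb") or appears in pathogen best hits
# ("pathogen"); neutral genera never collide with the shipped reference
# lists.
lineage_pool <- function() {
  read.delim(system.file("extdata", "lineage_pool.tsv",
                         package = "beetscreen", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Define a synthetic study design
#'
#' Defaults mirror the field design: four tissues by three fertilization
#' conditions for the clone libraries, lateral-root isolate collections on
#' two media under the two nutrient-limited conditions, and library depths
#' drawn once (from the seed) between 150 and 180 sequences.
#'
#' @param tissues ordered tissue labels.
#' @param conditions ordered fertilization conditions.
#' @param media isolation media for the collections.
#' @param collection_conditions conditions under which collections exist.
#' @param depth_range inclusive range from which per-library depths are
#'   drawn (both clone libraries and collections).
#' @param n_otus number of ground-truth OTUs.
#' @param n_planted_per_role planted OTUs per selection role.
#' @param template_length alignment columns of the sequence template
#'   (>= 500).
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `study_design`.
#' @export
study_design <- function(tissues = c("leaf_blade", "petiole", "taproot",
                                     "lateral_root"),
                         conditions = c("NPK", "PK", "K"),
                         media = c("R2A", "TSA"),
                         collection_conditions = c("PK", "K"),
                         depth_range = c(150, 180),
                         n_otus = 250, n_planted_per_role = 2,
                         template_length = 800, seed = 1) {
  if (length(tissues) == 0 || length(conditions) == 0)
    stop("tissues and conditions must be non-empty")
  if (any(depth_range <= 0)) stop("depths must be positive")
  if (n_otus < 6 * n_planted_per_role + 1)
    stop("n_otus too small for the requested planted roles (need > ",
         6 * n_planted_per_role, ")")
  abbrev <- TISSUE_ABBREV[tissues]
  if (any(is.na(abbrev))) abbrev <- toupper(substr(tissues, 1, 2))
  clone_ids <- as.vector(t(outer(abbrev, conditions, paste, sep = "-")))
  coll_ids <- as.vector(t(outer(
    paste0(abbrev[length(abbrev)], "-", collection_conditions),
    substr(media, 1, 1), paste, sep = "-")))
  set.seed(stage_seed(seed, "misc"))
  clone_depths <- setNames(
    sample(seq(depth_range[1], depth_range[2]), length(clone_ids),
           replace = TRUE), clone_ids)
  collection_depths <- setNames(
    sample(seq(depth_range[1], depth_range[2]), length(coll_ids),
           replace = TRUE), coll_ids)
  structure(list(tissues = tissues, conditions = conditions, media = media,
                 collection_conditions = collection_conditions,
                 clone_depths = clone_depths,
                 collection_depths = collection_depths,
                 n_otus = n_otus, n_planted_per_role = n_planted_per_role,
                 template_length = template_length, seed = seed),
            class = "study_design")
}

# Library metadata table implied by a design.
design_libraries <- function(design) {
  abbrev <- TISSUE_ABBREV[design$tissues]
  clone <- expand.grid(condition = design$conditions,
                       tissue = design$tissues, stringsAsFactors = FALSE)
  clone <- clone[order(match(clone$tissue, design$tissues)), ]
  clone_ids <- paste0(abbrev[clone$tissue], "-", clone$condition)
  coll <- expand.grid(medium = design$media,
                      condition = design$collection_conditions,
                      stringsAsFactors = FALSE)
  coll <- coll[order(match(coll$condition, design$collection_conditions)), ]
  lr <- design$tissues[length(design$tissues)]
  coll_ids <- paste0(abbrev[lr], "-", coll$condition, "-",
                     substr(coll$medium, 1, 1))
  rbind(
    data.frame(library_id = clone_ids, tissue = clone$tissue,
               condition = clone$condition, provenance = "clone",
               medium = NA_character_,
               depth = unname(design$clone_depths[clone_ids]),
               stringsAsFactors = FALSE),
    data.frame(library_id = coll_ids, tissue = lr,
               condition = coll$condition, provenance = "isolate",
               medium = coll$medium,
               depth = unname(design$collection_depths[coll_ids]),
               stringsAsFactors = FALSE))
}

# Expected relative-abundance share of every OTU in every library of the
# design (columns = libraries, including collections).
expected_shares <- function(truth, libraries) {
  n <- nrow(truth$otus)
  S <- matrix(0, n, nrow(libraries),
              dimnames = list(truth$otus$otu_id, libraries$library_id))
  for (i in seq_len(nrow(libraries))) {
    w <- truth$otus$base_abundance *
      truth$tissue_affinity[, libraries$tissue[i]] *
      truth$condition_stability[, libraries$condition[i]]
    if (libraries$provenance[i] == "isolate")
      w <- w * truth$culturability[, libraries$medium[i]]
    if (sum(w) > 0) S[, i] <- w / sum(w)
  }
  S
}

#' Plant the ground truth of a synthetic study
#'
#' Draws log-normal base abundances (sd 1.5 on the log scale, reproducing
#' a long-tailed rank-abundance curve), tissue- and condition-structured
#' multipliers, per-medium culturability, best-hit identities and taxon
#' names, and assigns planted roles: `n_planted_per_role` OTUs per
#' selection criterion (novel, tissue-specific, persistent, abundant,
#' known-PGPB) plus pathogen-like OTUs that must be excluded, one OTU that
#' is unculturable on every medium yet present in clone libraries, and
#' background OTUs constructed to satisfy no criterion (their expected
#' below-ground share is capped under the abundance threshold and one
#' fertilization condition is zeroed for every culturable background OTU,
#' breaking persistence).  Role contracts are enforced on expected
#' abundances by an iterative rescaling of base weights.
#'
#' @param design a [study_design()].
#' @return object of class `ground_truth`: list with `otus` (data frame:
#'   `otu_id`, `role`, `genus`, `base_abundance`, `identity`,
#'   `best_hit_taxon`), matrices `tissue_affinity` (OTU x tissue),
#'   `condition_stability` (OTU x condition), `culturability`
#'   (OTU x medium), and the `design`.
#' @export
plant_truth <- function(design) {
  set.seed(stage_seed(design$seed, "truth"))
  n <- design$n_otus
  k <- design$n_planted_per_role
  roles <- c(rep(CANDIDATE_ROLES, each = k), rep("pathogen_like", k),
             "unculturable", rep("background", n - 6 * k - 1))
  ids <- sprintf("T%03d", seq_len(n))
  planted <- roles %in% c(CANDIDATE_ROLES, "pathogen_like")

  base <- rlnorm(n, 0, 1.5)
  bg <- which(roles == "background")
  culturable_bg <- bg[rbinom(length(bg), 1, 0.4) == 1]

  tiss <- design$tissues
  nt <- length(tiss)
  aff <- matrix(runif(n * nt, 0.3, 1.2), n, nt,
                dimnames = list(ids, tiss))
  habitat <- sample(c("above", "below", "generalist"), n, replace = TRUE,
                    prob = c(0.3, 0.45, 0.25))
  above <- tiss[seq_len(max(1, floor(nt / 2)))]
  below <- setdiff(tiss, above)
  aff[habitat == "above", below] <- runif(sum(habitat == "above") *
                                            length(below), 0, 0.08)
  aff[habitat == "above", above] <- runif(sum(habitat == "above") *
                                            length(above), 0.6, 1.5)
  aff[habitat == "below", above] <- runif(sum(habitat == "below") *
                                            length(above), 0, 0.08)
  aff[habitat == "below", below] <- runif(sum(habitat == "below") *
                                            length(below), 0.6, 1.5)
  # planted OTUs live below ground so that they can be isolated
  aff[planted, above] <- runif(sum(planted) * length(above), 0, 0.05)
  aff[planted, below] <- runif(sum(planted) * length(below), 0.6, 1.5)
  aff[roles == "tissue_specific", above] <- 0
  aff[roles == "unculturable", above] <- 0
  # equal affinity across below-ground tissues keeps its expected counts
  # in a common band under the background cap
  aff[roles == "unculturable", below] <- runif(1, 0.8, 1.5)
  # culturable background OTUs must not look tissue-specific: their
  # above-ground affinity dominates so that above-ground presence is
  # guaranteed once they are detectable below ground
  aff[culturable_bg, below] <- runif(length(culturable_bg) *
                                       length(below), 0.4, 0.8)
  aff[culturable_bg, above] <- runif(length(culturable_bg) *
                                       length(above), 3.5, 5.0)

  conds <- design$conditions
  stab <- matrix(runif(n * length(conds), 0.7, 1.3), n, length(conds),
                 dimnames = list(ids, conds))
  stab[roles == "persistent", ] <- 1
  # a culturable background OTU must not look persistent: it loses one
  # fertilization condition entirely (needs >= 2 conditions to matter)
  if (length(conds) > 1)
    stab[cbind(culturable_bg,
               sample(length(conds), length(culturable_bg),
                      replace = TRUE))] <- 0

  media <- design$media
  cult <- matrix(0, n, length(media), dimnames = list(ids, media))
  cult[planted, ] <- runif(sum(planted) * length(media), 0.6, 1)
  reduce <- planted & rbinom(n, 1, 0.3) == 1
  cult[cbind(which(reduce),
             sample(length(media), sum(reduce), replace = TRUE))] <-
    runif(sum(reduce), 0.25, 0.5)
  pattern <- sample(c("both", media), length(culturable_bg),
                    replace = TRUE, prob = c(0.5, rep(0.5 / length(media),
                                                      length(media))))
  for (j in seq_along(culturable_bg)) {
    m <- if (pattern[j] == "both") media else pattern[j]
    cult[culturable_bg[j], m] <- runif(length(m), 0.3, 1)
  }

  identity <- runif(n, 0.975, 0.999)
  identity[roles == "novel"] <- runif(sum(roles == "novel"), 0.90, 0.965)

  pool <- lineage_pool()
  neutral <- pool$genus[pool$pool == "neutral"]
  pgpb <- pool$genus[pool$pool == "pgpb"]
  pathog <- pool[pool$pool == "pathogen", ]
  genus <- sample(neutral, n, replace = TRUE)
  genus[roles == "known_pgpb"] <- sample(pgpb, sum(roles == "known_pgpb"),
                                         replace = TRUE)
  path_idx <- sample(nrow(pathog), sum(roles == "pathogen_like"),
                     replace = TRUE)
  genus[roles == "pathogen_like"] <- pathog$genus[path_idx]
  epithets <- c("soli", "terrae", "radicis", "rhizosphaerae", "agri",
                "betae", "hortense", "arvi", "campestre", "humi")
  best_hit <- paste(genus, sample(epithets, n, replace = TRUE))
  best_hit[roles == "pathogen_like"] <- pathog$species[path_idx]

  truth <- list(otus = data.frame(otu_id = ids, role = roles, genus = genus,
                                  base_abundance = base,
                                  identity = identity,
                                  best_hit_taxon = best_hit,
                                  stringsAsFactors = FALSE),
                tissue_affinity = aff, condition_stability = stab,
                culturability = cult, design = design)
  class(truth) <- "ground_truth"
  enforce_role_contracts(truth)
}

# Iteratively rescale base abundances so that the planted-role contracts
# hold on expected (noiseless) library compositions:
#  * background/unculturable OTUs stay under one expected sequence in
#    every below-ground library or collection (hence under the 1%
#    abundance criterion and never spuriously "abundant"),
#  * planted candidates and pathogen-like OTUs reach ~2 expected isolates
#    in every collection (guaranteed isolation),
#  * persistent OTUs additionally reach ~2 expected clones in the deepest
#    below-ground clone library of every condition,
#  * the unculturable OTU keeps a sizeable expected clone presence.
enforce_role_contracts <- function(truth, max_iter = 1500) {
  design <- truth$design
  libraries <- design_libraries(design)
  below <- libraries$tissue %in%
    design$tissues[-seq_len(max(1, floor(length(design$tissues) / 2)))]
  bg_cols <- which(below)
  above_clone_cols <- which(!below & libraries$provenance == "clone")
  coll_cols <- which(libraries$provenance == "isolate")
  lr <- design$tissues[length(design$tissues)]
  lr_clone_cols <- which(libraries$tissue == lr &
                           libraries$provenance == "clone")
  depth <- libraries$depth
  roles <- truth$otus$role
  is_bg <- roles %in% c("background", "unculturable")
  is_cand <- roles %in% c(CANDIDATE_ROLES, "pathogen_like")
  is_pers <- roles == "persistent"
  is_uncult <- roles == "unculturable"
  is_cbg <- roles == "background" & rowSums(truth$culturability) > 0

  adjust <- function(base, rows, factor) {
    base[rows] <- base[rows] * factor
    base
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    S <- expected_shares(truth, libraries)
    E <- sweep(S, 2, depth, "*")  # expected counts
    b <- truth$otus$base_abundance
    changed <- FALSE
    # caps: background expected counts stay below one, below ground
    viol <- apply(E[is_bg, bg_cols, drop = FALSE], 1, max) / 0.9
    if (any(viol > 1.001)) {
      b <- adjust(b, which(is_bg)[viol > 1.001],
                  1 / (1.02 * viol[viol > 1.001]))
      changed <- TRUE
    }
    # floors: candidates reach ~2 expected isolates in every collection
    if (length(coll_cols)) {
      fl <- apply(E[is_cand, coll_cols, drop = FALSE], 1, min) / 1.9
      if (any(fl < 0.999)) {
        b <- adjust(b, which(is_cand)[fl < 0.999],
                    pmin(1.02 / pmax(fl[fl < 0.999], 1e-6), 4))
        changed <- TRUE
      }
    }
    # floors: persistent OTUs present in LR clone libraries per condition
    if (any(is_pers) && length(lr_clone_cols)) {
      fl <- apply(E[is_pers, lr_clone_cols, drop = FALSE], 1, min) / 1.9
      if (any(fl < 0.999)) {
        b <- adjust(b, which(is_pers)[fl < 0.999],
                    pmin(1.02 / pmax(fl[fl < 0.999], 1e-6), 4))
        changed <- TRUE
      }
    }
    # the unculturable OTU keeps expected clone presence near the cap
    if (any(is_uncult) && length(lr_clone_cols)) {
      e <- max(E[is_uncult, lr_clone_cols])
      if (e < 0.45) {
        b <- adjust(b, which(is_uncult), 0.7 / max(e, 1e-6))
        changed <- TRUE
      }
    }
    truth$otus$base_abundance <- b
    if (!changed) { converged <- TRUE; break }
  }
  # floors: culturable background OTUs keep guaranteed above-ground
  # presence (so they can never look tissue-specific).  These act on the
  # above-ground affinities only, leaving every below-ground constraint
  # untouched.
  if (any(is_cbg) && length(above_clone_cols)) {
    above_tis <- unique(libraries$tissue[above_clone_cols])
    for (iter in seq_len(500)) {
      S <- expected_shares(truth, libraries)
      E <- sweep(S, 2, depth, "*")
      fl <- apply(E[is_cbg, above_clone_cols, drop = FALSE], 1, max) / 1.15
      if (all(fl >= 0.999)) break
      rows <- which(is_cbg)[fl < 0.999]
      truth$tissue_affinity[rows, above_tis] <-
        truth$tissue_affinity[rows, above_tis] *
        pmin(1.02 / pmax(fl[fl < 0.999], 1e-6), 4)
    }
  }
  # verify the hard contracts themselves (expected-count form); the loop
  # may legitimately oscillate inside the tolerance bands
  S <- expected_shares(truth, libraries)
  E <- sweep(S, 2, depth, "*")
  bad <- character(0)
  if (max(E[is_bg, bg_cols, drop = FALSE]) >= 1)
    bad <- c(bad, "background below-ground cap")
  if (length(coll_cols) && any(is_cand) &&
        min(apply(E[is_cand, coll_cols, drop = FALSE], 1, min)) < 1)
    bad <- c(bad, "candidate isolation floor")
  if (any(is_pers) && length(lr_clone_cols) &&
        min(apply(E[is_pers, lr_clone_cols, drop = FALSE], 1, min)) < 1)
    bad <- c(bad, "persistence floor")
  if (any(is_cbg) && length(above_clone_cols) &&
        min(apply(E[is_cbg, above_clone_cols, drop = FALSE], 1, max)) < 1)
    bad <- c(bad, "background above-ground floor")
  if (length(bad))
    warning("role contracts not satisfied after ", max_iter,
            " iterations: ", paste(bad, collapse = ", "))
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground truth:", nrow(x$otus), "OTUs (",
      sum(x$otus$role != "background"), "planted )\n")
  print(table(x$otus$role))
  invisible(x)
}

#' Planted candidate OTUs of a ground truth
#'
#' The OTUs whose roles make them true positives of the selection screen
#' (novel, tissue-specific, persistent, abundant, known-PGPB; pathogen-like
#' OTUs are planted but must be excluded).
#'
#' @param truth a `ground_truth`.
#' @return character vector of OTU ids.
#' @export
planted_candidates <- function(truth) {
  truth$otus$otu_id[truth$otus$role %in% CANDIDATE_ROLES]
}

#' Draw one clone library
#'
#' Multinomial draw of `depth` sequences with probabilities proportional
#' to `base_abundance * tissue_affinity[tissue] *
#' condition_stability[condition]`; with `noiseless = TRUE` the
#' deterministic largest-remainder apportionment is used instead.
#'
#' @param truth a `ground_truth`.
#' @param tissue,condition labels present in the design.
#' @param depth number of sequences (> 0).
#' @param seed RNG seed (ignored when noiseless).
#' @param noiseless deterministic expected counts.
#' @return named integer vector of per-OTU counts summing to `depth`.
#' @export
draw_library <- function(truth, tissue, condition, depth, seed = 1,
                         noiseless = FALSE) {
  if (depth <= 0) stop("depth must be positive")
  w <- truth$otus$base_abundance * truth$tissue_affinity[, tissue] *
    truth$condition_stability[, condition]
  if (sum(w) == 0)
    stop("all OTU weights are zero for ", tissue, "/", condition)
  p <- w / sum(w)
  counts <- if (noiseless) apportion(p, depth) else {
    set.seed(seed)
    as.integer(rmultinom(1, depth, p))
  }
  setNames(counts, truth$otus$otu_id)
}

#' Draw one isolate collection
#'
#' As [draw_library()] for the lateral-root community, with probabilities
#' additionally weighted by per-medium culturability (colonies picked at
#' random from plates).
#'
#' @inheritParams draw_library
#' @param medium isolation medium label.
#' @param n_isolates number of colonies picked (> 0).
#' @return named integer vector of per-OTU counts summing to
#'   `n_isolates`.
#' @export
draw_isolate_collection <- function(truth, condition, medium, n_isolates,
                                    seed = 1, noiseless = FALSE) {
  if (n_isolates <= 0) stop("n_isolates must be positive")
  lr <- truth$design$tissues[length(truth$design$tissues)]
  w <- truth$otus$base_abundance * truth$tissue_affinity[, lr] *
    truth$condition_stability[, condition] *
    truth$culturability[, medium]
  if (sum(w) == 0)
    stop("no OTU is culturable on ", medium, " under ", condition)
  p <- w / sum(w)
  counts <- if (noiseless) apportion(p, n_isolates) else {
    set.seed(seed)
    as.integer(rmultinom(1, n_isolates, p))
  }
  setNames(counts, truth$otus$otu_id)
}

#' Emit aligned sequences for a synthetic study
#'
#' Builds a random template of `template_length` columns, derives one
#' representative per OTU by substituting a fixed number of random
#' positions (enough that every inter-representative p-distance exceeds
#' 0.055, re-drawing on collision), then emits one read per counted
#' sequence as a representative copy with at most `0.012 *
#' template_length` additional substitutions.  Intra-OTU read distances
#' therefore stay below 0.025 and inter-OTU read distances above 0.03, so
#' clustering at 0.03 recovers the planted partition exactly.  No indels
#' are introduced: rows are already aligned.
#'
#' @param truth a `ground_truth`.
#' @param read_counts OTU x library integer matrix (e.g. the `counts` of
#'   [simulate_study()]).
#' @param seed master seed.
#' @return list with `template`, `representatives` (named by OTU),
#'   `reads` (named character vector), `seq_library` and `seq_otu` maps.
#' @export
emit_sequences <- function(truth, read_counts, seed = 1) {
  L <- truth$design$template_length
  if (L < 500) stop("template length must be >= 500 alignment columns")
  set.seed(stage_seed(seed, "sequences"))
  bases <- c("A", "C", "G", "T")
  template <- sample(bases, L, replace = TRUE)
  n <- nrow(truth$otus)
  k <- ceiling(0.04 * L)
  mutate <- function(x, pos) {
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    x
  }
  reps <- lapply(seq_len(n), function(i)
    mutate(template, sample.int(L, k)))
  rep_mat <- do.call(rbind, reps)
  rownames(rep_mat) <- truth$otus$otu_id
  if (n > 1) {
    for (round in seq_len(60)) {
      d <- distance_matrix(rep_mat, model = "p")
      diag(d) <- 1
      worst <- which(d < 0.055, arr.ind = TRUE)
      if (nrow(worst) == 0) break
      redo <- unique(worst[, 1])[1]
      rep_mat[redo, ] <- mutate(template, sample.int(L, k))
      if (round == 60)
        stop("requested OTU count too large for the template length to ",
             "maintain inter-OTU separation")
    }
  }
  max_sub <- floor(0.012 * L)
  reads <- character(0)
  seq_library <- character(0)
  seq_otu <- character(0)
  for (lib in colnames(read_counts)) {
    counter <- 0L
    prefix <- gsub("-", "", lib)
    for (otu in rownames(read_counts)) {
      cnt <- read_counts[otu, lib]
      if (cnt == 0) next
      for (r in seq_len(cnt)) {
        counter <- counter + 1L
        m <- sample.int(max_sub + 1L, 1L) - 1L
        x <- rep_mat[otu, ]
        if (m > 0) x <- mutate(x, sample.int(L, m))
        id <- sprintf("%s_%04d", prefix, counter)
        reads[id] <- paste(x, collapse = "")
        seq_library[id] <- lib
        seq_otu[id] <- otu
      }
    }
  }
  list(template = paste(template, collapse = ""),
       representatives = setNames(apply(rep_mat, 1, paste, collapse = ""),
                                  truth$otus$otu_id),
       reads = reads, seq_library = seq_library, seq_otu = seq_otu)
}

# Per-sequence taxonomy assignments with rank-wise confidences; a fraction
# of sequences gets a sub-threshold genus confidence to exercise the
# "unclassified <parent>" rollup.
emit_taxonomy <- function(truth, seq_otu, seed = 1) {
  set.seed(stage_seed(seed, "taxonomy"))
  pool <- lineage_pool()
  li <- pool[match(truth$otus$genus, pool$genus), ]
  otu_idx <- match(seq_otu, truth$otus$otu_id)
  ns <- length(seq_otu)
  ranks <- TAXONOMIC_RANKS
  lower <- c(phylum = 0.95, class = 0.93, order = 0.90, family = 0.85,
             genus = 0.82)
  out <- vector("list", length(ranks))
  vague <- runif(ns) < 0.12
  for (r in seq_along(ranks)) {
    rk <- ranks[r]
    conf <- runif(ns, lower[rk], 1)
    if (rk == "genus") conf[vague] <- runif(sum(vague), 0.3, 0.78)
    out[[r]] <- data.frame(sequence_id = names(seq_otu), rank = rk,
                           taxon = li[[rk]][otu_idx], confidence = conf,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emit seedling inoculation records
#'
#' For every isolate in `effect_map` (true mean dry-weight ratio; 1 =
#' null), emits `n_repeats` batches of `n_per_test` treated and
#' `n_per_test` control seedlings.  Each batch has its own multiplicative
#' baseline (log-normal, sd 0.15), and individual dry weights are the
#' batch baseline times the true ratio (treated only) times log-normal
#' noise — so ratio-to-control normalization removes the batch effect
#' exactly in expectation.
#'
#' @param effect_map named numeric vector: isolate id -> true ratio.
#' @param n_per_test seedlings per group per batch (>= 2).
#' @param n_repeats batches (test dates) per isolate.
#' @param noise_sd log-scale sd of per-seedling noise.
#' @param seed RNG seed.
#' @param baseline mean dry weights (mg) of control shoots and roots.
#' @return data frame: `isolate_id`, `batch`, `group`, `shoot_mg`,
#'   `root_mg`.
#' @export
emit_inoculation_records <- function(effect_map, n_per_test = 12,
                                     n_repeats = 3, noise_sd = 0.12,
                                     seed = 1,
                                     baseline = c(shoot = 40, root = 12)) {
  if (n_per_test < 2)
    stop("n_per_test must be at least 2 (Welch t-test undefined)")
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  set.seed(stage_seed(seed, "inoculation"))
  rows <- list()
  for (iso in names(effect_map)) {
    ratio <- effect_map[[iso]]
    for (b in seq_len(n_repeats)) {
      mult <- rlnorm(1, 0, 0.15)
      grp <- function(g, r) data.frame(
        isolate_id = iso, batch = paste0("b", b), group = g,
        shoot_mg = baseline["shoot"] * mult * r *
          rlnorm(n_per_test, 0, noise_sd),
        root_mg = baseline["root"] * mult * r *
          rlnorm(n_per_test, 0, noise_sd),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- grp("control", 1)
      rows[[length(rows) + 1L]] <- grp("treated", ratio)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Runs [plant_truth()], draws every clone library and isolate collection,
#' optionally emits aligned sequences and per-sequence taxonomy, assigns
#' true inoculation effects to the planted candidates (known-PGPB and
#' novel OTUs promote, persistent OTUs inhibit, the rest are neutral) and
#' emits the corresponding seedling records.  Identical `(design, seed)`
#' give byte-identical results.
#'
#' @param design a [study_design()].
#' @param noiseless use deterministic expected counts instead of
#'   multinomial draws.
#' @param sequences emit aligned reads and taxonomy (slower; required for
#'   the clustering stages).
#' @return object of class `synthetic_study`: list with `design`, `truth`,
#'   `libraries`, `counts` (OTU x library), and — when requested —
#'   `sequences`, `seq_library`, `seq_otu`, `taxonomy`; plus `best_hits`,
#'   `effect_map` and `inoculation`.
#' @export
simulate_study <- function(design, noiseless = FALSE, sequences = TRUE) {
  truth <- plant_truth(design)
  libraries <- design_libraries(design)
  counts <- matrix(0L, design$n_otus, nrow(libraries),
                   dimnames = list(truth$otus$otu_id,
                                   libraries$library_id))
  for (i in seq_len(nrow(libraries))) {
    li <- libraries[i, ]
    counts[, i] <- if (li$provenance == "clone")
      draw_library(truth, li$tissue, li$condition, li$depth,
                   seed = stage_seed(design$seed, "library", i),
                   noiseless = noiseless)
    else
      draw_isolate_collection(truth, li$condition, li$medium, li$depth,
                              seed = stage_seed(design$seed, "collection", i),
                              noiseless = noiseless)
  }
  study <- list(design = design, truth = truth, libraries = libraries,
                counts = counts)
  if (sequences) {
    sq <- emit_sequences(truth, counts, seed = design$seed)
    study$sequences <- sq$reads
    study$seq_library <- sq$seq_library
    study$seq_otu <- sq$seq_otu
    study$representatives <- sq$representatives
    study$taxonomy <- emit_taxonomy(truth, sq$seq_otu, seed = design$seed)
  }
  study$best_hits <- data.frame(otu_id = truth$otus$otu_id,
                                identity = truth$otus$identity,
                                closest_taxon = truth$otus$best_hit_taxon,
                                stringsAsFactors = FALSE)
  cand <- truth$otus[truth$otus$role %in% CANDIDATE_ROLES, ]
  ratio <- rep(1, nrow(cand))
  ratio[cand$role %in% c("known_pgpb", "novel")] <- 1.35
  ratio[cand$role == "persistent"] <- 0.72
  study$effect_map <- setNames(ratio, paste0("iso_", cand$otu_id))
  study$inoculation <- emit_inoculation_records(
    study$effect_map, seed = design$seed)
  class(study) <- "synthetic_study"
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic study:", x$design$n_otus, "OTUs,",
      nrow(x$libraries), "libraries,", sum(x$counts), "sequences\n")
  invisible(x)
}

#' Ground-truth OTU table of a synthetic study
#'
#' Builds an `otu_table_bs` directly from the planted counts (bypassing
#' sequence emission and clustering), with members synthesised from the
#' per-library counts when no reads were emitted.
#'
#' @param study a `synthetic_study`.
#' @return an `otu_table_bs` keyed by ground-truth OTU ids.
#' @export
truth_otu_table <- function(study) {
  if (!is.null(study$seq_otu))
    return(build_otu_table(study$seq_otu, study$seq_library,
                           study$libraries))
  counts <- study$counts
  seq_otu <- character(0)
  seq_library <- character(0)
  for (lib in colnames(counts)) {
    prefix <- gsub("-", "", lib)
    nz <- which(counts[, lib] > 0)
    reps <- counts[nz, lib]
    ids <- sprintf("%s_%04d", prefix, seq_len(sum(reps)))
    seq_otu[ids] <- rep(rownames(counts)[nz], reps)
    seq_library[ids] <- lib
  }
  build_otu_table(seq_otu, seq_library, study$libraries)
}

#' Write a synthetic study to disk
#'
#' Emits the aligned reads (FASTA), per-sequence metadata, taxonomy,
#' best-hit and inoculation tables (TSV), the count matrix, and the ground
#' truth (JSON).  Output bytes are a pure function of `(design, seed)`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(study$sequences)) {
    write_fasta(study$sequences, file.path(dir, "sequences.fasta"))
    tsv(data.frame(sequence_id = names(study$seq_library),
                   library_id = unname(study$seq_library),
                   tissue = study$libraries$tissue[
                     match(study$seq_library, study$libraries$library_id)],
                   condition = study$libraries$condition[
                     match(study$seq_library, study$libraries$library_id)],
                   provenance = study$libraries$provenance[
                     match(study$seq_library, study$libraries$library_id)],
                   medium = study$libraries$medium[
                     match(study$seq_library, study$libraries$library_id)],
                   stringsAsFactors = FALSE), "metadata.tsv")
    tsv(study$taxonomy, "taxonomy.tsv")
  }
  counts <- data.frame(otu_id = rownames(study$counts), study$counts,
                       check.names = FALSE, stringsAsFactors = FALSE)
  tsv(counts, "counts.tsv")
  tsv(study$libraries, "libraries.tsv")
  tsv(study$best_hits, "best_hits.tsv")
  tsv(study$inoculation, "inoculation.tsv")
  jsonlite::write_json(
    list(design = unclass(study$design),
         otus = study$truth$otus,
         effect_map = as.list(study$effect_map)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
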