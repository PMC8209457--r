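# Agglomerative OTU clustering and the OTU table.

dmat <- function(v, ids) {
  m <- matrix(v, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  m
}

test_that("degenerate matrices cluster as expected", {
  ids <- paste0("s", 1:4)
  all_far <- dmat(0.5, ids)
  p <- cluster_otus(all_far, threshold = 0.03)
  expect_length(p$otus, 4)
  all_same <- dmat(0, ids)
  p <- cluster_otus(all_same, threshold = 0.03)
  expect_length(p$otus, 1)
  expect_setequal(p$otus[[1]], ids)
})

test_that("a hand-worked 6-sequence matrix clusters correctly", {
  # two tight triplets 0.01 apart internally, 0.2 across; one member of
  # the second triplet 0.05 from its mates exceeds the furthest-linkage
  # threshold and stays separate
  ids <- letters[1:6]
  m <- dmat(0.2, ids)
  m["a", "b"] <- m["b", "a"] <- 0.01
  m["a", "c"] <- m["c", "a"] <- 0.012
  m["b", "c"] <- m["c", "b"] <- 0.015
  m["d", "e"] <- m["e", "d"] <- 0.01
  m["d", "f"] <- m["f", "d"] <- 0.05
  m["e", "f"] <- m["f", "e"] <- 0.05
  p <- cluster_otus(m, threshold = 0.03, linkage = "furthest")
  part <- split(names(p$assignment), p$assignment)
  expect_setequal(lapply(unname(part), sort),
                  list(c("a", "b", "c"), c("d", "e"), "f"))
  # OTU ids ordered by size then smallest member
  expect_equal(sort(p$otus[["OTU-1"]]), c("a", "b", "c"))
})

test_that("clustering agrees with hclust complete linkage", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    x <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(x)) / 4
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    thr <- runif(1, 0.05, 0.2)
    mine <- cluster_otus(d, threshold = thr, linkage = "furthest")
    hc <- stats::cutree(stats::hclust(as.dist(d), method = "complete"),
                        h = thr)
    # same partition up to labelling
    expect_equal(length(mine$otus), length(unique(hc)))
    key_mine <- vapply(split(names(mine$assignment), mine$assignment),
                       function(s) paste(sort(s), collapse = ","),
                       character(1))
    key_hc <- vapply(split(names(hc), hc),
                     function(s) paste(sort(s), collapse = ","),
                     character(1))
    expect_setequal(unname(key_mine), unname(key_hc))
  }
})

test_that("furthest linkage bounds intra-OTU distances by the threshold", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 15
    d <- matrix(runif(n * n, 0, 0.1), n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    p <- cluster_otus(d, threshold = 0.04, linkage = "furthest")
    worst <- max(vapply(p$otus, function(m)
      if (length(m) > 1) max(d[m, m]) else 0, numeric(1)))
    expect_lte(worst, 0.04)
  }
})

test_that("the OTU count is non-increasing in the threshold", {
  set.seed(3)
  n <- 20
  d <- matrix(runif(n * n, 0, 0.1), n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  counts <- vapply(c(0, 0.01, 0.03, 0.05, 0.08, 0.15), function(thr)
    length(cluster_otus(d, threshold = thr)$otus), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the OTU table counts sequences per library correctly", {
  assignment <- c(r1 = "OTU-1", r2 = "OTU-1", r3 = "OTU-2")
  seq_library <- c(r1 = "L1", r2 = "L2", r3 = "L1")
  libs <- data.frame(library_id = c("L1", "L2"),
                     tissue = c("taproot", "lateral_root"),
                     condition = "NPK", provenance = "clone",
                     medium = NA_character_)
  tab <- build_otu_table(assignment, seq_library, libs)
  expect_equal(tab$counts["OTU-1", "L1"], 1L)
  expect_equal(tab$counts["OTU-1", "L2"], 1L)
  expect_equal(tab$counts["OTU-2", "L1"], 1L)
  expect_equal(unname(colSums(tab$counts)), c(2L, 1L))
  expect_equal(sum(tab$counts), 3L)
  expect_error(build_otu_table(assignment, seq_library[1:2], libs),
               "missing from the library map")
})

test_that("provenance classification partitions the OTUs", {
  st <- simulate_study(small_design(seed = 2), noiseless = TRUE,
                       sequences = FALSE)
  tab <- truth_otu_table(st)
  cls <- classify_otus_by_provenance(tab)
  present <- sum(rowSums(tab$counts) > 0)
  expect_equal(sum(cls), present)
  # matches the planted culturability ground truth
  culturable <- rowSums(st$truth$culturability) > 0
  iso_libs <- tab$libraries$library_id[tab$libraries$provenance == "isolate"]
  with_iso <- rowSums(tab$counts[, iso_libs, drop = FALSE]) > 0
  expect_equal(unname(cls["isolate_only"] + cls["both"]), sum(with_iso))
  expect_true(all(names(which(with_iso)) %in%
                    st$truth$otus$otu_id[culturable]))
})

test_that("representatives are deterministic and require isolates", {
  assignment <- c(i1 = "OTU-1", i2 = "OTU-1", c1 = "OTU-1", c2 = "OTU-2")
  seq_library <- c(i1 = "COLL", i2 = "COLL", c1 = "LIB", c2 = "LIB")
  libs <- data.frame(library_id = c("LIB", "COLL"),
                     tissue = "lateral_root", condition = "PK",
                     provenance = c("clone", "isolate"),
                     medium = c(NA, "R2A"))
  tab <- build_otu_table(assignment, seq_library, libs)
  expect_equal(otu_representative(tab, "OTU-1"), "i1")  # smallest id wins tie
  expect_equal(otu_representative(tab, "OTU-1", "smallest_id"), "i1")
  expect_error(otu_representative(tab, "OTU-2"),
               class = "beetscreen_no_isolate")
  expect_equal(otu_representative(tab, "OTU-2", "smallest_id",
                                  require_isolate = FALSE), "c2")
})
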