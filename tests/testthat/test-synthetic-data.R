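# The synthetic-study generator: determinism, conservation, planted-role
# contracts and the sequence geometry.

test_that("identical designs and seeds give byte-identical studies", {
  d1 <- tiny_seq_design(seed = 5)
  d2 <- tiny_seq_design(seed = 5)
  s1 <- simulate_study(d1, noiseless = FALSE)
  s2 <- simulate_study(d2, noiseless = FALSE)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth$otus, s2$truth$otus)
  expect_identical(s1$inoculation, s2$inoculation)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  write_study(s1, out1); write_study(s2, out2)
  for (f in list.files(out1))
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  s3 <- simulate_study(tiny_seq_design(seed = 6))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("library counts sum to the designed depths", {
  for (noiseless in c(TRUE, FALSE)) {
    st <- simulate_study(small_design(seed = 8), noiseless = noiseless,
                         sequences = FALSE)
    expect_equal(unname(colSums(st$counts)), st$libraries$depth)
    expect_true(all(st$counts >= 0))
  }
})

test_that("planted roles are materialised in the truth", {
  des <- small_design(seed = 12)
  tr <- plant_truth(des)
  expect_equal(nrow(tr$otus), 40)
  expect_equal(sum(tr$otus$role != "background"), 13)  # 6 roles x 2 + 1
  expect_equal(as.vector(table(tr$otus$role)[c("novel", "known_pgpb")]),
               c(2L, 2L))
  # novelty identities sit strictly below the threshold, others above
  expect_true(all(tr$otus$identity[tr$otus$role == "novel"] < 0.97))
  expect_true(all(tr$otus$identity[tr$otus$role != "novel"] >= 0.97))
  # one OTU unculturable on every medium
  expect_true(any(rowSums(tr$culturability) == 0 &
                    tr$otus$role == "unculturable"))
  # determinism of the truth stage alone
  expect_identical(tr$otus, plant_truth(des)$otus)
  expect_error(study_design(n_otus = 5, n_planted_per_role = 2),
               "too small")
})

test_that("the samplers honour their weight contracts", {
  # single positive-weight OTU takes the whole library
  tt <- toy_truth(c(only = 1))
  expect_equal(unname(draw_library(tt, "lateral_root", "NPK", 175,
                                   seed = 1)), 175)
  # law of large numbers for two equal weights
  tt2 <- toy_truth(c(a = 1, b = 1))
  cn <- draw_library(tt2, "lateral_root", "NPK", 1e5, seed = 2)
  expect_lt(abs(cn["a"] / 1e5 - 0.5), 0.01)
  # zero tissue affinity silences an OTU in that tissue
  aff <- matrix(c(0, 1, 1, 1), 2, 2,
                dimnames = list(c("a", "b"),
                                c("leaf_blade", "lateral_root")))
  tt3 <- toy_truth(c(a = 1, b = 1), affinity = aff)
  for (s in 1:5)
    expect_equal(unname(draw_library(tt3, "leaf_blade", "NPK", 50,
                                     seed = s)["a"]), 0)
  expect_error(draw_library(toy_truth(c(a = 1), affinity = aff[1, 1,
                                                               drop = FALSE] * 0),
                            "leaf_blade", "NPK", 10), "zero")
})

test_that("culturability biases isolate collections as specified", {
  # all culturable on the medium: reduces to the lateral-root library
  tt <- toy_truth(c(a = 3, b = 1))
  lib <- draw_library(tt, "lateral_root", "NPK", 500, seed = 4)
  col <- draw_isolate_collection(tt, "NPK", "R2A", 500, seed = 4)
  expect_equal(lib, col)
  # an OTU culturable only on TSA never shows up on R2A
  cult <- matrix(c(0, 1, 1, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("R2A", "TSA")))
  tt2 <- toy_truth(c(a = 5, b = 1), media = c("R2A", "TSA"),
                   culturability = cult)
  for (s in 1:5)
    expect_equal(unname(draw_isolate_collection(tt2, "NPK", "R2A", 100,
                                                seed = s)["a"]), 0)
  # copiotroph bias: expected frequency from renormalized weights
  cult3 <- matrix(c(0.2, 1, 1, 1), 2, 2,
                  dimnames = list(c("a", "b"), c("R2A", "TSA")))
  tt3 <- toy_truth(c(a = 4, b = 1), media = c("R2A", "TSA"),
                   culturability = cult3)
  cn <- draw_isolate_collection(tt3, "NPK", "R2A", 2e5, seed = 6)
  expect_lt(abs(cn["a"] / 2e5 - 0.8 / 1.8), 0.01)
  expect_error(draw_isolate_collection(tt2, "NPK", "R2A", 10,
                                       seed = 1)["a"], NA)
})

test_that("the unculturable OTU reaches clone libraries but no collection", {
  appeared <- 0L
  for (s in 1:100) {
    des <- study_design(n_otus = 25, n_planted_per_role = 1,
                        depth_range = c(150, 160), template_length = 600,
                        seed = s)
    st <- simulate_study(des, noiseless = FALSE, sequences = FALSE)
    unc <- st$truth$otus$otu_id[st$truth$otus$role == "unculturable"]
    iso <- st$libraries$provenance == "isolate"
    expect_equal(sum(st$counts[unc, iso]), 0)
    if (sum(st$counts[unc, !iso]) > 0) appeared <- appeared + 1L
  }
  expect_gte(appeared, 90)
})

test_that("emitted sequences respect the OTU distance geometry", {
  des <- tiny_seq_design(seed = 9)
  st <- simulate_study(des, noiseless = TRUE)
  reps <- st$representatives
  d <- distance_matrix(reps, model = "p")
  diag(d) <- 1
  expect_gt(min(d), 0.03)   # inter-OTU representatives well separated
  # reads stay within 0.03 of their own representative partition:
  # clustering the reads at 0.03 recovers the planted partition
  dm <- distance_matrix(st$sequences, model = "p")
  p <- cluster_otus(dm, threshold = 0.03, linkage = "furthest")
  truth_of_cluster <- tapply(st$seq_otu[names(p$assignment)],
                             p$assignment, function(x) length(unique(x)))
  expect_equal(length(p$otus), length(unique(st$seq_otu)))
  expect_true(all(truth_of_cluster == 1))
  expect_error(
    emit_sequences(structure(list(design = list(template_length = 100)),
                             class = "ground_truth"), NULL),
    ">= 500")
})

test_that("one read per OTU clusters into exactly n_otus OTUs", {
  des <- study_design(tissues = c("leaf_blade", "lateral_root"),
                      conditions = "NPK", collection_conditions = "NPK",
                      media = "R2A", n_otus = 8, n_planted_per_role = 1,
                      depth_range = c(150, 160), template_length = 1500,
                      seed = 14)
  tr <- plant_truth(des)
  counts <- matrix(1L, 8, 1, dimnames = list(tr$otus$otu_id, "LB-NPK"))
  sq <- emit_sequences(tr, counts, seed = 1)
  d <- distance_matrix(sq$reads, model = "p")
  expect_length(cluster_otus(d, 0.03)$otus, 8)
  # 3 OTUs on a 1500-column template: p-distances > 0.03 by construction
  d3 <- distance_matrix(sq$representatives[1:3], model = "p")
  expect_gt(min(d3[upper.tri(d3)]), 0.03)
})
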