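# Weighted UniFrac and principal coordinate analysis.

# independent second implementation: explicit descendant-tip sets per edge
brute_unifrac <- function(tree, a, b, normalized = FALSE) {
  tree <- midpoint_root(tree)
  ntip <- length(tree$tip.label)
  full <- function(p) {
    x <- setNames(numeric(ntip), tree$tip.label)
    x[names(p)] <- p
    x
  }
  pa <- full(a); pb <- full(b)
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  raw <- 0; denom <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[e, 2])
    A <- sum(pa[tips]); B <- sum(pb[tips])
    raw <- raw + tree$edge.length[e] * abs(A - B)
    denom <- denom + tree$edge.length[e] * (A + B)
  }
  if (normalized) raw / denom else raw
}

test_that("identical profiles have zero UniFrac distance on any tree", {
  set.seed(1)
  for (i in 1:5) {
    tr <- ape::rtree(6)
    p <- runif(6); p <- setNames(p / sum(p), tr$tip.label)
    expect_equal(weighted_unifrac(tr, p, p), 0)
    expect_equal(weighted_unifrac(tr, p, p, normalized = TRUE), 0)
  }
})

test_that("the two-leaf hand computation holds", {
  tr <- read_newick("(x:0.4,y:0.7);")
  a <- c(x = 1); b <- c(y = 1)
  expect_equal(weighted_unifrac(tr, a, b), 0.4 + 0.7)
  expect_equal(weighted_unifrac(tr, a, b, normalized = TRUE), 1)
})

test_that("weighted UniFrac equals a brute-force traversal on random trees", {
  set.seed(17)
  for (i in 1:10) {
    tr <- ape::rtree(6)
    a <- runif(6); a <- setNames(a / sum(a), tr$tip.label)
    b <- runif(6); b <- setNames(b / sum(b), tr$tip.label)
    expect_equal(weighted_unifrac(tr, a, b), brute_unifrac(tr, a, b),
                 tolerance = 1e-12)
    dn <- weighted_unifrac(tr, a, b, normalized = TRUE)
    expect_equal(dn, brute_unifrac(tr, a, b, normalized = TRUE),
                 tolerance = 1e-12)
    expect_gte(dn, 0); expect_lte(dn, 1)
    # symmetry
    expect_equal(weighted_unifrac(tr, b, a), weighted_unifrac(tr, a, b))
  }
})

test_that("weighted UniFrac agrees with the phyloseq implementation", {
  set.seed(23)
  tr <- ape::rtree(8)
  counts <- matrix(rpois(8 * 3, 20) + 1, 8, 3,
                   dimnames = list(tr$tip.label, c("L1", "L2", "L3")))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(midpoint_root(tr)))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                     normalized = FALSE))
  prof <- sweep(counts, 2, colSums(counts), "/")
  for (i in 1:2) for (j in (i + 1):3) {
    mine <- weighted_unifrac(tr, prof[, i], prof[, j])
    expect_equal(mine, ref[i, j], tolerance = 1e-9)
  }
})

test_that("profile validation catches unnormalized and alien leaves", {
  tr <- read_newick("(x:1,y:1);")
  expect_error(weighted_unifrac(tr, c(x = 0.6, y = 0.6), c(x = 1)),
               "not normalized")
  expect_error(weighted_unifrac(tr, c(z = 1), c(x = 1)), "absent")
})

test_that("the UniFrac matrix matches per-pair calls; duplicates at 0", {
  st <- simulate_study(small_design(seed = 6), noiseless = TRUE,
                       sequences = FALSE)
  tab <- truth_otu_table(st)
  set.seed(31)
  tr <- ape::rtree(nrow(tab$counts))
  tr$tip.label <- rownames(tab$counts)
  m <- unifrac_matrix(tr, tab)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, ncol(tab$counts)))
  prof <- otu_fractions(tab)
  for (pair in list(c(1, 5), c(3, 12))) {
    mine <- weighted_unifrac(tr, prof[, pair[1]], prof[, pair[2]])
    expect_equal(m[pair[1], pair[2]], mine, tolerance = 1e-12)
  }
  # duplicated community -> zero distance
  tab2 <- tab
  tab2$counts[, 2] <- tab2$counts[, 1]
  tab2$libraries$size[2] <- tab2$libraries$size[1]
  m2 <- unifrac_matrix(tr, tab2)
  expect_equal(m2[1, 2], 0)
})

test_that("PCoA reconstructs Euclidean configurations", {
  # collinear points: one positive axis carrying 100%
  x <- matrix(c(0, 1, 2.5), ncol = 1)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("p", 1:3), paste0("p", 1:3))
  ord <- pcoa_ordination(d)
  expect_equal(ord$percent_explained[1], 100)
  expect_equal(ncol(ord$coordinates), 1)
  # random 2-D configuration: distances reproduced to 1e-9
  set.seed(19)
  y <- matrix(rnorm(20), ncol = 2)
  d2 <- as.matrix(dist(y))
  dimnames(d2) <- list(paste0("p", 1:10), paste0("p", 1:10))
  ord2 <- pcoa_ordination(d2)
  rec <- as.matrix(dist(ord2$coordinates))
  expect_equal(unname(rec), unname(d2), tolerance = 1e-9)
  # agreement with cmdscale up to sign
  cmd <- stats::cmdscale(d2, k = 2, eig = TRUE)
  expect_equal(abs(unname(ord2$coordinates[, 1:2])),
               abs(unname(cmd$points)), tolerance = 1e-6)
  # duplicate rows coincide
  d3 <- as.matrix(dist(y[c(1, 1, 2:9), ]))
  dimnames(d3) <- list(paste0("p", 1:10), paste0("p", 1:10))
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$coordinates[1, ], ord3$coordinates[2, ],
               tolerance = 1e-9)
})

test_that("axis one separates above- from below-ground communities", {
  hits <- 0L
  for (s in 1:20) {
    des <- study_design(n_otus = 30, n_planted_per_role = 1,
                        depth_range = c(150, 160), template_length = 600,
                        seed = s)
    st <- simulate_study(des, noiseless = TRUE, sequences = FALSE)
    tab <- truth_otu_table(st)
    sq <- emit_sequences(st$truth, st$counts[, 0, drop = FALSE], seed = s)
    dr <- distance_matrix(sq$representatives, model = "p")
    tree <- midpoint_root(nj_tree(dr))
    ord <- pcoa_ordination(unifrac_matrix(tree, tab))
    ax1 <- ord$coordinates[, 1]
    above <- tab$libraries$tissue %in% c("leaf_blade", "petiole")
    sep <- max(ax1[above]) < min(ax1[!above]) ||
      max(ax1[!above]) < min(ax1[above])
    hits <- hits + sep
  }
  expect_equal(hits, 20L)
})
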