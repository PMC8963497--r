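test_that("simulate_tree yields seed-deterministic ultrametric Yule trees", {
  expect_error(simulate_tree(1), "n_leaves")
  t1 <- simulate_tree(8, seed = 1)
  t2 <- simulate_tree(8, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1))
  expect_equal(length(t1$tip.label), 8L)
  expect_equal(t1$Nnode, 7L)  # rooted binary: n - 1 internal nodes
  expect_true(all(t1$edge.length > 0))
  cherry <- simulate_tree(2, seed = 2)
  expect_equal(nrow(cherry$edge), 2L)
})

test_that("evolve_sequences: zero-length branches copy the root, JC69 distance matches closed form", {
  tr <- read_newick("((A:0,B:0):0,C:0);")
  seqs <- evolve_sequences(tr, 200, seed = 4)
  expect_equal(unname(seqs["A"]), unname(seqs["B"]))
  expect_equal(unname(seqs["A"]), unname(seqs["C"]))

  tr2 <- read_newick("(a:0.15,b:0.15);")
  seqs2 <- evolve_sequences(tr2, 10000, seed = 7)
  mm <- mean(strsplit(seqs2[["a"]], "")[[1]] != strsplit(seqs2[["b"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.3 / 3))  # total path 0.3
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(mm - p_exp), 3 * se)

  expect_identical(evolve_sequences(tr2, 100, seed = 5),
                   evolve_sequences(tr2, 100, seed = 5))
  expect_error(evolve_sequences(tr2, 0), "root_length")
})

test_that("fragment_genes respects counts, containment, and identity limits", {
  tr <- simulate_tree(4, seed = 3)
  seqs <- evolve_sequences(tr, 500, seed = 3)
  fr <- fragment_genes(seqs, c(100, 200), n_per_leaf = 3, seed = 8)
  expect_equal(length(fr$fragments), 12L)
  expect_true(all(fr$truth$start >= 1 & fr$truth$end <= 500))
  expect_true(all(nchar(fr$fragments) == fr$truth$end - fr$truth$start + 1))
  # full-length fragment equals its source
  full <- fragment_genes(seqs, c(500, 500), n_per_leaf = 1, seed = 9)
  expect_equal(unname(full$fragments),
               unname(seqs[full$truth$source_leaf]))
  expect_error(fragment_genes(seqs, c(10, 50), 1), ">= 30")
  expect_error(fragment_genes(seqs, c(100, 600), 1), "exceeds")
})

test_that("fragment_genes optional reverse complement and error rate work", {
  tr <- simulate_tree(3, seed = 5)
  seqs <- evolve_sequences(tr, 400, seed = 5)
  fr <- fragment_genes(seqs, c(100, 100), 5, seed = 10, revcomp_prob = 1)
  expect_true(all(fr$truth$revcomp))
  src <- substr(seqs[[fr$truth$source_leaf[1]]],
                fr$truth$start[1], fr$truth$end[1])
  expect_equal(fr$fragments[[1]], revcomp(src))
  err <- fragment_genes(seqs, c(200, 200), 5, seed = 11, error_rate = 0.1)
  mm <- mean(mapply(function(f, i) {
    src <- substr(seqs[[err$truth$source_leaf[i]]],
                  err$truth$start[i], err$truth$end[i])
    mean(strsplit(f, "")[[1]] != strsplit(src, "")[[1]])
  }, err$fragments, seq_along(err$fragments)))
  expect_lt(abs(mm - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("simulate_genome_with_island plants a truthful, GC-accurate island", {
  g <- simulate_genome_with_island(20000, 0.50, 5000, 0.71, order = 3,
                                   seed = 9)
  expect_equal(g$truth$island_end - g$truth$island_start + 1L, 5000L)
  expect_equal(nchar(g$record$residues), 25000L)
  expect_gte(g$truth$island_start, 501L)
  isl <- substr(g$record$residues, g$truth$island_start, g$truth$island_end)
  se <- sqrt(0.71 * 0.29 / 5000)
  expect_lt(abs(gc_content(isl) - 0.71), 3 * se)
  expect_true(any(grepl("transposase", g$annotations$product)))
  expect_error(simulate_genome_with_island(2000, 0.5, 3000, 0.5), "longer")
  expect_error(simulate_genome_with_island(2000, 0.5, 1000, 0.5, order = 2),
               "order")
})

test_that("same-composition iid island is statistically unremarkable", {
  g <- simulate_genome_with_island(20000, 0.5, 2000, 0.5, order = 0, seed = 21)
  sc <- island_scan(g$record$residues,
                    c(g$truth$island_start, g$truth$island_end),
                    n_null_windows = 100, seed = 22)
  expect_lte(sc$percentile, 95)
})

test_that("simulate_gain_loss limits: no gains, planted gain, determinism", {
  tr <- simulate_tree(8, seed = 12)
  expect_warning(res0 <- simulate_gain_loss(tr, 0, 0, seed = 1), "absent")
  expect_true(all(res0$leaf_states == 0))

  # planted gain on an internal edge: exactly that subtree present
  internal_edges <- which(tr$edge[, 2] > length(tr$tip.label))
  e <- internal_edges[1]
  res <- simulate_gain_loss(tr, 0, 0, planted_gain_edge = e)
  below <- unlist(phangorn::Descendants(tr, tr$edge[e, 2], "tips"))
  expect_setequal(names(which(res$leaf_states == 1)), tr$tip.label[below])
  expect_equal(res$events$type, "gain")
  expect_equal(res$events$edge, e)

  a <- simulate_gain_loss(tr, 0.5, 0.2, seed = 33)
  b <- simulate_gain_loss(tr, 0.5, 0.2, seed = 33)
  expect_identical(a, b)
  expect_error(simulate_gain_loss(tr, -1, 0), "rates")
})

test_that("simulate_survey honors mixes, contamination limits, and count ranges", {
  expect_error(simulate_survey(3, sample_type_mix = c(Soil = 0.5, Leaf = 0.4)),
               "sum to 1")
  sv0 <- simulate_survey(6, contamination_rate = 0, seed = 41)
  # labels truthful: every in-genus label has an in-genus true lineage
  genus <- sv0$fragments$lineage %in% c("Methylobacterium", "Methylorubrum")
  expect_true(all(sv0$fragments$true_lineage[genus] == "in-genus"))

  sv1 <- simulate_survey(4, contamination_rate = 1, seed = 42)
  # perfect dual-classifier intersection leaves nothing
  cand <- select_candidates(sv1$fragments)
  oracle <- data.frame(name = sv1$fragments$fragment_id,
                       clade = sv1$fragments$true_clade)
  expect_equal(nrow(conservative_intersect(cand, oracle)), 0L)

  sv2 <- simulate_survey(5, counts_range = c(150, 150), seed = 43)
  expect_true(all(sv2$metadata$vana_count == 150))
  expect_equal(nrow(filter_metagenomes(sv2$metadata)), 5L)
  # per-fragment metagenome membership is unique and complete
  expect_equal(sum(sv2$metadata$vana_count), nrow(sv2$fragments))
  expect_false(anyDuplicated(sv2$fragments$fragment_id) > 0)
})

test_that("make_reference_package builds a consistent clade-labeled package", {
  mk <- make_reference_package(n_ingroup = 8, n_clades = 3, n_outgroup = 2,
                               seq_length = 120, seed = 51)
  rp <- mk$rp
  expect_s3_class(rp, "reference_package")
  expect_setequal(names(mk$clades), rp$tree$tip.label)
  expect_equal(sum(mk$clades == "outgroup"), 2L)
  expect_equal(length(unique(mk$clades)), 4L)
  expect_true(all(nchar(rp$alignment) == 120L))
})
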