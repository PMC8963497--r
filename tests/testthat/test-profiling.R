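make_ann <- function(genome, tags, kos) {
  n <- length(tags)
  data.frame(genome_id = genome, locus_tag = tags, contig_id = "c1",
             start = seq(1, by = 1000, length.out = n),
             end = seq(900, by = 1000, length.out = n),
             strand = "+", ko_id = kos,
             product = "", stringsAsFactors = FALSE)
}

test_that("presence matrix flags markers with locus-tag provenance", {
  ann <- rbind(
    make_ann("g1", c("g1_1", "g1_2", "g1_3"), c("K03862", "K00448", "K00448")),
    make_ann("g2", c("g2_1"), c("K99999")))
  expect_warning(pm <- build_presence_matrix(ann, genomes = c("g1", "g2", "g3")),
                 "zero annotation rows")
  expect_true(pm$presence["g1", "vanA"])
  expect_true(pm$presence["g1", "pcaG"])
  expect_equal(pm$provenance$g1$pcaG, c("g1_2", "g1_3"))
  expect_false(any(pm$presence["g2", ]))
  expect_false(any(pm$presence["g3", ]))
})

test_that("Fitch reconstruction matches hand-worked cases", {
  # cherry, both present: no change
  ch <- read_newick("(A:1,B:1);")
  r <- fitch_gain_loss(ch, c(A = 1, B = 1), root_policy = NULL)
  expect_equal(r$score, 0L)
  expect_equal(r$node_states[3], 1L)

  # ((A,B),(C,D)) with D absent: one loss on D's pendant branch
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  r2 <- fitch_gain_loss(tr, c(A = 1, B = 1, C = 1, D = 0), root_policy = NULL)
  expect_equal(r2$score, 1L)
  ev <- r2$events[r2$events$event != "none", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event, "loss")
  expect_equal(tr$tip.label[ev$child], "D")

  # all absent: nothing happens
  r3 <- fitch_gain_loss(tr, c(A = 0, B = 0, C = 0, D = 0), root_policy = NULL)
  expect_equal(r3$score, 0L)
  expect_true(all(r3$events$event == "none"))

  expect_error(fitch_gain_loss(tr, c(A = 1, B = 1, C = 1), root_policy = NULL),
               "missing")
})

test_that("Fitch score equals the exhaustive minimum over internal labelings", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- simulate_tree(n, seed = 1000 + i)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    got <- fitch_gain_loss(tr, states, root_policy = NULL)$score
    expect_equal(got, exhaustive_parsimony(tr, states))
  }
})

test_that("a single planted gain is recovered on its exact branch", {
  tr <- simulate_tree(10, seed = 19)
  internal_edges <- which(tr$edge[, 2] > length(tr$tip.label))
  for (e in internal_edges[1:3]) {
    hist <- simulate_gain_loss(tr, 0, 0, planted_gain_edge = e)
    rec <- fitch_gain_loss(tr, hist$leaf_states, root_policy = NULL)
    expect_equal(rec$score, 1L)
    ev <- rec$events[rec$events$event != "none", ]
    expect_equal(ev$event, "gain")
    expect_equal(ev$edge, e)
  }
})

test_that("rooting policies work: outgroup leaf and midpoint", {
  tr <- simulate_tree(6, seed = 23)
  states <- stats::setNames(c(1, 1, 1, 0, 0, 0), tr$tip.label)
  un <- ape::unroot(tr)
  r_out <- fitch_gain_loss(un, states, root_policy = tr$tip.label[6])
  r_mid <- fitch_gain_loss(un, states, root_policy = "midpoint")
  expect_true(ape::is.rooted(r_out$tree))
  expect_true(ape::is.rooted(r_mid$tree))
  expect_equal(r_out$score, exhaustive_parsimony(r_out$tree, states))
})

test_that("growth prediction encodes the marker-substrate rules", {
  all_on <- c(vanA = TRUE, pcaG = TRUE, pobA = TRUE, ech = TRUE)
  expect_true(all(predict_growth(all_on)))
  no_vanA <- c(vanA = FALSE, pcaG = TRUE, pobA = TRUE, ech = TRUE)
  p <- predict_growth(no_vanA)
  expect_false(p[["vanillate"]])
  expect_false(p[["ferulate"]])  # ech alone is not enough
  expect_true(p[["PHBA"]] && p[["PCA"]])
  expect_false(any(predict_growth(c(vanA = FALSE, pcaG = FALSE,
                                    pobA = FALSE, ech = FALSE))))
})

test_that("concordance accounting matches the assayed-strain fixture", {
  fx <- growth_assay_fixture()
  expect_equal(dim(fx$genotype), c(8L, 4L))
  preds <- t(apply(fx$genotype, 1, predict_growth))
  rep <- concordance_report(preds, fx$observed)
  expect_equal(rep$total, 32L)
  expect_equal(rep$gene_present_no_growth, 3L)
  expect_equal(rep$gene_absent_growth, 0L)
  expect_equal(rep$concordant + rep$gene_present_no_growth +
                 rep$gene_absent_growth, rep$total)

  # degenerate grids
  same <- matrix(TRUE, 8, 4, dimnames = dimnames(fx$observed))
  all_grow <- matrix("growth", 8, 4, dimnames = dimnames(fx$observed))
  expect_equal(concordance_report(same, all_grow)$gene_present_no_growth, 0L)
  none <- matrix("little-or-none", 8, 4, dimnames = dimnames(fx$observed))
  expect_equal(concordance_report(same, none)$gene_present_no_growth, 32L)
  expect_error(concordance_report(preds[1:2, ], fx$observed), "grid")
})

test_that("gene neighborhoods truncate at contig ends", {
  ann <- make_ann("g1", paste0("L", 1:31), rep("", 31))
  nb <- extract_neighborhood(ann, "L16", n = 15)
  expect_equal(nrow(nb), 31L)
  expect_equal(sum(nb$is_target), 1L)
  nb2 <- extract_neighborhood(ann, "L1", n = 15)
  expect_equal(nrow(nb2), 16L)  # nothing upstream
  expect_equal(nb2$locus_tag[1], "L1")
  nb3 <- extract_neighborhood(ann, "L10", n = 0)
  expect_equal(nb3$locus_tag, "L10")
  expect_error(extract_neighborhood(ann, "nope"), "unknown locus")
})

test_that("genome manifest bookkeeping separates excluded from analyzed", {
  mf <- data.frame(genome_id = c("a", "b", "c", "d"),
                   exclusion_reason = c("", "misclassified", "", ""))
  v <- validate_genome_manifest(mf)
  expect_equal(v$n_retrieved, 4L)
  expect_equal(v$n_excluded, 1L)
  expect_equal(v$n_analyzed, 3L)
  expect_equal(v$excluded$genome_id, "b")
  expect_error(validate_genome_manifest(
    data.frame(genome_id = c("a", "a"), exclusion_reason = "")), "duplicate")
})
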