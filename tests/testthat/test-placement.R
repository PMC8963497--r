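test_that("substitution models are proper stochastic matrices", {
  for (m in list(substitution_model("JC69"), substitution_model("K80", 4))) {
    expect_equal(transition_prob(m, 0), diag(4), ignore_attr = TRUE)
    for (t in c(0.01, 0.3, 2, 50)) {
      P <- transition_prob(m, t)
      expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(P >= 0))
    }
  }
  # K80 with kappa = 1 collapses to JC69
  expect_equal(transition_prob(substitution_model("K80", 1), 0.37),
               transition_prob(substitution_model("JC69"), 0.37))
  expect_error(substitution_model("K80", -1), "kappa")
})

test_that("reference packages validate their invariants", {
  mk <- tiny_refpkg()
  aln <- mk$sequences
  bad <- aln
  bad[[1]] <- substr(bad[[1]], 1, 10)
  expect_error(reference_package(bad, mk$tree, mk$clades), "length")
  expect_error(reference_package(aln[-1], mk$tree, mk$clades), "leaf set")
  expect_error(reference_package(aln, mk$tree, mk$clades[-1]),
               "without a clade")
})

test_that("fragment alignment recovers substrings in either orientation", {
  mk <- tiny_refpkg(seq_length = 200, seed = 31)
  rp <- mk$rp
  frag <- substr(rp$alignment[[3]], 41, 160)
  al <- align_fragment(frag, rp)
  expect_false(al$unalignable)
  expect_equal(al$orientation, "+")
  aligned <- strsplit(al$aligned, "")[[1]]
  expect_true(all(aligned[41:160] != "-"))
  expect_true(all(aligned[c(1:40, 161:200)] == "-"))
  # zero mismatches to the source row over the placed columns
  src <- strsplit(rp$alignment[[3]], "")[[1]]
  expect_true(all(aligned[41:160] == src[41:160]))

  al_rc <- align_fragment(revcomp(frag), rp)
  expect_false(al_rc$unalignable)
  expect_equal(al_rc$orientation, "-")
  expect_equal(al_rc$aligned, al$aligned)

  expect_error(align_fragment("ACGT", rp), "shorter than 30")
})

test_that("random unrelated sequences are flagged unalignable", {
  mk <- tiny_refpkg(seq_length = 300, seed = 37)
  set.seed(38)
  for (i in 1:5) {
    junk <- random_dna(150)
    al <- align_fragment(junk, mk$rp)
    expect_true(al$unalignable)
    expect_lt(al$score, 0)
  }
})

test_that("per-edge log-likelihoods match the brute-force oracle", {
  for (seed in c(11, 61)) {
    mk <- make_reference_package(n_ingroup = 5, n_clades = 2, n_outgroup = 0,
                                 seq_length = 50, depth = 0.5, seed = seed)
    rp <- mk$rp
    frag <- substr(rp$alignment[[2]], 6, 45)
    al <- align_fragment(frag, rp)
    for (model in list(substitution_model("JC69"),
                       substitution_model("K80", 3))) {
      ll <- edge_likelihoods(al$aligned, rp, model, pendant = 0.15)
      bf <- vapply(seq_len(nrow(rp$tree$edge)), function(e)
        brute_edge_loglik(rp, al$aligned, model, 0.15, e), 0)
      expect_equal(ll, bf, tolerance = 1e-8)
    }
  }
})

test_that("a fragment equidistant from both leaves of a cherry ties", {
  tree <- read_newick("(L1:0.2,L2:0.2);")
  aln <- c(L1 = "ACGTACGTACGTACGTACGTACGTACGTAAAA",
           L2 = "ACGTACGTACGTACGTACGTACGTACGTTTTT")
  rp <- reference_package(aln, tree, c(L1 = "x", L2 = "y"))
  # fragment differs from each leaf at exactly 2 of the last 4 positions
  frag <- "ACGTACGTACGTACGTACGTACGTACGTAATT"
  ll <- edge_likelihoods(frag, rp)
  expect_equal(ll[1], ll[2], tolerance = 1e-9)
})

test_that("saturated pendant branches decouple the fragment", {
  mk <- tiny_refpkg(seq_length = 60, seed = 41)
  rp <- mk$rp
  al <- align_fragment(substr(rp$alignment[[1]], 11, 50), rp)
  ll <- edge_likelihoods(al$aligned, rp, pendant = 50)
  expect_lt(diff(range(ll)), 1e-6)
})

test_that("likelihoods are invariant to the rooting of the reference tree", {
  mk <- make_reference_package(n_ingroup = 6, n_clades = 2, n_outgroup = 0,
                               seq_length = 80, depth = 0.4, seed = 43)
  frag <- substr(mk$sequences[[4]], 11, 70)
  lls <- lapply(c(1, 3, 5), function(og) {
    tr <- ape::root(ape::unroot(mk$tree), outgroup = og, resolve.root = TRUE)
    rp <- reference_package(mk$sequences, tr, mk$clades)
    al <- align_fragment(frag, rp)
    sort(edge_likelihoods(al$aligned, rp))
  })
  expect_equal(lls[[1]], lls[[2]], tolerance = 1e-9)
  expect_equal(lls[[1]], lls[[3]], tolerance = 1e-9)
})

test_that("placement normalizes LWRs and classifies by clade", {
  mk <- make_reference_package(seed = 101)
  rp <- mk$rp
  # every reference leaf self-places on its own pendant edge
  for (leaf in rp$tree$tip.label) {
    al <- align_fragment(rp$alignment[[leaf]], rp)
    res <- place_fragment(al$aligned, rp, name = leaf)
    expect_equal(sum(res$placements$like_weight_ratio), 1, tolerance = 1e-9)
    tip_idx <- which(rp$tree$tip.label == leaf)
    expect_equal(res$classification$best_edge,
                 which(rp$tree$edge[, 2] == tip_idx))
    # LWR ordering matches log-likelihood ordering (ties at underflowed
    # LWRs allowed)
    lwr_by_ll <- res$placements$like_weight_ratio[
      order(res$placements$log_likelihood, decreasing = TRUE)]
    expect_true(all(diff(lwr_by_ll) <= 1e-15))
  }
  # an outgroup-derived fragment lands in the outgroup or outside
  og_leaf <- names(mk$clades)[mk$clades == "outgroup"][1]
  al <- align_fragment(substr(rp$alignment[[og_leaf]], 100, 700), rp)
  res <- place_fragment(al$aligned, rp, name = "og")
  expect_true(res$classification$clade %in% c("outgroup", "outside"))
})

test_that("classify_batch preserves order, writes deterministic jplace", {
  mk <- tiny_refpkg(seq_length = 200, seed = 47)
  rp <- mk$rp
  fr <- fragment_genes(mk$sequences, c(60, 120), 2, seed = 48)
  p1 <- withr::local_tempfile(fileext = ".jplace")
  p2 <- withr::local_tempfile(fileext = ".jplace")
  r1 <- classify_batch(fr$fragments, rp, jplace_path = p1)
  r2 <- classify_batch(fr$fragments, rp, jplace_path = p2)
  expect_equal(r1$classifications$name, names(fr$fragments))
  expect_identical(readLines(p1), readLines(p2))
  # unalignable fragments come back "outside" but keep their slot
  set.seed(49)
  mixed <- c(fr$fragments[1], junk = random_dna(100), fr$fragments[2])
  r3 <- classify_batch(mixed, rp)
  expect_equal(nrow(r3$classifications), 3L)
  expect_equal(r3$classifications$clade[2], "outside")
})
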