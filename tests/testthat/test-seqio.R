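test_that("FASTA reading normalizes case, keeps Ns, and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first record", "acgt", ">b", "GGNN", "AC"), path)
  recs <- read_fasta(path)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$description, c("first record", ""))
  expect_equal(recs$residues, c("ACGT", "GGNNAC"))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  expect_equal(read_fasta(out), recs)
})

test_that("FASTA reading tolerates CRLF line endings", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a\r", "ACGT\r"), path, sep = "\n")
  expect_equal(read_fasta(path)$residues, "ACGT")
})

test_that("FASTA format errors name the problem", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACQT"), path)
  expect_error(read_fasta(path), "line 2.*'Q'")
  writeLines(c(">a", "AC", ">a", "GT"), path)
  expect_error(read_fasta(path), "duplicate ids")
  writeLines(character(), path)
  expect_error(read_fasta(path), "no records")
})

test_that("Newick reading round-trips topology and branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_newick(path)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, out)
  tr2 <- read_newick(out)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length), tolerance = 1e-9)
})

test_that("Newick parsing defaults missing branch lengths and rejects bad input", {
  expect_warning(tr <- read_newick("(A,B);"), "branch lengths")
  expect_equal(tr$edge.length, c(0, 0))
  expect_error(read_newick("((A,B,C);"), "unbalanced")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate leaf")
})

test_that("annotation tables are validated row by row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("genome_id", "locus_tag", "contig_id", "start", "end",
                 "strand", "ko_id", "product"), collapse = "\t")
  writeLines(c(hdr,
               "g1\tL1\tc1\t10\t90\t+\tK03862\tvanA",
               "g1\tL2\tc1\t100\t190\t-\t\thypothetical",
               "g1\tL3\tc1\t200\t290\t+\tK00448\tpcaG"), path)
  ann <- read_annotation_table(path)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$ko_id[2], "")  # empty KO = unannotated, accepted

  writeLines(c(hdr, "g1\tL1\tc1\t10\t9\t+\t\tx"), path)
  expect_error(read_annotation_table(path), "line 2.*start <= end")
  writeLines(c(hdr, "g1\tL1\tc1\t1\t9\t*\t\tx"), path)
  expect_error(read_annotation_table(path), "strand")
  writeLines(paste(c("genome_id", "locus_tag"), collapse = "\t"), path)
  expect_error(read_annotation_table(path), "missing columns")
})

test_that("BED export converts to 0-based half-open exactly", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(start = 101L, end = 200L, name = "island"), "chr1", path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(fields, c("chr1", "100", "200", "island"))
})

test_that("jplace writing validates edges, normalizes, and round-trips", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # empty placements still yield a valid file
  p0 <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(list(), tr, p0)
  got0 <- read_jplace(p0)
  expect_equal(nrow(got0$placements), 0L)

  mk <- tiny_refpkg()
  rp <- mk$rp
  al <- align_fragment(substr(rp$alignment[[1]], 3, 38), rp)
  res <- place_fragment(al$aligned, rp, name = "f1")
  expect_equal(nrow(res$placements), 5L)  # 4-leaf unrooted tree: 5 edges
  expect_equal(sum(res$placements$like_weight_ratio), 1, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(list(list(name = "f1",
                         p = data.frame(edge_num = res$placements$edge_num,
                                        likelihood = res$placements$log_likelihood,
                                        like_weight_ratio = res$placements$like_weight_ratio))),
               rp$tree, path)
  got <- read_jplace(path)
  expect_equal(sort(got$placements$edge_num), sort(res$placements$edge_num))
  expect_equal(got$fields, c("edge_num", "likelihood", "like_weight_ratio"))
  expect_match(got$tree, "\\{1\\}")  # edge-numbered Newick

  bad <- list(list(name = "f2", p = data.frame(edge_num = 99L, likelihood = -1,
                                               like_weight_ratio = 1)))
  expect_error(write_jplace(bad, rp$tree, path), "consistency")
})
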