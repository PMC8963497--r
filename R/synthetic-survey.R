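#' Build a synthetic reference package with known clades
#'
#' Simulates an ingroup Yule tree (scaled to a chosen root-to-tip depth),
#' joins a distant outgroup subtree, evolves gap-free aligned sequences over
#' the whole tree, and assigns ingroup leaves to clades by splitting the
#' deepest subtrees. Clade labels follow the vanA reference-package
#' vocabulary: `nodulans-cluster`, `AMS5-cluster`, `aquaticum-clade`, and
#' `outgroup`.
#'
#' @param n_ingroup Ingroup leaves (>= n_clades * 2 recommended).
#' @param n_clades Number of ingroup clades (<= 3 named labels shipped;
#'   further clades are labeled `cladeN`).
#' @param n_outgroup Outgroup leaves (0 for none).
#' @param seq_length Alignment length in bp.
#' @param depth Ingroup root-to-tip depth in expected substitutions/site.
#' @param outgroup_stem Stem length separating ingroup and outgroup.
#' @param model A `subst_model`.
#' @param seed Optional integer seed.
#' @return List with `rp` (a `reference_package`), `tree`, `sequences`, and
#'   `clades`.
#' @export
make_reference_package <- function(n_ingroup = 12, n_clades = 3,
                                   n_outgroup = 3, seq_length = 900,
                                   depth = 0.3, outgroup_stem = 0.5,
                                   model = substitution_model("JC69"),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale_to_depth <- function(tr, d) {
    tr$edge.length <- tr$edge.length * d / max(ape::node.depth.edgelength(tr))
    tr
  }
  ing <- scale_to_depth(ape::rphylo(n_ingroup, 1, 0), depth)
  ing$tip.label <- paste0("ref", seq_len(n_ingroup))
  if (n_outgroup > 0) {
    if (n_outgroup == 1) {
      out_txt <- "og1:0.05"
    } else {
      out <- scale_to_depth(ape::rphylo(n_outgroup, 1, 0), 0.05)
      out$tip.label <- paste0("og", seq_len(n_outgroup))
      out_txt <- sub(";$", "", ape::write.tree(out))
    }
    ing_txt <- sub(";$", "", ape::write.tree(ing))
    tree <- ape::read.tree(text = paste0(
      "(", ing_txt, ":", outgroup_stem / 2, ",", out_txt, ":",
      outgroup_stem / 2, ");"))
  } else {
    tree <- ing
  }
  # clades: recursively split the largest ingroup subtree
  clade_labels <- c("nodulans-cluster", "AMS5-cluster", "aquaticum-clade")
  if (n_clades > 3) {
    clade_labels <- c(clade_labels, paste0("clade", 4:n_clades))
  }
  groups <- list(ing$tip.label)
  subtree_tips <- function(tr, node) {
    tr$tip.label[unlist(phangorn::Descendants(tr, node, "tips"))]
  }
  while (length(groups) < n_clades) {
    sizes <- lengths(groups)
    gi <- which.max(sizes)
    tips <- groups[[gi]]
    node <- ape::getMRCA(ing, tips)
    kids <- ing$edge[ing$edge[, 1] == node, 2]
    parts <- lapply(kids, function(k) {
      if (k <= length(ing$tip.label)) ing$tip.label[k] else subtree_tips(ing, k)
    })
    groups <- c(groups[-gi], parts)
  }
  clades <- character(0)
  for (i in seq_along(groups)) {
    clades[groups[[i]]] <- clade_labels[i]
  }
  if (n_outgroup > 0) {
    clades[paste0("og", seq_len(n_outgroup))] <- "outgroup"
  }
  sequences <- evolve_sequences(tree, seq_length, model)
  rp <- reference_package(sequences, tree, clades)
  list(rp = rp, tree = tree, sequences = sequences, clades = clades)
}

#' The raw ecosystem-string vocabulary used by the survey generator
#'
#' Matches the survey module's shipped mapping table exactly.
#'
#' @return Character vector of raw Ecosystem-Type strings.
#' @export
survey_ecosystem_vocabulary <- function() {
  names(sample_type_map())
}

#' Simulate a vanA metagenome survey with known truth
#'
#' Each metagenome draws a raw ecosystem string from `sample_type_mix` and a
#' total vanA-scaffold count uniformly from `counts_range` (spanning the
#' >100 filter boundary by default). Each fragment is, independently:
#' a contaminant with probability `contamination_rate` (an outgroup-derived
#' scaffold mislabeled with an in-genus lineage — the discrepancy the
#' conservative dual-classifier intersection must catch); otherwise a
#' truthfully labeled outgroup scaffold with probability `nongenus_rate`;
#' otherwise a true in-genus scaffold whose clade is drawn from
#' `clade_mix_per_type` for its sample type. When a reference package is
#' supplied, fragment sequences are generated by fragmenting the leaf
#' sequences of the fragment's true clade (or the outgroup).
#'
#' @param n_metagenomes Number of metagenomes.
#' @param sample_type_mix Named probability vector over raw ecosystem strings
#'   (must sum to 1 within 1e-9).
#' @param clade_mix_per_type Named list: for each mapped sample type, a named
#'   probability vector over in-genus clade labels (each summing to 1).
#' @param contamination_rate Probability a fragment is a mislabeled outgroup
#'   scaffold, in `[0, 1]`.
#' @param counts_range Integer range for per-metagenome vanA counts.
#' @param seed Optional integer seed.
#' @param nongenus_rate Probability (among non-contaminants) of a truthfully
#'   outgroup-labeled scaffold.
#' @param refpkg Optional output of [make_reference_package()]; when given,
#'   fragment sequences are attached.
#' @param frag_len_range Fragment length range when sequences are generated.
#' @return List with `metadata` (metagenome_id, ecosystem, vana_count),
#'   `fragments` (fragment_id, metagenome_id, lineage, ecosystem,
#'   sample_type, true_clade, true_lineage), `sequences` (named character or
#'   NULL), and `truth` (the fragments table plus per-metagenome counts).
#' @export
simulate_survey <- function(n_metagenomes,
                            sample_type_mix = c(Soil = 0.4, Rhizosphere = 0.35,
                                                Phyllosphere = 0.25),
                            clade_mix_per_type = NULL,
                            contamination_rate = 0.1,
                            counts_range = c(50, 300),
                            seed = NULL,
                            nongenus_rate = 0.3,
                            refpkg = NULL,
                            frag_len_range = c(300, 600)) {
  if (abs(sum(sample_type_mix) - 1) > 1e-9) {
    stop("sample_type_mix must sum to 1")
  }
  if (contamination_rate < 0 || contamination_rate > 1) {
    stop("contamination_rate must be in [0, 1]")
  }
  if (is.null(clade_mix_per_type)) {
    clade_mix_per_type <- list(
      Soil = c("nodulans-cluster" = 0.7, "AMS5-cluster" = 0.1,
               "aquaticum-clade" = 0.2),
      Root = c("nodulans-cluster" = 0.55, "AMS5-cluster" = 0.2,
               "aquaticum-clade" = 0.25),
      Leaf = c("nodulans-cluster" = 0.3, "AMS5-cluster" = 0.5,
               "aquaticum-clade" = 0.2))
  }
  for (nm in names(clade_mix_per_type)) {
    if (abs(sum(clade_mix_per_type[[nm]]) - 1) > 1e-9) {
      stop("clade mix for sample type '", nm, "' must sum to 1")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  ecosystems <- sample(names(sample_type_mix), n_metagenomes, replace = TRUE,
                       prob = sample_type_mix)
  counts <- counts_range[1] +
    sample.int(counts_range[2] - counts_range[1] + 1L, n_metagenomes,
               replace = TRUE) - 1L
  metadata <- data.frame(metagenome_id = sprintf("mg%03d", seq_len(n_metagenomes)),
                         ecosystem = ecosystems, vana_count = counts)
  stypes <- map_sample_type(ecosystems)
  rows <- vector("list", n_metagenomes)
  for (m in seq_len(n_metagenomes)) {
    n <- counts[m]
    stype <- stypes[m]
    mix <- clade_mix_per_type[[stype]]
    if (is.null(mix)) mix <- clade_mix_per_type[[1]]
    u <- stats::runif(n)
    contaminant <- u < contamination_rate
    nongenus <- !contaminant &
      (u < contamination_rate + nongenus_rate * (1 - contamination_rate))
    true_clade <- character(n)
    lineage <- character(n)
    true_lineage <- character(n)
    k_in <- sum(!contaminant & !nongenus)
    true_clade[contaminant] <- "outgroup"
    true_clade[nongenus] <- "outgroup"
    if (k_in > 0) {
      true_clade[!contaminant & !nongenus] <-
        sample(names(mix), k_in, replace = TRUE, prob = mix)
    }
    lineage[contaminant] <- "Methylobacterium"      # the lie
    lineage[nongenus] <- sample(c("Azospirillum", "Bosea", "Sphingomonas"),
                                sum(nongenus), replace = TRUE)
    lineage[!contaminant & !nongenus] <-
      sample(c("Methylobacterium", "Methylorubrum"), k_in, replace = TRUE,
             prob = c(0.8, 0.2))
    true_lineage[contaminant | nongenus] <- "outgroup"
    true_lineage[!contaminant & !nongenus] <- "in-genus"
    rows[[m]] <- data.frame(
      fragment_id = sprintf("%s_f%04d", metadata$metagenome_id[m], seq_len(n)),
      metagenome_id = metadata$metagenome_id[m],
      lineage = lineage, ecosystem = ecosystems[m], sample_type = stype,
      true_clade = true_clade, true_lineage = true_lineage)
  }
  fragments <- do.call(rbind, rows)
  sequences <- NULL
  if (!is.null(refpkg)) {
    clades <- refpkg$clades
    seqs <- refpkg$sequences
    lo <- frag_len_range[1]; hi <- frag_len_range[2]
    len <- nchar(seqs[[1]])
    pick <- function(cl) {
      leaves <- names(clades)[clades == cl]
      leaves[sample.int(length(leaves), 1)]
    }
    sequences <- vapply(fragments$true_clade, function(cl) {
      src <- seqs[[pick(cl)]]
      w <- if (lo == hi) lo else sample(lo:hi, 1)
      s <- if (len == w) 1L else sample.int(len - w + 1L, 1)
      substr(src, s, s + w - 1L)
    }, "")
    names(sequences) <- fragments$fragment_id
  }
  list(metadata = metadata, fragments = fragments, sequences = sequences,
       truth = list(fragments = fragments, counts = metadata))
}
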