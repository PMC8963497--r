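#' The four aromatic-catabolism marker genes
#'
#' KEGG Orthology identifiers for the markers profiled across genomes:
#' vanA (vanillate monooxygenase alpha subunit), pcaG (protocatechuate
#' 3,4-dioxygenase alpha subunit), pobA (p-hydroxybenzoate 3-monooxygenase),
#' and ech (trans-feruloyl-CoA hydratase/vanillin synthase).
#'
#' @return Named character vector mapping marker name to KO id.
#' @export
marker_set <- function() {
  c(vanA = "K03862", pcaG = "K00448", pobA = "K00481", ech = "K18383")
}

#' Build a genome x marker presence/absence matrix
#'
#' A cell is TRUE iff at least one annotation row of that genome carries the
#' marker's KO id. Provenance (the matching locus tags) is retained per cell.
#'
#' @param annotations Annotation data.frame (see [read_annotation_table()]),
#'   possibly spanning several genomes.
#' @param markers Named character vector of KO ids; defaults to
#'   [marker_set()].
#' @param genomes Optional character vector of genome ids to include even if
#'   they have no annotation rows (such genomes get an all-FALSE row with a
#'   warning).
#' @return An object of class `presence_matrix`: list with `presence`
#'   (logical matrix), `provenance` (nested list of locus tags), `markers`.
#' @export
build_presence_matrix <- function(annotations, markers = marker_set(),
                                  genomes = NULL) {
  stopifnot(length(markers) > 0, !anyDuplicated(markers))
  if (is.null(genomes)) genomes <- unique(annotations$genome_id)
  empty <- setdiff(genomes, unique(annotations$genome_id))
  if (length(empty) > 0) {
    warning("genomes with zero annotation rows (all-FALSE): ",
            paste(empty, collapse = ", "))
  }
  presence <- matrix(FALSE, length(genomes), length(markers),
                     dimnames = list(genomes, names(markers)))
  provenance <- stats::setNames(vector("list", length(genomes)), genomes)
  for (g in genomes) {
    rows <- annotations[annotations$genome_id == g, , drop = FALSE]
    prov <- lapply(markers, function(ko) rows$locus_tag[rows$ko_id == ko])
    names(prov) <- names(markers)
    presence[g, ] <- vapply(prov, function(x) length(x) > 0, TRUE)
    provenance[[g]] <- prov
  }
  structure(list(presence = presence, provenance = provenance,
                 markers = markers), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence/absence matrix:", nrow(x$presence), "genomes x",
      ncol(x$presence), "markers\n")
  print(x$presence)
  invisible(x)
}

# Fold a list of Fitch state sets pairwise: intersection if nonempty, else
# union (one change). Returns set and number of union operations.
fitch_combine <- function(sets) {
  acc <- sets[[1]]; unions <- 0L
  for (s in sets[-1]) {
    inter <- intersect(acc, s)
    if (length(inter) > 0) acc <- inter else {
      acc <- union(acc, s); unions <- unions + 1L
    }
  }
  list(set = sort(acc), unions = unions)
}

#' Fitch parsimony gain/loss reconstruction
#'
#' Bottom-up Fitch pass over a rooted tree followed by a top-down refinement.
#' The parsimony score is the number of union operations. Ties at the root
#' and at ambiguous nodes are resolved toward absence (state 0), giving one
#' deterministic minimal reconstruction; the full ambiguity sets are reported
#' alongside. Each branch is labeled `gain` (0 -> 1), `loss` (1 -> 0) or
#' `none` under that reconstruction.
#'
#' @param tree [ape::phylo]; rooted via `root_policy` if needed.
#' @param leaf_states Named vector (names = tip labels) of 0/1 presence.
#' @param root_policy Either `"midpoint"` or the label of an outgroup leaf.
#'   Ignored (with the tree used as-is) when `NULL` and the tree is already
#'   rooted.
#' @return List of class `gain_loss`: `score`, `node_sets` (possible states
#'   per node), `node_states` (the deterministic reconstruction), `events`
#'   (data.frame: edge, parent/child nodes and states, event), `ambiguous`
#'   (nodes whose state set has both 0 and 1), `tree` (the rooted tree).
#' @export
fitch_gain_loss <- function(tree, leaf_states, root_policy = "midpoint") {
  missing <- setdiff(tree$tip.label, names(leaf_states))
  if (length(missing) > 0) {
    stop("leaf_states missing for: ", paste(missing, collapse = ", "))
  }
  if (!is.null(root_policy)) {
    if (identical(root_policy, "midpoint")) {
      tree <- phangorn::midpoint(tree)
    } else if (root_policy %in% tree$tip.label) {
      tree <- ape::root(tree, outgroup = root_policy, resolve.root = TRUE)
    } else if (!ape::is.rooted(tree)) {
      stop("root_policy must be 'midpoint' or a leaf label")
    }
  } else if (!ape::is.rooted(tree)) {
    stop("tree is unrooted and root_policy is NULL")
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  node_sets <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    node_sets[[i]] <- as.integer(leaf_states[[tree$tip.label[i]]])
  }
  score <- 0L
  preorder_edges <- ape::reorder.phylo(tree, "cladewise")$edge
  postorder <- rev(unique(preorder_edges[, 1]))  # parents after all children
  for (nd in postorder) {
    res <- fitch_combine(node_sets[kids[[as.character(nd)]]])
    node_sets[[nd]] <- res$set
    score <- score + res$unions
  }
  root <- ntip + 1L
  node_states <- integer(nnode)
  node_states[root] <- min(node_sets[[root]])  # ties -> 0
  # top-down refinement in preorder
  edge_index <- match(paste(preorder_edges[, 1], preorder_edges[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  events <- data.frame(edge = edge_index,
                       parent = preorder_edges[, 1],
                       child = preorder_edges[, 2],
                       parent_state = NA_integer_, child_state = NA_integer_,
                       event = NA_character_)
  for (r in seq_len(nrow(preorder_edges))) {
    p <- preorder_edges[r, 1]; ch <- preorder_edges[r, 2]
    ps <- node_states[p]
    cs <- if (ps %in% node_sets[[ch]]) ps else min(node_sets[[ch]])
    node_states[ch] <- cs
    events$parent_state[r] <- ps
    events$child_state[r] <- cs
    events$event[r] <- if (ps == cs) "none" else if (cs == 1L) "gain" else "loss"
  }
  ambiguous <- which(vapply(node_sets, length, 0L) > 1)
  structure(list(score = score, node_sets = node_sets,
                 node_states = node_states, events = events,
                 ambiguous = ambiguous, tree = tree),
            class = "gain_loss")
}

#' @export
print.gain_loss <- function(x, ...) {
  ev <- x$events[x$events$event != "none", , drop = FALSE]
  cat("Fitch gain/loss reconstruction: parsimony score", x$score, "\n")
  cat(sum(ev$event == "gain"), "gain(s),", sum(ev$event == "loss"),
      "loss(es);", length(x$ambiguous), "ambiguous node(s)\n")
  invisible(x)
}

#' Predict growth on aromatic substrates from genotype
#'
#' PHBA growth is predicted from pobA, PCA from pcaG, vanillate from vanA,
#' and ferulate from ech AND vanA (ferulate catabolism funnels through
#' vanillate, so an organism lacking vanA is predicted not to grow on
#' ferulate even when ech is present).
#'
#' @param presence_row Named logical vector over the markers vanA, pcaG,
#'   pobA, ech (a row of a presence matrix).
#' @return Named logical vector over substrates PHBA, PCA, vanillate,
#'   ferulate.
#' @export
predict_growth <- function(presence_row) {
  need <- c("vanA", "pcaG", "pobA", "ech")
  if (!all(need %in% names(presence_row))) {
    stop("presence_row must be named over: ", paste(need, collapse = ", "))
  }
  p <- as.logical(presence_row)
  names(p) <- names(presence_row)
  c(PHBA = unname(p["pobA"]), PCA = unname(p["pcaG"]),
    vanillate = unname(p["vanA"]), ferulate = unname(p["ech"] && p["vanA"]))
}

#' Growth-assay fixture: 8 strains x 4 substrates
#'
#' Transcription of the growth-assay outcomes for the eight assayed strains
#' on the four substrates of the marker genes. Genotype: all four markers
#' present in every strain except Methylobacterium sp. 4-46, which lacks
#' vanA. Observed outcome is "growth" everywhere except M. variabile on
#' vanillate and ferulate, M. nodulans on ferulate, and sp. 4-46 on vanillate
#' and ferulate ("little-or-none"). Note: M. variabile's vanillate growth was
#' reported as modest; it is encoded "little-or-none" here, flagged in
#' `notes`.
#'
#' @return List with `genotype` (8x4 logical matrix over markers), `observed`
#'   (8x4 character matrix over substrates), and `notes`.
#' @export
growth_assay_fixture <- function() {
  strains <- c("M. aquaticum DSM 16371", "M. aquaticum MA-22A", "M. platani",
               "M. tarhaniae", "M. variabile", "M. nodulans",
               "Methylobacterium sp. 4-46", "Methylobacterium sp. AMS5")
  markers <- c("vanA", "pcaG", "pobA", "ech")
  substrates <- c("PHBA", "PCA", "vanillate", "ferulate")
  genotype <- matrix(TRUE, 8, 4, dimnames = list(strains, markers))
  genotype["Methylobacterium sp. 4-46", "vanA"] <- FALSE
  observed <- matrix("growth", 8, 4, dimnames = list(strains, substrates))
  observed["M. variabile", c("vanillate", "ferulate")] <- "little-or-none"
  observed["M. nodulans", "ferulate"] <- "little-or-none"
  observed["Methylobacterium sp. 4-46", c("vanillate", "ferulate")] <- "little-or-none"
  list(genotype = genotype, observed = observed,
       notes = c("M. variabile vanillate growth reported as modest; encoded little-or-none"))
}

#' Genotype/growth concordance accounting
#'
#' Counts, over a strain x substrate grid, the cases where genes predict
#' growth but little or none was observed, and the reverse.
#'
#' @param predictions Logical matrix (strains x substrates), TRUE = growth
#'   predicted from genotype.
#' @param observed Character matrix of the same dimnames with values
#'   "growth" or "little-or-none".
#' @return List with `total`, `gene_present_no_growth`, `gene_absent_growth`,
#'   `concordant`.
#' @export
concordance_report <- function(predictions, observed) {
  if (!identical(dimnames(predictions), dimnames(observed))) {
    stop("predictions and observed must share the same strain x substrate grid")
  }
  grew <- observed == "growth"
  gp_ng <- sum(predictions & !grew)
  ga_g <- sum(!predictions & grew)
  total <- length(predictions)
  list(total = total,
       gene_present_no_growth = gp_ng,
       gene_absent_growth = ga_g,
       concordant = total - gp_ng - ga_g)
}

#' Extract the gene neighborhood around a locus
#'
#' Up to `n` genes upstream and downstream of the target on the same contig,
#' ordered by start coordinate, truncated at contig ends.
#'
#' @param annotations Annotation data.frame.
#' @param locus_tag Target locus tag.
#' @param n Genes to take on each side (default 15).
#' @return Annotation rows of the neighborhood (target included), ordered by
#'   start, with a logical column `is_target`.
#' @export
extract_neighborhood <- function(annotations, locus_tag, n = 15) {
  hit <- annotations[annotations$locus_tag == locus_tag, , drop = FALSE]
  if (nrow(hit) == 0) stop("unknown locus tag: ", locus_tag)
  hit <- hit[1, ]
  same <- annotations[annotations$genome_id == hit$genome_id &
                        annotations$contig_id == hit$contig_id, , drop = FALSE]
  same <- same[order(same$start), ]
  idx <- which(same$locus_tag == locus_tag)
  keep <- max(1L, idx - n):min(nrow(same), idx + n)
  out <- same[keep, ]
  out$is_target <- out$locus_tag == locus_tag
  out
}

#' Validate a genome-set manifest
#'
#' Bookkeeping for the genome survey inputs: counts retrieved genomes,
#' genomes flagged for exclusion (with reasons), and the analyzed remainder.
#'
#' @param manifest data.frame with columns `genome_id` and
#'   `exclusion_reason` (empty string = analyzed), or a path to such a TSV.
#' @return List with `n_retrieved`, `n_excluded`, `n_analyzed`, and the
#'   `excluded` rows.
#' @export
validate_genome_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                                  colClasses = "character")
  }
  stopifnot(all(c("genome_id", "exclusion_reason") %in% names(manifest)))
  if (anyDuplicated(manifest$genome_id)) {
    stop("duplicate genome ids in manifest")
  }
  manifest$exclusion_reason[is.na(manifest$exclusion_reason)] <- ""
  excluded <- manifest[nzchar(manifest$exclusion_reason), , drop = FALSE]
  list(n_retrieved = nrow(manifest),
       n_excluded = nrow(excluded),
       n_analyzed = nrow(manifest) - nrow(excluded),
       excluded = excluded)
}
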