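#' Assemble a reference package for phylogenetic placement
#'
#' Bundles an aligned set of reference marker sequences, a reference tree
#' over the same leaf labels, and a leaf -> clade map. The tree is unrooted
#' on construction (placement likelihoods are unrooted). Edge ids are the row
#' indices of the unrooted tree's edge matrix.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (gaps `-` allowed), or a data.frame from [read_fasta()].
#' @param tree [ape::phylo] whose tip labels equal the alignment names.
#' @param clades Named character vector mapping every leaf to a clade label
#'   (use `"outgroup"` for non-target leaves).
#' @return An object of class `reference_package`.
#' @export
reference_package <- function(alignment, tree, clades) {
  if (is.data.frame(alignment)) {
    alignment <- stats::setNames(alignment$residues, alignment$id)
  }
  if (length(unique(nchar(alignment))) != 1) {
    stop("reference alignment rows differ in length")
  }
  if (nchar(alignment[1]) < 1) stop("alignment must have >= 1 column")
  if (!setequal(names(alignment), tree$tip.label)) {
    stop("tree leaf set and alignment id set differ")
  }
  missing <- setdiff(tree$tip.label, names(clades))
  if (length(missing) > 0) {
    stop("leaves without a clade label: ", paste(missing, collapse = ", "))
  }
  if (length(tree$tip.label) > 2) tree <- ape::unroot(tree)
  rp <- list(alignment = alignment[tree$tip.label], tree = tree,
             clades = clades[tree$tip.label],
             consensus = alignment_consensus(alignment),
             edge_clade = NULL, cache = new.env(parent = emptyenv()))
  rp$edge_clade <- edge_clade_map(tree, rp$clades)
  structure(rp, class = "reference_package")
}

#' @export
print.reference_package <- function(x, ...) {
  cat("Reference package:", length(x$alignment), "sequences x",
      nchar(x$alignment[1]), "columns;",
      nrow(x$tree$edge), "edges; clades:",
      paste(unique(x$clades), collapse = ", "), "\n")
  invisible(x)
}

# Column-wise majority consensus of an alignment (gaps ignored; ties broken
# alphabetically; all-gap columns become N).
alignment_consensus <- function(alignment) {
  set <- Biostrings::DNAStringSet(alignment)
  cm <- Biostrings::consensusMatrix(set)
  acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  best <- apply(acgt, 2, function(col) {
    if (sum(col) == 0) "N" else c("A", "C", "G", "T")[which.max(col)]
  })
  paste(best, collapse = "")
}

# For every edge, the most specific clade whose induced subtree contains both
# endpoints, else "outside". The induced subtree of a clade is the Steiner
# tree of its leaves; for a singleton clade it is taken to be the leaf's
# pendant edge.
edge_clade_map <- function(tree, clades) {
  ntip <- length(tree$tip.label)
  labels <- setdiff(unique(clades), NA)
  node_sets <- lapply(labels, function(cl) {
    leaves <- which(tree$tip.label %in% names(clades)[clades == cl])
    if (length(leaves) == 1) {
      parent <- tree$edge[tree$edge[, 2] == leaves, 1]
      return(c(leaves, parent))
    }
    nodes <- leaves[1]
    for (l in leaves[-1]) {
      nodes <- union(nodes, ape::nodepath(tree, leaves[1], l))
    }
    nodes
  })
  names(node_sets) <- labels
  sizes <- vapply(labels, function(cl) sum(clades == cl), 0L)
  out <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    containing <- labels[vapply(labels, function(cl) {
      all(c(u, v) %in% node_sets[[cl]])
    }, TRUE)]
    out[e] <- if (length(containing) == 0) "outside" else
      containing[which.min(sizes[containing])]
  }
  out
}

# Tip partial likelihoods: 4 x L matrix per tip. Gaps, N and any ambiguity
# are missing data (all-ones partial).
tip_partials <- function(alignment) {
  lapply(alignment, function(s) {
    ch <- strsplit(s, "")[[1]]
    m <- matrix(1, 4, length(ch), dimnames = list(base_order, NULL))
    for (b in base_order) {
      hit <- ch == b
      if (any(hit)) {
        m[, hit] <- 0
        m[b, hit] <- 1
      }
    }
    m
  })
}

# Directional messages on the unrooted reference tree: for every directed
# edge u -> v, the conditional likelihood (4 x L, with per-column log scale)
# of the subtree on u's side, as seen at u. Computed once per (package,
# model) and cached; fragments only ever multiply in at the grafted midpoint.
build_messages <- function(rp, model) {
  key <- paste0("msg_", model$name, "_", model$kappa)
  if (!is.null(rp$cache[[key]])) return(rp$cache[[key]])
  tree <- rp$tree
  ntip <- length(tree$tip.label)
  L <- nchar(rp$alignment[1])
  tips <- tip_partials(rp$alignment)
  edges <- tree$edge
  # adjacency with branch lengths
  nb <- list()
  addnb <- function(a, b, t) {
    k <- as.character(a)
    nb[[k]] <<- rbind(nb[[k]], c(node = b, len = t))
  }
  for (e in seq_len(nrow(edges))) {
    addnb(edges[e, 1], edges[e, 2], tree$edge.length[e])
    addnb(edges[e, 2], edges[e, 1], tree$edge.length[e])
  }
  cache <- new.env(parent = emptyenv())
  msg <- function(u, v) {
    k <- paste(u, v)
    got <- cache[[k]]
    if (!is.null(got)) return(got)
    res <- if (u <= ntip) {
      list(mat = tips[[u]], logscale = numeric(L))
    } else {
      mat <- matrix(1, 4, L)
      logscale <- numeric(L)
      for (r in seq_len(nrow(nb[[as.character(u)]]))) {
        w <- nb[[as.character(u)]][r, "node"]
        t <- nb[[as.character(u)]][r, "len"]
        if (w == v) next
        child <- msg(w, u)
        mat <- mat * (transition_prob(model, t) %*% child$mat)
        logscale <- logscale + child$logscale
      }
      s <- apply(mat, 2, max)
      list(mat = sweep(mat, 2, s, "/"), logscale = logscale + log(s))
    }
    cache[[k]] <- res
    res
  }
  for (e in seq_len(nrow(edges))) {
    msg(edges[e, 1], edges[e, 2])
    msg(edges[e, 2], edges[e, 1])
  }
  out <- list(get = function(u, v) cache[[paste(u, v)]], L = L)
  rp$cache[[key]] <- out
  out
}

fragment_partial <- function(aligned_fragment) {
  ch <- strsplit(aligned_fragment, "")[[1]]
  m <- matrix(1, 4, length(ch), dimnames = list(base_order, NULL))
  for (b in base_order) {
    hit <- ch == b
    if (any(hit)) {
      m[, hit] <- 0
      m[b, hit] <- 1
    }
  }
  list(partial = m, nongap = which(ch != "-"))
}

#' Per-edge placement log-likelihoods for an aligned fragment
#'
#' For every edge of the unrooted reference tree, the fragment is grafted at
#' the edge midpoint by a pendant branch and the alignment log-likelihood is
#' computed by Felsenstein pruning, restricted to the columns where the
#' fragment is non-gap. N in the fragment is treated as missing data.
#'
#' @param aligned_fragment Fragment string padded to alignment length (from
#'   [align_fragment()]).
#' @param rp A `reference_package`.
#' @param model A `subst_model`.
#' @param pendant Pendant branch length (> 0).
#' @return Numeric vector of log-likelihoods, one per edge (edge ids = rows
#'   of `rp$tree$edge`).
#' @export
edge_likelihoods <- function(aligned_fragment, rp,
                             model = substitution_model("JC69"),
                             pendant = 0.1) {
  stopifnot(inherits(rp, "reference_package"), pendant > 0)
  if (nchar(aligned_fragment) != nchar(rp$alignment[1])) {
    stop("aligned fragment length differs from alignment length")
  }
  fp <- fragment_partial(aligned_fragment)
  cols <- fp$nongap
  if (length(cols) == 0) stop("fragment is all-gap")
  msgs <- build_messages(rp, model)
  Fmat <- transition_prob(model, pendant) %*% fp$partial[, cols, drop = FALSE]
  tree <- rp$tree
  pkey <- paste0("phalf_", model$name, "_", model$kappa)
  if (is.null(rp$cache[[pkey]])) {
    rp$cache[[pkey]] <- lapply(tree$edge.length / 2, function(h) {
      transition_prob(model, h)
    })
  }
  phalf <- rp$cache[[pkey]]
  ll <- numeric(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    P <- phalf[[e]]
    mu <- msgs$get(u, v); mv <- msgs$get(v, u)
    A <- P %*% mu$mat[, cols, drop = FALSE]
    B <- P %*% mv$mat[, cols, drop = FALSE]
    collik <- 0.25 * colSums(A * B * Fmat)
    ll[e] <- sum(log(collik)) + sum(mu$logscale[cols]) + sum(mv$logscale[cols])
  }
  ll
}

#' Align a fragment against a reference package
#'
#' Semi-global alignment (fragment global, reference local: no end penalties
#' on the reference) of the fragment against the column-wise majority
#' consensus of the reference alignment, scored match +1 / mismatch -1 /
#' gap -2. Both orientations are tried when `try_revcomp` is TRUE and the
#' higher-scoring one kept. A score below `score_floor` flags the fragment
#' unalignable. Fragment insertions relative to the consensus are dropped
#' (the reference column set is fixed).
#'
#' @param fragment Fragment sequence (>= 30 bp).
#' @param rp A `reference_package`.
#' @param try_revcomp Also try the reverse complement.
#' @param score_floor Minimum acceptable alignment score (default 0).
#' @return List with `aligned` (fragment padded to alignment length, or NA),
#'   `score`, `orientation` ("+"/"-"), `unalignable` (logical).
#' @export
align_fragment <- function(fragment, rp, try_revcomp = TRUE,
                           score_floor = 0) {
  if (nchar(fragment) < 30) stop("fragment shorter than 30 bp")
  subs <- matrix(-1, 5, 5, dimnames = list(c(base_order, "N"),
                                           c(base_order, "N")))
  diag(subs) <- 1
  subs["N", ] <- 0; subs[, "N"] <- 0
  consensus <- Biostrings::DNAString(rp$consensus)
  try_one <- function(fr) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(fr), subject = consensus,
      type = "global-local", substitutionMatrix = subs,
      gapOpening = 0, gapExtension = 2)
  }
  pa <- try_one(fragment)
  orientation <- "+"
  best_score <- Biostrings::score(pa)
  if (try_revcomp) {
    rcfrag <- revcomp(fragment)
    pa_rc <- try_one(rcfrag)
    if (Biostrings::score(pa_rc) > best_score) {
      pa <- pa_rc
      best_score <- Biostrings::score(pa_rc)
      orientation <- "-"
    }
  }
  if (best_score < score_floor) {
    return(list(aligned = NA_character_, score = best_score,
                orientation = orientation, unalignable = TRUE))
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- sub != "-"                     # drop fragment insertions
  pat <- pat[keep]
  s <- Biostrings::start(Biostrings::subject(pa))
  out <- rep("-", nchar(rp$consensus))
  out[s:(s + length(pat) - 1L)] <- pat
  list(aligned = paste(out, collapse = ""), score = best_score,
       orientation = orientation, unalignable = FALSE)
}

#' Place one aligned fragment on the reference tree
#'
#' Converts per-edge log-likelihoods to likelihood weight ratios
#' `LWR_e = exp(l_e - l_max) / sum(exp(l_e' - l_max))`, picks the best edge
#' (ties broken by lowest edge id), and classifies the fragment by the most
#' specific labeled clade whose induced subtree contains both endpoints of
#' the best edge, else `"outside"`.
#'
#' @inheritParams edge_likelihoods
#' @param name Fragment id carried into the outputs.
#' @return List with `placements` (data.frame: edge_num, log_likelihood,
#'   like_weight_ratio, pendant) and `classification` (data.frame: name,
#'   best_edge, clade, best_lwr).
#' @export
place_fragment <- function(aligned_fragment, rp,
                           model = substitution_model("JC69"),
                           pendant = 0.1, name = "fragment") {
  ll <- edge_likelihoods(aligned_fragment, rp, model, pendant)
  lwr <- exp(ll - max(ll))
  lwr <- lwr / sum(lwr)
  best <- which(lwr == max(lwr))[1]
  list(placements = data.frame(edge_num = seq_along(ll),
                               log_likelihood = ll,
                               like_weight_ratio = lwr,
                               pendant = pendant),
       classification = data.frame(name = name, best_edge = best,
                                   clade = rp$edge_clade[best],
                                   best_lwr = lwr[best]))
}

#' Align, place and classify a batch of fragments
#'
#' Applies [align_fragment()] then [place_fragment()] to each fragment, in
#' input order. Unalignable fragments are classified `"outside"` with no
#' placement records. Optionally writes a jplace file of the placements.
#'
#' @param fragments Named character vector of fragment sequences.
#' @param rp A `reference_package`.
#' @param model A `subst_model`.
#' @param pendant Pendant branch length.
#' @param jplace_path Optional output path for a jplace file.
#' @param lwr_keep Keep only edges with LWR >= this value in the jplace
#'   records (all edges are always used for the classification).
#' @return List with `classifications` (one row per fragment) and
#'   `placements` (list per fragment).
#' @export
classify_batch <- function(fragments, rp,
                           model = substitution_model("JC69"),
                           pendant = 0.1, jplace_path = NULL,
                           lwr_keep = 0) {
  stopifnot(length(fragments) >= 1)
  if (is.null(names(fragments))) {
    names(fragments) <- paste0("frag", seq_along(fragments))
  }
  cls <- vector("list", length(fragments))
  pls <- vector("list", length(fragments))
  for (i in seq_along(fragments)) {
    nm <- names(fragments)[i]
    al <- align_fragment(fragments[[i]], rp)
    if (al$unalignable) {
      cls[[i]] <- data.frame(name = nm, best_edge = NA_integer_,
                             clade = "outside", best_lwr = NA_real_)
      next
    }
    res <- place_fragment(al$aligned, rp, model, pendant, name = nm)
    cls[[i]] <- res$classification
    keep <- res$placements$like_weight_ratio >= lwr_keep
    pls[[i]] <- list(name = nm,
                     p = data.frame(
                       edge_num = res$placements$edge_num[keep],
                       likelihood = res$placements$log_likelihood[keep],
                       like_weight_ratio = res$placements$like_weight_ratio[keep]))
  }
  classifications <- do.call(rbind, cls)
  pls <- pls[!vapply(pls, is.null, TRUE)]
  if (!is.null(jplace_path)) {
    write_jplace(pls, rp$tree, jplace_path)
  }
  list(classifications = classifications, placements = pls)
}
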