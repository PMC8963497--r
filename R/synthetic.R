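#' Simulate a Yule (pure-birth) reference tree
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed; a fixed seed gives an identical tree.
#' @return An ultrametric [ape::phylo] with positive branch lengths and tip
#'   labels `t1..tn`.
#' @export
simulate_tree <- function(n_leaves, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_leaves) || n_leaves < 2) stop("n_leaves must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ape::rphylo(n_leaves, birth = birth_rate, death = 0)
}

base_order <- c("A", "C", "G", "T")

# Sample child bases site-wise given parent bases (integer-coded 1..4) and a
# 4x4 transition matrix.
mutate_bases <- function(parent, P) {
  child <- integer(length(parent))
  for (b in 1:4) {
    idx <- which(parent == b)
    if (length(idx) > 0) {
      child[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  child
}

#' Evolve aligned sequences down a tree
#'
#' Indel-free simulation under JC69 or K80: a uniform-random root sequence is
#' propagated down every branch using the model's transition probabilities.
#' All leaf sequences share the root length (a gap-free alignment).
#'
#' @param tree [ape::phylo] with branch lengths in expected
#'   substitutions/site.
#' @param root_length Sequence length (>= 1).
#' @param model A `subst_model` (default JC69).
#' @param seed Optional integer seed.
#' @return Named character vector of leaf sequences (names = tip labels).
#' @export
evolve_sequences <- function(tree, root_length,
                             model = substitution_model("JC69"),
                             seed = NULL) {
  if (!is.numeric(root_length) || root_length < 1) {
    stop("root_length must be >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4, root_length, replace = TRUE)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  bl <- tree$edge.length[match(paste(pre[, 1], pre[, 2]),
                               paste(tree$edge[, 1], tree$edge[, 2]))]
  for (r in seq_len(nrow(pre))) {
    P <- transition_prob(model, bl[r])
    seqs[[pre[r, 2]]] <- mutate_bases(seqs[[pre[r, 1]]], P)
  }
  out <- vapply(seq_len(ntip), function(i) {
    paste(base_order[seqs[[i]]], collapse = "")
  }, "")
  stats::setNames(out, tree$tip.label)
}

#' Fragment leaf sequences into metagenome-like gene fragments
#'
#' Fragments are contiguous substrings of the (aligned, gap-free) leaf
#' sequences, in coding-strand orientation by default; optionally each
#' fragment is reverse-complemented with probability `revcomp_prob`, and a
#' uniform per-base substitution error can be applied. Truth records the
#' source leaf and 1-based coordinates.
#'
#' @param leaf_sequences Named character vector of equal-length sequences.
#' @param frag_len_range Integer range `c(min, max)`; min >= 30 and max <=
#'   sequence length.
#' @param n_per_leaf Fragments per leaf.
#' @param seed Optional integer seed.
#' @param revcomp_prob Probability a fragment is reverse-complemented.
#' @param error_rate Uniform per-base substitution error rate (default 0;
#'   assembled scaffolds, not raw reads, are being emulated).
#' @return List with `fragments` (named character vector) and `truth`
#'   (data.frame: fragment_id, source_leaf, start, end, revcomp).
#' @export
fragment_genes <- function(leaf_sequences, frag_len_range, n_per_leaf,
                           seed = NULL, revcomp_prob = 0, error_rate = 0) {
  len <- unique(nchar(leaf_sequences))
  stopifnot(length(len) == 1)
  lo <- as.integer(frag_len_range[1]); hi <- as.integer(frag_len_range[2])
  if (lo < 30) stop("minimum fragment length must be >= 30")
  if (hi > len) stop("fragment length range exceeds sequence length")
  if (lo > hi) stop("frag_len_range must be nondecreasing")
  if (!is.null(seed)) set.seed(seed)
  n_total <- length(leaf_sequences) * n_per_leaf
  truth <- data.frame(
    fragment_id = paste0("frag", seq_len(n_total)),
    source_leaf = rep(names(leaf_sequences), each = n_per_leaf),
    start = NA_integer_, end = NA_integer_, revcomp = FALSE)
  frags <- character(n_total)
  for (i in seq_len(n_total)) {
    src <- leaf_sequences[[truth$source_leaf[i]]]
    w <- if (lo == hi) lo else sample(lo:hi, 1)
    s <- if (len == w) 1L else sample.int(len - w + 1L, 1)
    frag <- substr(src, s, s + w - 1L)
    if (error_rate > 0) {
      hitpos <- which(stats::runif(w) < error_rate)
      if (length(hitpos) > 0) {
        ch <- strsplit(frag, "")[[1]]
        for (p in hitpos) {
          ch[p] <- sample(setdiff(base_order, ch[p]), 1)
        }
        frag <- paste(ch, collapse = "")
      }
    }
    rc <- revcomp_prob > 0 && stats::runif(1) < revcomp_prob
    if (rc) frag <- revcomp(frag)
    frags[i] <- frag
    truth$start[i] <- s; truth$end[i] <- s + w - 1L; truth$revcomp[i] <- rc
  }
  names(frags) <- truth$fragment_id
  list(fragments = frags, truth = truth)
}

#' Simulate presence/absence history by gain/loss along a tree
#'
#' Two-state continuous-time Markov process (0 = absent, 1 = present) run
#' down every branch from an absent root. The truth lists every flip with its
#' branch and time. Alternatively a single gain can be planted
#' deterministically on a chosen edge (rates then ignored), for forcing a
#' known topology of events.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param gain_rate Rate of 0 -> 1 flips (>= 0).
#' @param loss_rate Rate of 1 -> 0 flips (>= 0).
#' @param seed Optional integer seed.
#' @param planted_gain_edge Optional edge index (row of `tree$edge`); when
#'   given, the history is exactly one gain at the midpoint of that edge.
#' @return List with `leaf_states` (named 0/1), `events` (data.frame: edge,
#'   time within branch, type), `n_events`.
#' @export
simulate_gain_loss <- function(tree, gain_rate, loss_rate, seed = NULL,
                               planted_gain_edge = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  bl <- tree$edge.length[match(paste(pre[, 1], pre[, 2]),
                               paste(tree$edge[, 1], tree$edge[, 2]))]
  edge_index <- match(paste(pre[, 1], pre[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  state <- integer(nnode)
  events <- list()
  if (!is.null(planted_gain_edge)) {
    # force a single gain; propagate presence to the planted edge's subtree
    for (r in seq_len(nrow(pre))) {
      s <- state[pre[r, 1]]
      if (edge_index[r] == planted_gain_edge) {
        s <- 1L
        events[[length(events) + 1]] <- data.frame(
          edge = planted_gain_edge, time = bl[r] / 2, type = "gain")
      }
      state[pre[r, 2]] <- s
    }
  } else {
    if (gain_rate == 0 && loss_rate == 0) {
      warning("both rates are 0 and the root is absent: all leaves absent")
    }
    for (r in seq_len(nrow(pre))) {
      s <- state[pre[r, 1]]
      remaining <- bl[r]; at <- 0
      repeat {
        rate <- if (s == 0L) gain_rate else loss_rate
        if (rate == 0) break
        dt <- stats::rexp(1, rate)
        if (dt >= remaining) break
        at <- at + dt; remaining <- remaining - dt
        s <- 1L - s
        events[[length(events) + 1]] <- data.frame(
          edge = edge_index[r], time = at,
          type = if (s == 1L) "gain" else "loss")
      }
      state[pre[r, 2]] <- s
    }
  }
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(edge = integer(), time = numeric(), type = character())
  leaf_states <- stats::setNames(state[seq_len(ntip)], tree$tip.label)
  list(leaf_states = leaf_states, events = events, n_events = nrow(events))
}
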