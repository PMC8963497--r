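# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive and separate from the package's
# implementation paths.

# reverse complement without Biostrings
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  apply(do.call(expand.grid, rep(list(b), k))[, k:1, drop = FALSE],
        1, paste, collapse = "")
}

# naive dictionary k-mer counter with strand symmetrization and N-window
# skipping
naive_symmetrized_counts <- function(seq, k) {
  count_one <- function(s) {
    n <- nchar(s)
    words <- substring(s, 1:(n - k + 1), k:n)
    words <- words[!grepl("N", words, fixed = TRUE)]
    table(factor(words, levels = all_kmers(k)))
  }
  cnt <- count_one(seq) + count_one(rc_chr(seq))
  stats::setNames(as.integer(cnt), all_kmers(k))
}

naive_rho <- function(seq, k) {
  cnt <- naive_symmetrized_counts(seq, k)
  f <- cnt / sum(cnt)
  nt <- naive_symmetrized_counts(seq, 1)
  fnt <- nt / sum(nt)
  vapply(names(f), function(w) {
    den <- prod(fnt[strsplit(w, "")[[1]]])
    if (f[[w]] == 0 || den == 0) 0 else f[[w]] / den
  }, 0)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exhaustive minimum-change score over all internal labelings (binary states)
exhaustive_parsimony <- function(tree, leaf_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- c(as.integer(leaf_states[tree$tip.label]), rep(NA_integer_, nint))
  grid <- as.matrix(expand.grid(rep(list(0:1), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    states[ntip + seq_len(nint)] <- grid[g, ]
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# brute-force per-edge placement log-likelihood: explicit summation over all
# internal-node states of the grafted tree (gap-free references; tips fixed)
brute_edge_loglik <- function(rp, aligned_fragment, model, pendant, edge) {
  tree <- rp$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  u <- tree$edge[edge, 1]; v <- tree$edge[edge, 2]
  t <- tree$edge.length[edge]
  m <- nnode + 1L; fr <- nnode + 2L
  edges <- rbind(
    cbind(tree$edge, tree$edge.length)[-edge, , drop = FALSE],
    c(m, u, t / 2), c(m, v, t / 2), c(m, fr, pendant))
  bases <- c(A = 1, C = 2, G = 3, T = 4)
  aln_chars <- lapply(rp$alignment, function(s) bases[strsplit(s, "")[[1]]])
  frag_chars <- strsplit(aligned_fragment, "")[[1]]
  cols <- which(frag_chars != "-")
  internal <- c(setdiff(unique(tree$edge[, 1]), seq_len(ntip)), m)
  Pmats <- lapply(seq_len(nrow(edges)), function(i)
    transition_prob(model, edges[i, 3]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (col in cols) {
    state <- integer(nnode + 2L)
    for (tip in seq_len(ntip)) state[tip] <- aln_chars[[tip]][col]
    state[fr] <- bases[[frag_chars[col]]]
    L <- 0
    for (g in seq_len(nrow(grid))) {
      state[internal] <- grid[g, ]
      p <- 0.25
      for (i in seq_len(nrow(edges))) {
        p <- p * Pmats[[i]][state[edges[i, 1]], state[edges[i, 2]]]
      }
      L <- L + p
    }
    total <- total + log(L)
  }
  total
}

# small reference package reused across placement tests
tiny_refpkg <- function(n_ingroup = 4, seq_length = 40, seed = 11) {
  make_reference_package(n_ingroup = n_ingroup, n_clades = 2, n_outgroup = 0,
                         seq_length = seq_length, depth = 0.4, seed = seed)
}
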