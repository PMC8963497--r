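# Per-context base probabilities for a Markov nucleotide chain whose
# stationary GC is exactly `gc`: within every context, p(G)+p(C) = gc and the
# G-vs-C and A-vs-T splits are Beta-perturbed to create k-mer scale structure.
markov_context_probs <- function(gc, order, beta_shape = 5) {
  n_ctx <- 4L^order
  probs <- matrix(0, n_ctx, 4, dimnames = list(NULL, base_order))
  wg <- if (order == 0) rep(0.5, n_ctx) else stats::rbeta(n_ctx, beta_shape, beta_shape)
  wa <- if (order == 0) rep(0.5, n_ctx) else stats::rbeta(n_ctx, beta_shape, beta_shape)
  probs[, "G"] <- gc * wg
  probs[, "C"] <- gc * (1 - wg)
  probs[, "A"] <- (1 - gc) * wa
  probs[, "T"] <- (1 - gc) * (1 - wa)
  probs
}

# Generate an integer-coded (1..4) sequence from context probabilities.
markov_chain_seq <- function(len, probs, order) {
  out <- integer(len)
  if (order == 0) {
    # iid
    p <- probs[1, ]
    return(sample.int(4, len, replace = TRUE, prob = p))
  }
  cum <- t(apply(probs, 1, cumsum))
  out[1:order] <- sample.int(4, order, replace = TRUE,
                             prob = colMeans(probs))
  ctx_mult <- 4L^(seq_len(order) - 1L)  # little-endian context code
  u <- stats::runif(len)
  for (i in (order + 1L):len) {
    ctx <- sum((out[(i - order):(i - 1L)] - 1L) * ctx_mult) + 1L
    out[i] <- findInterval(u[i], cum[ctx, ], left.open = TRUE) + 1L
  }
  out
}

#' Simulate a host genome with an inserted island
#'
#' The host and the island are generated by independent nucleotide chains
#' (iid or 3rd-order Markov) with their own GC targets, then the island is
#' inserted at a uniformly drawn position at least 500 bp from either end.
#' Transposase/tRNA marker annotations are planted at the island bounds,
#' emulating the flanking mobile elements of a horizontally acquired
#' catabolic island. Setting `island_gc = host_gc` (and the same order)
#' yields an island that is compositionally indistinguishable from the host,
#' the situation in which an island scan should return a null verdict.
#'
#' @param host_len,island_len Lengths in bp (>= 1000 each; island <= host).
#' @param host_gc,island_gc GC fractions in (0, 1).
#' @param order Markov order, 0 (iid) or 3.
#' @param seed Optional integer seed.
#' @return List with `record` (data.frame: id, description, residues),
#'   `truth` (genome_id, island_start, island_end, host_gc, island_gc), and
#'   `annotations` (planted flanking marker rows).
#' @export
simulate_genome_with_island <- function(host_len, host_gc, island_len,
                                        island_gc, order = 0, seed = NULL) {
  if (host_len < 1000 || island_len < 1000) stop("lengths must be >= 1000")
  if (island_len > host_len) stop("island longer than host")
  if (host_gc <= 0 || host_gc >= 1 || island_gc <= 0 || island_gc >= 1) {
    stop("gc fractions must be in (0, 1)")
  }
  if (!order %in% c(0, 3)) stop("order must be 0 or 3")
  if (!is.null(seed)) set.seed(seed)
  host_probs <- markov_context_probs(host_gc, order)
  island_probs <- markov_context_probs(island_gc, order)
  host <- markov_chain_seq(host_len, host_probs, order)
  island <- markov_chain_seq(island_len, island_probs, order)
  pos <- sample(500:(host_len - 500), 1)  # insertion point, after this base
  genome <- c(host[1:pos], island, host[(pos + 1):host_len])
  residues <- paste(base_order[genome], collapse = "")
  island_start <- pos + 1L
  island_end <- pos + island_len
  gid <- "synthetic_genome_1"
  annotations <- data.frame(
    genome_id = gid,
    locus_tag = c("ISL_tnpA_left", "ISL_tnpA_right", "ISL_tRNA_left"),
    contig_id = "contig1",
    start = c(island_start, island_end - 999L, max(1L, island_start - 80L)),
    end = c(island_start + 999L, island_end, max(76L, island_start - 5L)),
    strand = c("+", "-", "+"),
    ko_id = "",
    product = c("MULE-superfamily transposase", "MULE-superfamily transposase",
                "tRNA-Pro"))
  list(record = data.frame(id = gid, description = "host with inserted island",
                           residues = residues),
       truth = list(genome_id = gid, island_start = island_start,
                    island_end = island_end, host_gc = host_gc,
                    island_gc = island_gc),
       annotations = annotations)
}
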