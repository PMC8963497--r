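#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T). N residues are excluded from both numerator and
#' denominator; a sequence of only Ns returns `NA`.
#'
#' @param seq A DNA string over A/C/G/T/N.
#' @return GC fraction in `[0, 1]`, or `NA` if no unambiguous bases.
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop("seq must be a single nonempty string")
  }
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                     c("A", "C", "G", "T"))
  tot <- sum(cnt)
  if (tot == 0) return(NA_real_)
  unname((cnt[["G"]] + cnt[["C"]]) / tot)
}

#' Sliding-window GC profile
#'
#' Non-overlapping windows by default (`step = window`). Windows start at
#' 1, 1 + step, ...; a trailing partial window is dropped. Coordinates are
#' 1-based inclusive. Windows with more than 10% N are flagged.
#'
#' @param seq DNA string.
#' @param window Window size in bp (5000 for whole genomes, 500 for island
#'   regions in the source analysis).
#' @param step Step size in bp; defaults to `window`.
#' @return data.frame with columns `start`, `end`, `gc`, `n_frac`, `flagged`.
#' @export
sliding_gc <- function(seq, window, step = window) {
  len <- nchar(seq)
  if (window < 1 || window > len) stop("window must be in [1, length(seq)]")
  if (step < 1) stop("step must be >= 1")
  starts <- seq.int(1L, len - window + 1L, by = step)
  x <- Biostrings::DNAString(seq)
  v <- Biostrings::Views(x, start = starts, width = window)
  cnt <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
  acgt <- rowSums(cnt[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt == 0, NA_real_,
               (cnt[, "G"] + cnt[, "C"]) / acgt)
  n_frac <- cnt[, "N"] / window
  data.frame(start = starts, end = starts + window - 1L,
             gc = unname(gc), n_frac = unname(n_frac),
             flagged = unname(n_frac > 0.1))
}

#' Genome signature: symmetrized k-mer relative abundances
#'
#' Word counts are accumulated over the sequence and its reverse complement
#' (strand symmetrization); windows containing N contribute to no word.
#' Frequencies `f` are normalized over the counted windows. Relative
#' abundances are, for the default zeroth-order normalization,
#' `rho*_w = f_w / prod(f_nucleotides of w)`, with single-nucleotide
#' frequencies taken from the same symmetrized counts. The `"mmax"` option
#' applies the maximal-order Markov normalization
#' `f_w * f_mid / (f_prefix * f_suffix)` instead. Words with zero frequency
#' get `rho* = 0`.
#'
#' @param seq DNA string, length >= k + 3.
#' @param k Word size, one of 2, 3, 4 (default 4, tetranucleotides).
#' @param normalization "zeroth" (default) or "mmax".
#' @return An object of class `signature_vector` with elements `k`, `f`,
#'   `rho`, `n_words`, `nt_freq`, `normalization`.
#' @export
genome_signature <- function(seq, k = 4, normalization = c("zeroth", "mmax")) {
  normalization <- match.arg(normalization)
  if (!k %in% c(2, 3, 4)) stop("k must be 2, 3, or 4")
  if (nchar(seq) < k + 3) stop("sequence shorter than k + 3")
  x <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(x)
  kmer_f <- function(kk) {
    counts <- Biostrings::oligonucleotideFrequency(x, kk) +
      Biostrings::oligonucleotideFrequency(rc, kk)
    tot <- sum(counts)
    if (tot == 0) stop("no N-free windows of size ", kk, " in sequence")
    list(f = counts / tot, n = tot)
  }
  top <- kmer_f(k)
  f <- top$f
  nt <- kmer_f(1)$f
  words <- names(f)
  rho <- if (normalization == "zeroth") {
    denom <- vapply(strsplit(words, ""), function(w) prod(nt[w]), 0)
    ifelse(f == 0, 0, ifelse(denom == 0, 0, f / denom))
  } else {
    fk1 <- kmer_f(k - 1)$f
    fk2 <- if (k >= 3) kmer_f(k - 2)$f else NULL
    pre <- substr(words, 1, k - 1)
    suf <- substr(words, 2, k)
    mid <- substr(words, 2, k - 1)
    fmid <- if (k == 2) rep(1, length(words)) else fk2[mid]
    denom <- fk1[pre] * fk1[suf]
    ifelse(f == 0, 0, ifelse(denom == 0, 0, f * fmid / denom))
  }
  structure(list(k = k, f = f, rho = stats::setNames(as.numeric(rho), words),
                 n_words = top$n, nt_freq = nt, normalization = normalization),
            class = "signature_vector")
}

#' @export
print.signature_vector <- function(x, ...) {
  cat("Genome signature: k =", x$k, "(", x$normalization,
      "normalization ),", x$n_words, "symmetrized words\n")
  cat("rho* range:", signif(min(x$rho), 4), "-", signif(max(x$rho), 4), "\n")
  invisible(x)
}

#' delta* genome-signature difference
#'
#' `delta* = (1 / 4^k) * sum_w |rho*_w(a) - rho*_w(b)|`: the mean absolute
#' difference between two relative-abundance vectors. Returned raw, with the
#' conventional x1000 value attached as attribute `"x1000"`.
#'
#' @param a,b `signature_vector` objects sharing the same `k` and
#'   normalization.
#' @return Nonnegative scalar; attribute `x1000` carries `1000 * delta*`.
#' @export
delta_star <- function(a, b) {
  stopifnot(inherits(a, "signature_vector"), inherits(b, "signature_vector"))
  if (a$k != b$k) stop("signatures have mismatched k: ", a$k, " vs ", b$k)
  if (a$normalization != b$normalization) {
    stop("signatures have mismatched normalizations")
  }
  d <- mean(abs(a$rho[names(a$rho)] - b$rho[names(a$rho)]))
  attr(d, "x1000") <- 1000 * d
  d
}

#' Composition scan of a candidate genomic island
#'
#' Computes delta*(region, genome) and the GC content of both, then builds an
#' empirical null distribution of delta* from random same-length windows of
#' the genome. The region's percentile within that null operationalizes
#' "significance": a percentile <= 95 is reported as compositionally
#' indistinguishable from the host genome (the amelioration signature of an
#' old or close-relative transfer), > 95 as distinct.
#'
#' @param genome DNA string of the full genome (island included).
#' @param region Integer vector `c(start, end)`, 1-based inclusive.
#' @param n_null_windows Number of random null windows (>= 100).
#' @param seed Optional integer seed for the null-window draw.
#' @param k Word size for the signature.
#' @return A list with `delta_obs`, `delta_x1000`, `gc_region`, `gc_genome`,
#'   `percentile`, `verdict`, and the vector `null_delta`.
#' @export
island_scan <- function(genome, region, n_null_windows = 200, seed = NULL,
                        k = 4) {
  len <- nchar(genome)
  start <- as.integer(region[1]); end <- as.integer(region[2])
  if (start < 1 || end > len || start > end) {
    stop("region must lie within the genome")
  }
  if (n_null_windows < 100) stop("n_null_windows must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  w <- end - start + 1L
  sig_g <- genome_signature(genome, k)
  sig_r <- genome_signature(substr(genome, start, end), k)
  obs <- as.numeric(delta_star(sig_r, sig_g))
  # null windows must not overlap the query region (a region should not be
  # compared against windows of itself); degenerate regions covering the
  # whole genome fall back to unrestricted windows
  all_starts <- seq_len(len - w + 1L)
  overlap <- all_starts >= (start - w + 1L) & all_starts <= end
  valid <- all_starts[!overlap]
  if (length(valid) == 0) valid <- all_starts
  null_starts <- valid[sample.int(length(valid), n_null_windows,
                                  replace = TRUE)]
  null_delta <- vapply(null_starts, function(s) {
    as.numeric(delta_star(genome_signature(substr(genome, s, s + w - 1L), k), sig_g))
  }, 0)
  pct <- 100 * mean(null_delta < obs)
  list(delta_obs = obs, delta_x1000 = 1000 * obs,
       gc_region = gc_content(substr(genome, start, end)),
       gc_genome = gc_content(genome),
       percentile = pct,
       verdict = if (pct <= 95) "indistinguishable" else "distinct",
       null_delta = null_delta,
       region = c(start = start, end = end), window = w)
}
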