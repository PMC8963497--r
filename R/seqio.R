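#' Read a FASTA file of DNA sequences
#'
#' Reads sequence records, uppercases residues, and validates that the
#' alphabet is restricted to A, C, G, T, N. Windows-style line endings are
#' tolerated. IDs (the first whitespace-delimited token of each header) must
#' be unique within a file.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA format error in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA format error in ", path, ": file contains no records")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("FASTA format error in ", path, ": duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  residues <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", residues)
  if (any(bad)) {
    # locate the offending line for the error message
    lines <- sub("\r$", "", readLines(path, warn = FALSE))
    is_seq <- !startsWith(lines, ">") & nzchar(lines)
    off <- which(is_seq & grepl("[^ACGTNacgtn]", lines))[1]
    ch <- regmatches(lines[off], regexpr("[^ACGTNacgtn]", lines[off]))
    stop("FASTA format error in ", path, ", line ", off,
         ": non-ACGTN character '", ch, "'")
  }
  empty <- !nzchar(residues)
  if (any(empty)) {
    stop("FASTA format error in ", path, ": empty sequence for id ",
         ids[which(empty)[1]])
  }
  data.frame(id = ids, description = desc, residues = residues,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records A data.frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          residues = unname(records), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "residues") %in% names(records)))
  nm <- records$id
  if (!is.null(records$description)) {
    has_desc <- nzchar(records$description)
    nm[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::DNAStringSet(records$residues)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA sequence
#'
#' @param seq A single DNA string over A/C/G/T/N.
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a Newick tree
#'
#' Parses a single Newick tree. Missing branch lengths default to 0 with a
#' warning; duplicate leaf labels and unbalanced parentheses are errors.
#'
#' @param path Path to a Newick file, or a literal Newick string.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) {
    paste(sub("\r$", "", readLines(path, warn = FALSE)), collapse = "")
  } else path
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse error: could not parse tree")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("Newick parse error: duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("Newick tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("Newick tree has missing branch lengths; defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("Newick parse error: negative branch lengths")
  }
  tree
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

annotation_columns <- c("genome_id", "locus_tag", "contig_id", "start", "end",
                        "strand", "ko_id", "product")

#' Read a gene-annotation table
#'
#' Tab-separated, with a header row carrying the eight columns `genome_id`,
#' `locus_tag`, `contig_id`, `start`, `end`, `strand`, `ko_id`, `product`.
#' Coordinates are 1-based inclusive. An empty `ko_id` means the gene is
#' unannotated. Row-level violations are reported with the file line number.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame of annotation rows.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(annotation_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("Annotation table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[annotation_columns]
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$ko_id[is.na(df$ko_id)] <- ""
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_coord <- is.na(df$start) | is.na(df$end) | df$start < 1L | df$start > df$end
  if (any(bad_coord)) {
    stop("Annotation table ", path, ", line ", line[which(bad_coord)[1]],
         ": invalid coordinates (require 1 <= start <= end)")
  }
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("Annotation table ", path, ", line ", line[which(bad_strand)[1]],
         ": unknown strand '", df$strand[which(bad_strand)[1]], "'")
  }
  dup <- duplicated(df[c("genome_id", "locus_tag")])
  if (any(dup)) {
    stop("Annotation table ", path, ", line ", line[which(dup)[1]],
         ": duplicate locus_tag '", df$locus_tag[which(dup)[1]],
         "' within genome ", df$genome_id[which(dup)[1]])
  }
  df
}

#' Write an annotation table
#'
#' @param annotations Annotation data.frame (1-based inclusive coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations[annotation_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention exactly (start - 1, end).
#'
#' @param intervals data.frame with columns `start`, `end` and optionally
#'   `name`; 1-based inclusive.
#' @param chrom Chromosome/contig name recycled across rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, chrom, path) {
  stopifnot(all(c("start", "end") %in% names(intervals)))
  nm <- if (!is.null(intervals$name)) intervals$name else
    paste0("region", seq_len(nrow(intervals)))
  bed <- data.frame(chrom = chrom, start = intervals$start - 1L,
                    end = intervals$end, name = nm)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Edge-numbered Newick for jplace: edge numbers are row indices of tree$edge.
jplace_tree_string <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- tree$edge.length
  if (is.null(bl)) bl <- rep(0, nrow(tree$edge))
  rec <- function(node, edge_row) {
    lab <- if (node <= ntip) {
      tree$tip.label[node]
    } else {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, function(e) rec(tree$edge[e, 2], e), ""),
                        collapse = ","), ")")
    }
    if (is.na(edge_row)) paste0(lab, ":0") else
      paste0(lab, ":", format(bl[edge_row], digits = 12), "{", edge_row, "}")
  }
  paste0(rec(ntip + 1L, NA_integer_), ";")
}

#' Write placements in jplace format
#'
#' Serializes placements against an edge-numbered Newick tree. Edge numbers
#' are the row indices of the ape edge matrix of `tree`. Fields follow the
#' jplace standard: `edge_num`, `likelihood`, `like_weight_ratio`.
#'
#' @param placements A list; each element is a list with `name` (fragment id)
#'   and `p`, a data.frame with columns `edge_num`, `likelihood`,
#'   `like_weight_ratio`. May be empty.
#' @param tree Reference tree ([ape::phylo]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placements, tree, path) {
  n_edges <- nrow(tree$edge)
  pl <- lapply(placements, function(p) {
    stopifnot(!is.null(p$name), !is.null(p$p))
    if (any(p$p$edge_num < 1L | p$p$edge_num > n_edges)) {
      stop("jplace consistency error: placement for '", p$name,
           "' references an edge not present in the tree")
    }
    mat <- cbind(p$p$edge_num, p$p$likelihood, p$p$like_weight_ratio)
    list(p = unname(split(mat, row(mat))), n = list(p$name))
  })
  obj <- list(
    version = 3L,
    tree = jplace_tree_string(tree),
    placements = pl,
    fields = c("edge_num", "likelihood", "like_weight_ratio"),
    metadata = list(invocation = "methoxr::write_jplace")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a jplace file
#'
#' @param path Path to a jplace file.
#' @return A list with `tree` (edge-numbered Newick string), `fields`, and
#'   `placements`, a data.frame with one row per (fragment, edge).
#' @export
read_jplace <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fields <- unlist(obj$fields)
  rows <- lapply(obj$placements, function(p) {
    nm <- unlist(p$n)[1]
    if (length(p$p) == 0) return(NULL)
    mat <- do.call(rbind, lapply(p$p, unlist))
    df <- as.data.frame(mat)
    names(df) <- fields
    df$name <- nm
    df
  })
  placements <- do.call(rbind, rows)
  if (is.null(placements)) {
    placements <- data.frame(edge_num = integer(), likelihood = numeric(),
                             like_weight_ratio = numeric(), name = character())
  }
  placements$edge_num <- as.integer(placements$edge_num)
  list(tree = obj$tree, fields = fields, placements = placements)
}
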