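# round half away from zero
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Filter metagenomes by vanA-gene count
#'
#' Keeps metagenomes whose count strictly exceeds `min_count` (the survey's
#' ">100 genes" rule; the boundary value is excluded).
#'
#' @param metas data.frame with columns `metagenome_id` and `vana_count`.
#' @param min_count Threshold (default 100).
#' @return The kept subset of `metas`.
#' @export
filter_metagenomes <- function(metas, min_count = 100) {
  stopifnot(all(c("metagenome_id", "vana_count") %in% names(metas)))
  if (any(metas$vana_count < 0)) stop("negative vanA count")
  metas[metas$vana_count > min_count, , drop = FALSE]
}

#' Select candidate fragments by lineage label
#'
#' Candidates are fragments whose scaffold lineage assignment matches the
#' target genus set (default Methylobacterium or Methylorubrum),
#' case-insensitively on the first whitespace-delimited token. Fragments with
#' a missing label are skipped with a warning.
#'
#' @param fragments data.frame with columns `fragment_id` and `lineage`.
#' @param genera Character vector of genus names to match.
#' @return The candidate subset of `fragments`.
#' @export
select_candidates <- function(fragments,
                              genera = c("Methylobacterium", "Methylorubrum")) {
  stopifnot(all(c("fragment_id", "lineage") %in% names(fragments)))
  lab <- fragments$lineage
  missing <- is.na(lab) | !nzchar(trimws(ifelse(is.na(lab), "", lab)))
  if (any(missing)) {
    warning(sum(missing), " fragment(s) without a lineage label were skipped")
  }
  genus <- tolower(sub("\\s.*$", "", trimws(ifelse(is.na(lab), "", lab))))
  fragments[!missing & genus %in% tolower(genera), , drop = FALSE]
}

#' Conservative dual-classifier intersection
#'
#' Confirmed fragments are candidates whose phylogenetic placement also falls
#' inside an in-genus clade: placements of `"outside"` or into a clade
#' labeled `"outgroup"` are excluded. Every candidate must have a
#' classification.
#'
#' @param candidates data.frame with a `fragment_id` column (from
#'   [select_candidates()]).
#' @param classifications data.frame with columns `name` (fragment id) and
#'   `clade` (from [classify_batch()] or an oracle).
#' @return The confirmed subset of `candidates`, with a `clade` column
#'   appended.
#' @export
conservative_intersect <- function(candidates, classifications) {
  idx <- match(candidates$fragment_id, classifications$name)
  if (anyNA(idx)) {
    stop("candidate(s) without a classification: ",
         paste(utils::head(candidates$fragment_id[is.na(idx)], 5),
               collapse = ", "))
  }
  clade <- classifications$clade[idx]
  keep <- !is.na(clade) & tolower(clade) != "outside" &
    !startsWith(tolower(clade), "outgroup")
  out <- candidates[keep, , drop = FALSE]
  out$clade <- clade[keep]
  out
}

#' The shipped Ecosystem-Type to Sample-Type mapping
#'
#' Covers the documented pairs (Phyllosphere/Phylloplane -> Leaf,
#' Rhizosphere/Rhizoplane -> Root) plus obvious identities; extensible via
#' [map_sample_type()]'s `extra` argument.
#'
#' @return Named character vector: raw ecosystem string -> sample type.
#' @export
sample_type_map <- function() {
  c(Phyllosphere = "Leaf", Phylloplane = "Leaf", Leaf = "Leaf",
    Rhizosphere = "Root", Rhizoplane = "Root", Root = "Root", Roots = "Root",
    Soil = "Soil", Peat = "Soil", Permafrost = "Soil",
    Sediment = "Sediment",
    Freshwater = "Aquatic", Marine = "Aquatic", Aquatic = "Aquatic",
    Wastewater = "Engineered", Bioreactor = "Engineered",
    Compost = "Engineered")
}

#' Map raw ecosystem strings to sample types
#'
#' Total function: unmapped strings map to `"Other"` with a warning.
#'
#' @param ecosystem_fields Character vector of raw Ecosystem-Type strings.
#' @param extra Optional named character vector extending/overriding the
#'   shipped [sample_type_map()].
#' @return Character vector of sample types.
#' @export
map_sample_type <- function(ecosystem_fields, extra = NULL) {
  tbl <- sample_type_map()
  if (!is.null(extra)) tbl[names(extra)] <- extra
  key <- trimws(ecosystem_fields)
  out <- unname(tbl[key])
  unmapped <- is.na(out)
  if (any(unmapped)) {
    warning("unmapped ecosystem string(s) -> 'Other': ",
            paste(unique(key[unmapped]), collapse = ", "))
    out[unmapped] <- "Other"
  }
  out
}

#' Summarize a vanA metagenome survey
#'
#' Per-clade and per-sample-type counts over the confirmed fragments, with
#' integer percents (rounded half away from zero) and exact raw fractions;
#' the candidate frequency among all scaffolds is reported as a percent with
#' 2 decimals.
#'
#' @param confirmed data.frame of confirmed fragments with columns `clade`
#'   and `sample_type` (see [conservative_intersect()], [map_sample_type()]).
#' @param n_candidates Number of lineage-labeled candidate fragments.
#' @param n_total Total scaffolds carrying the marker across metagenomes.
#' @return Object of class `survey_summary`: totals, per-clade and
#'   per-sample-type counts, integer percents and raw fractions, and the
#'   candidate frequency.
#' @export
summarize_survey <- function(confirmed, n_candidates, n_total) {
  n_confirmed <- nrow(confirmed)
  if (n_confirmed > n_candidates || n_candidates > n_total) {
    stop("expected confirmed <= candidates <= total")
  }
  tab_of <- function(x) {
    counts <- sort(table(x), decreasing = TRUE)
    frac <- as.numeric(counts) / n_confirmed
    data.frame(level = names(counts), count = as.integer(counts),
               fraction = frac,
               percent = if (n_confirmed == 0) NA_real_ else
                 round_half_away(100 * frac))
  }
  structure(list(
    n_total = n_total,
    n_candidates = n_candidates,
    n_confirmed = n_confirmed,
    candidate_frequency_pct = round_half_away(100 * n_candidates / n_total, 2),
    candidate_fraction = n_candidates / n_total,
    by_clade = if (n_confirmed > 0) tab_of(confirmed$clade) else NULL,
    by_sample_type = if (n_confirmed > 0 && !is.null(confirmed$sample_type))
      tab_of(confirmed$sample_type) else NULL),
    class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("vanA survey:", x$n_total, "scaffolds;", x$n_candidates,
      "lineage-labeled candidates (", x$candidate_frequency_pct, "% );",
      x$n_confirmed, "confirmed by placement\n")
  if (!is.null(x$by_clade)) {
    cat("By clade:\n"); print(x$by_clade, row.names = FALSE)
  }
  if (!is.null(x$by_sample_type)) {
    cat("By sample type:\n"); print(x$by_sample_type, row.names = FALSE)
  }
  invisible(x)
}

#' Tally an externally supplied read-recruitment hit table
#'
#' Summarizes precomputed BLAST-style hit counts (reads with >= 90% identity
#' to a query genome) per genome and sample type. The aligner itself is out
#' of scope; this is the tallying stage only.
#'
#' @param hits data.frame with columns `genome_id`, `metagenome_id`,
#'   `n_hits`, and `sample_type`.
#' @return data.frame with one row per genome x sample type: summed hits and
#'   the within-genome percent (half-away-from-zero integer).
#' @export
tally_hits <- function(hits) {
  stopifnot(all(c("genome_id", "metagenome_id", "n_hits", "sample_type")
                %in% names(hits)))
  agg <- stats::aggregate(n_hits ~ genome_id + sample_type, data = hits, sum)
  tot <- stats::aggregate(n_hits ~ genome_id, data = hits, sum)
  agg$percent <- round_half_away(
    100 * agg$n_hits / tot$n_hits[match(agg$genome_id, tot$genome_id)])
  agg[order(agg$genome_id, -agg$n_hits), ]
}
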