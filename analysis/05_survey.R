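#!/usr/bin/env Rscript
# Stage 5: the metagenome survey — filter metagenomes by vanA count (>100),
# select in-genus candidates by lineage label, intersect with the placement
# calls (the conservative dual-classifier rule), map ecosystems to sample
# types, and summarize clade / sample-type proportions.

suppressMessages(library(methoxr))
dir.create("results", showWarnings = FALSE)

metas <- utils::read.delim("results/simulated/survey_metadata.tsv")
truth <- utils::read.delim("results/simulated/survey_truth.tsv")
cls <- utils::read.delim("results/04_classifications.tsv")

kept <- filter_metagenomes(metas, min_count = 100)
cat("Metagenome filter (>100 vanA):", nrow(kept), "of", nrow(metas),
    "metagenomes kept\n")
frags <- truth[truth$metagenome_id %in% kept$metagenome_id, ]

candidates <- select_candidates(frags)
cat("Candidates (in-genus lineage label):", nrow(candidates), "of",
    nrow(frags), "scaffolds\n")

confirmed <- conservative_intersect(candidates, cls)
confirmed$sample_type <- map_sample_type(confirmed$ecosystem)
cat("Confirmed by the dual-classifier intersection:", nrow(confirmed), "\n")

s <- summarize_survey(confirmed, n_candidates = nrow(candidates),
                      n_total = nrow(frags))
print(s)
utils::write.table(s$by_clade, "results/05_survey_by_clade.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(s$by_sample_type, "results/05_survey_by_sample_type.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# long table for per-metagenome bar plots
long <- stats::aggregate(
  fragment_id ~ metagenome_id + clade + sample_type, data = confirmed, length)
names(long)[4] <- "n_fragments"
utils::write.table(long, "results/05_survey_long.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# how well did the conservative rule work against truth?
unconfirmed <- candidates[!candidates$fragment_id %in% confirmed$fragment_id, ]
cat("Of the unconfirmed candidates,",
    sum(unconfirmed$true_lineage == "outgroup"), "of", nrow(unconfirmed),
    "were truly outgroup contaminants\n")
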