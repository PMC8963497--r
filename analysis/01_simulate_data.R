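#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume,
# with ground truth: a clade-labeled vanA reference package, host genomes
# with planted catabolic islands (one compositionally shifted, one not),
# a marker gain/loss history on a species tree, and a metagenome survey.

suppressMessages(library(methoxr))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)
out <- function(...) file.path("results/simulated", ...)

## Reference package: 12 ingroup leaves in 3 clades + 3 outgroup leaves
mk <- make_reference_package(seed = 101)
write_fasta(mk$sequences, out("vanA_reference_alignment.fasta"))
write_newick(mk$tree, out("vanA_reference_tree.nwk"))
utils::write.table(
  data.frame(leaf = names(mk$clades), clade = unname(mk$clades)),
  out("vanA_clade_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
cat("Reference package:", length(mk$sequences), "leaves;",
    "clades:", paste(names(table(mk$clades)), table(mk$clades),
                     collapse = ", "), "\n")

## Host genomes with planted islands
shifted <- simulate_genome_with_island(30000, 0.50, 5000, 0.70, order = 3,
                                       seed = 73)
ameliorated <- simulate_genome_with_island(30000, 0.60, 5000, 0.60, order = 0,
                                           seed = 21)
write_fasta(data.frame(id = c("shifted_island_genome",
                              "ameliorated_island_genome"),
                       description = "",
                       residues = c(shifted$record$residues,
                                    ameliorated$record$residues)),
            out("island_genomes.fasta"))
truth <- rbind(
  data.frame(genome = "shifted_island_genome",
             start = shifted$truth$island_start,
             end = shifted$truth$island_end, host_gc = 0.50, island_gc = 0.70),
  data.frame(genome = "ameliorated_island_genome",
             start = ameliorated$truth$island_start,
             end = ameliorated$truth$island_end, host_gc = 0.60,
             island_gc = 0.60))
utils::write.table(truth, out("island_truth.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("Planted islands at", truth$start[1], "-", truth$end[1], "(shifted) and",
    truth$start[2], "-", truth$end[2], "(same-composition)\n")

## Marker gain/loss history on a 16-leaf species tree
sp_tree <- simulate_tree(16, seed = 301)
write_newick(sp_tree, out("species_tree.nwk"))
hist <- simulate_gain_loss(sp_tree, gain_rate = 0.4, loss_rate = 0.2,
                           seed = 302)
utils::write.table(
  data.frame(leaf = names(hist$leaf_states), present = hist$leaf_states),
  out("marker_history_leaves.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(hist$events, out("marker_history_events.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Gain/loss history:", hist$n_events, "true events;",
    sum(hist$leaf_states), "of 16 leaves carry the marker\n")

## Metagenome survey (sequences attached from the reference package)
sv <- simulate_survey(8, contamination_rate = 0.3,
                      counts_range = c(80, 150), seed = 61, refpkg = mk)
write_fasta(sv$sequences, out("survey_fragments.fasta"))
utils::write.table(sv$metadata, out("survey_metadata.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sv$fragments, out("survey_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Survey:", nrow(sv$metadata), "metagenomes,", nrow(sv$fragments),
    "vanA scaffolds (", sum(sv$fragments$true_lineage == "outgroup"),
    "truly outgroup )\n")
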