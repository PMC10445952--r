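#!/usr/bin/env Rscript
## Stage 2: genome-organization analytics.
## Recomputes every feature length from its coordinates, classifies the
## inter-feature gaps into spacers and overlaps, audits the printed size
## column, reads start/stop codons off the simulated molecule and tallies
## base composition.

suppressPackageStartupMessages(library(mitopop))

ft <- read_feature_table("results/features.tsv")
genome <- paste(readLines("results/genome.fasta")[-1], collapse = "")

len <- feature_length(ft$start, ft$end)
adj <- adjacency_deltas(ft)
bad <- audit_printed_sizes(ft)

cat(sprintf("%d features; longest %s (%d bp), shortest %s (%d bp)\n",
            nrow(ft), ft$name[which.max(len)], max(len),
            ft$name[which.min(len)], min(len)))
cat(sprintf("%d spacers (%d-%d bp) and %d overlaps\n", adj$n_spacers,
            adj$spacer_range[1], adj$spacer_range[2], adj$n_overlaps))
cat(sprintf("printed-size audit: %d discrepancy(ies): %s\n", nrow(bad),
            paste(sprintf("%s printed %d vs computed %d", bad$name,
                          bad$printed_size, bad$computed_size), collapse = "; ")))

codons <- lapply(seq_len(nrow(ft)), function(i) {
  if (is.na(ft$start_codon[i])) return(c(NA, NA))
  unlist(extract_codons(genome, ft$start[i], ft$end[i], ft$strand[i]))
})
codons <- do.call(rbind, codons)

report <- data.frame(ft[, c("name", "start", "end", "strand")],
                     length = len,
                     delta = c(NA, adj$pairs$delta),
                     class = c(NA, adj$pairs$class),
                     start_codon = codons[, 1], stop_codon = codons[, 2])
utils::write.table(report, "results/layout_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

bc <- base_composition(genome)
cat(sprintf("base composition: A %.2f%% C %.2f%% G %.2f%% T %.2f%% (G+C %.2f%%)\n",
            bc$percent["A"], bc$percent["C"], bc$percent["G"], bc$percent["T"],
            bc$gc))
write_stats_json(c(as.list(bc$percent), list(at = bc$at, gc = bc$gc)),
                 "results/base_composition.json")
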