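#!/usr/bin/env Rscript
## Stage 3: control-region motif profiling and in-silico PCR.
## Scans the simulated genome for the conserved D-loop elements (invariant
## tetradecamer, TACAT/TATAT termination-associated motifs, the interrupted
## thymine string, poly-C and poly-G) and predicts every amplicon of the
## 15-pair primer panel on the circular molecule.

suppressPackageStartupMessages(library(mitopop))

genome <- paste(readLines("results/genome.fasta")[-1], collapse = "")
dloop <- substr(genome, 1, 1227)

motif_set <- c(tetradecamer = "AACTATGAATGGTT",
               thymine_string = "TTTTATTTTTTAA",
               poly_C = "CCCCCCCTTTCCCC",
               poly_G = "AGGGGGGGT",
               TACAT = "TACAT", TATAT = "TATAT")
hits <- do.call(rbind, lapply(names(motif_set), function(nm) {
  h <- find_motif(dloop, motif_set[[nm]])
  if (nrow(h)) cbind(element = nm, h) else NULL
}))
utils::write.table(hits, "results/dloop_motifs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
counts <- table(hits$element)
cat("D-loop motif hits:",
    paste(sprintf("%s x%d", names(counts), counts), collapse = ", "), "\n")
runs <- rbind(find_homopolymer_runs(dloop, "C", 5),
              find_homopolymer_runs(dloop, "G", 5))
cat(sprintf("%d homopolymer runs of length >= 5 in the D-loop\n", nrow(runs)))

primers <- read_primer_table(system.file("extdata", "table3_primers.tsv",
                                         package = "mitopop"))
pan <- pcr_panel(genome, primers)
utils::write.table(pan, "results/amplicons.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("in-silico PCR: %d/%d amplicons at their printed size (%d-%d bp)\n",
            sum(pan$matches_printed), nrow(pan), min(pan$length),
            max(pan$length)))
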