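#!/usr/bin/env Rscript
## Stage 1: generate the study inputs synthetically.
## A 16,775 bp circular mitogenome laid out like the chicken reference
## organization (19 features, control-region motifs, the 15-pair primer
## panel planted at its printed coordinates), plus a D-loop-sized haplotype
## population with transition-biased mutation. Everything downstream runs
## off these files; no external data is touched.

suppressPackageStartupMessages(library(mitopop))
dir.create("results", showWarnings = FALSE)

seed <- 20260925L

primers <- read_primer_table(system.file("extdata", "table3_primers.tsv",
                                         package = "mitopop"))
gen <- make_genome(primers = primers, seed = seed)
writeLines(c(">synthetic_mitogenome", gen$sequence), "results/genome.fasta")
utils::write.table(gen$layout$features, "results/features.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("genome: %d bp, %d features\n", nchar(gen$sequence),
            nrow(gen$layout$features)))

## D-loop-sized region, 8 matrilines on a coalescent genealogy
pop <- make_population(n = 8, length = 1227, genealogy = "coalescent",
                       theta = 0.005, ts_tv_bias = 15, seed = seed)
write_alignment(pop$aln, "results/population.fasta")
write_newick(pop$tree, "results/true_genealogy.nwk")
write_stats_json(list(theta = pop$theta, n = 8, length = 1227,
                      mutated_sites = pop$mutated_sites),
                 "results/population_truth.json")
cat(sprintf("population: n = 8, %d truly mutated sites\n",
            length(pop$mutated_sites)))
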