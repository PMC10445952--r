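#!/usr/bin/env Rscript
## Stage 4: haplotype structure and Nei diversity.
## Collapses the simulated D-loop alignment into haplotypes under complete
## deletion, renders the variable-site (dot) matrix, classifies the
## substitution spectrum, computes S / H / Hd / pi, and runs the
## haplotype-frequency differentiation permutation test between the two
## halves of the sample.

suppressPackageStartupMessages(library(mitopop))

aln <- read_alignment("results/population.fasta")
ht <- collapse_haplotypes(aln)
stats <- diversity_stats(ht)
cat(sprintf("n = %d sequences -> H = %d haplotypes, S = %d segregating sites\n",
            stats$n, stats$H, stats$S))
cat(sprintf("Hd = %.4f, pi = %.6f per site\n", stats$Hd, stats$pi))

haps <- ht$haplotypes
haps$members <- vapply(haps$members, paste, "", collapse = ",")
utils::write.table(haps, "results/haplotypes.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
write_stats_json(stats[c("S", "H", "Hd", "pi", "n", "nc")],
                 "results/diversity.json")

vm <- variable_site_matrix(ht, ref_name = ht$haplotypes$name[1])
writeLines(vm$text, "results/variable_sites.txt")

sp <- substitution_spectrum(ht)
cat(sprintf("substitutions vs H1: %d transitions, %d transversions\n",
            sp$transitions, sp$transversions))
write_stats_json(as.list(sp$counts), "results/substitution_spectrum.json")

## split the sample into two demes by index and test differentiation
half <- split(seq_along(aln$names), rep(1:2, each = length(aln$names) / 2))
tabs <- lapply(half, function(idx)
  collapse_haplotypes(aln_set(aln$rows[idx], aln$names[idx])))
dif <- differentiation(tabs[[1]], tabs[[2]], n_perm = 1000, seed = 99)
cat(sprintf("differentiation (Gst-style) = %.4f, permutation p = %.4f\n",
            dif$statistic, dif$p_value))
write_stats_json(dif[c("statistic", "p_value", "n_perm", "Ht", "Hs")],
                 "results/differentiation.json")
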