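test_that("motif search counts overlapping hits at 1-based positions", {
  expect_equal(find_motif("TATATATAT", "TATAT")$position, c(1L, 3L, 5L))
  expect_equal(nrow(find_motif("ACGTACGT", "GGG")), 0L)
  expect_error(find_motif("ACGT", ""), class = "mitopop_value_error")
  ## positions shift exactly by a planted flanking offset
  set.seed(41)
  core <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  hits0 <- find_motif(core, "ACG")$position
  flank <- strrep("T", 17)
  expect_equal(find_motif(paste0(flank, core), "ACG")$position,
               hits0 + 17L)
})

test_that("the tetradecamer planted in the synthetic D-loop is found at 264 and 325", {
  g <- make_genome(seed = 2)
  hits <- find_motif(g$sequence, "AACTATGAATGGTT")
  expect_true(all(c(264L, 325L) %in% hits$position))
  spans <- hits[hits$position %in% c(264L, 325L), ]
  expect_equal(spans$position + spans$length - 1L, c(277L, 338L))
})

test_that("homopolymer runs are maximal and match a hand scanner", {
  r <- find_homopolymer_runs("AGGGGGGGT", "G", 5)
  expect_equal(r$position, 2L)
  expect_equal(r$length, 7L)
  expect_equal(nrow(find_homopolymer_runs("CCCC", "C", 5)), 0L)
  set.seed(42)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C"), 200, replace = TRUE, prob = c(0.3, 0.7)),
               collapse = "")
    got <- find_homopolymer_runs(s, "C", 3)
    ## regex-free scanner
    ch <- strsplit(s, "")[[1]]
    runs <- list(); start <- NA
    for (p in seq_along(ch)) {
      if (ch[p] == "C" && is.na(start)) start <- p
      if ((ch[p] != "C" || p == length(ch)) && !is.na(start)) {
        end <- if (ch[p] == "C") p else p - 1L
        if (end - start + 1L >= 3L) runs[[length(runs) + 1L]] <- c(start, end - start + 1L)
        start <- NA
      }
    }
    exp <- do.call(rbind, runs)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$position, exp[, 1])
      expect_equal(got$length, exp[, 2])
    }
  }
})

test_that("conserved-block detection reports the violating columns", {
  a <- aln_set(c("ACGTACGT", "ACGTACGT", "ACGTACGT"))
  expect_true(conserved_block(a, 1, 8)$conserved)
  b <- aln_set(c("ACGTACGT", "ACGTACTT", "ACGTACGT"))
  expect_true(conserved_block(b, 1, 6)$conserved)     # variant outside range
  cb <- conserved_block(b, 1, 8)
  expect_false(cb$conserved)
  expect_equal(cb$violating_columns, 7L)
  ## missing data does not create variability
  d <- aln_set(c("ACGT", "AC-T", "ACNT"))
  expect_true(conserved_block(d, 1, 4)$conserved)
})

test_that("in-silico PCR reproduces planted amplicons, including across the origin", {
  set.seed(43)
  bg <- paste(sample(c("A", "C"), 500, replace = TRUE), collapse = "")
  fwd <- "GGATCGTTAGGCATTGAGGTT"   # 21-mer planted at 270..290
  rev <- "TTGACCTGATCGGACTGAATT"   # its reverse complement at 316..336
  g <- paste0(substr(bg, 1, 269), fwd,
              substr(bg, 291, 315), mitopop:::revcomp(rev),
              substr(bg, 337, 500))
  amp <- insilico_pcr(g, fwd, rev)
  expect_equal(amp$length, 67L)
  expect_equal(amp$start, 270L)
  expect_equal(amp$end, 336L)
  expect_false(amp$spans_origin)
  ## product straddling the origin of a 100 bp circular toy
  fwd2 <- "GATTACAGAT"
  rev2 <- "CCAGTTACAA"
  circ <- paste0(mitopop:::revcomp(rev2), substr(bg, 11, 90), fwd2)
  amp2 <- insilico_pcr(circ, fwd2, rev2)
  expect_equal(amp2$length, 20L)
  expect_equal(amp2$start, 91L)
  expect_equal(amp2$end, 10L)
  expect_true(amp2$spans_origin)
  expect_error(insilico_pcr(bg, "GGGGGGGGGGGG", rev),
               class = "mitopop_no_amplicon_error")
})

test_that("every primer-panel row amplifies at its printed size on the synthetic genome", {
  primers <- read_primer_table(extdata("table3_primers.tsv"))
  g <- make_genome(primers = primers, seed = 3)
  pan <- pcr_panel(g$sequence, primers)
  expect_equal(nrow(pan), 15L)
  expect_true(all(pan$matches_printed))
  expect_equal(pan$length[pan$region_start == 270], 67L)
  expect_equal(pan$length[pan$region_start == 3916], 338L)
  ## printed sizes equal the position range for all but two known rows
  off <- pan[!pan$matches_region, ]
  expect_setequal(off$region_start, c(14683L, 369L))
  expect_equal(off$length, off$region_end - off$region_start)
})
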