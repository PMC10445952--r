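test_that("haplotype collapsing merges identical rows and counts segregating sites", {
  ht0 <- collapse_haplotypes(aln_set(rep("ACGTACGT", 4)))
  expect_equal(nrow(ht0$haplotypes), 1L)
  expect_equal(ht0$x, 1)
  expect_equal(ht0$S, 0L)
  ht <- collapse_haplotypes(aln_set(c("ACGT", "ACGA", "ACGA"), c("a", "b", "c")))
  expect_equal(ht$haplotypes$count, c(1L, 2L))
  expect_equal(ht$haplotypes$name, c("H1", "H2"))
  expect_equal(ht$S, 1L)
  expect_equal(ht$sites, 4L)
  expect_equal(ht$haplotypes$members[[2]], c("b", "c"))
})

test_that("a gap column in any row is excluded for all rows (complete deletion)", {
  ht <- collapse_haplotypes(aln_set(c("ACG-T", "ACGAT", "ACGAT")))
  expect_equal(length(ht$retained_columns), 4L)
  expect_equal(nrow(ht$haplotypes), 1L)
  expect_equal(ht$retained_columns, c(1L, 2L, 3L, 5L))
  expect_error(collapse_haplotypes(aln_set(c("A-", "-A"))),
               class = "mitopop_degenerate_alignment_error")
  ## pairwise policy keeps all columns
  ht2 <- collapse_haplotypes(aln_set(c("ACG-T", "ACGAT")), gap_policy = "pairwise")
  expect_equal(length(ht2$retained_columns), 5L)
})

test_that("haplotype structure is invariant under row permutation", {
  set.seed(51)
  for (i in 1:20) {
    a <- random_aln(6, 30, alphabet = c("A", "G"))
    ht <- collapse_haplotypes(a)
    perm <- sample(length(a$names))
    b <- aln_set(a$rows[perm], a$names[perm])
    ht2 <- collapse_haplotypes(b)
    expect_equal(nrow(ht2$haplotypes), nrow(ht$haplotypes))
    expect_equal(ht2$S, ht$S)
    expect_setequal(ht2$haplotypes$pattern, ht$haplotypes$pattern)
    cnt <- setNames(ht$haplotypes$count, ht$haplotypes$pattern)
    expect_equal(unname(cnt[ht2$haplotypes$pattern]), ht2$haplotypes$count)
  }
})

test_that("S agrees with a direct column scan on random gapped alignments", {
  set.seed(52)
  for (i in 1:200) {
    a <- random_aln(sample(2:8, 1), sample(10:60, 1),
                    alphabet = c("A", "C", "G", "T", "-"))
    ht <- tryCatch(collapse_haplotypes(a),
                   mitopop_degenerate_alignment_error = function(e) NULL)
    if (is.null(ht)) next
    m <- as.matrix(a)
    keep <- colSums(m == "-") == 0L
    s_direct <- sum(apply(m[, keep, drop = FALSE], 2,
                          function(col) length(unique(col)) > 1L))
    expect_equal(ht$S, s_direct)
  }
})

test_that("substitution spectrum classifies transitions and transversions", {
  a <- aln_set(c("AAAA", "GAAA"))
  sp <- substitution_spectrum(collapse_haplotypes(a), reference = "AAAA")
  expect_equal(unname(sp$counts["A/G"]), 1L)
  expect_equal(sp$transversions, 0L)
  b <- aln_set(c("CC", "TC", "CA"))
  sp2 <- substitution_spectrum(collapse_haplotypes(b), reference = "CC")
  expect_equal(unname(sp2$counts["C/T"]), 1L)
  expect_equal(unname(sp2$counts["A/C"]), 1L)
  expect_equal(sp2$transitions, 1L)
  expect_equal(sp2$transversions, 1L)
  ## a triallelic site is counted once per alternate and flagged
  tri <- aln_set(c("A", "C", "G"))
  sp3 <- substitution_spectrum(collapse_haplotypes(tri), reference = "A")
  expect_equal(sp3$total, 2L)
  expect_equal(sp3$multiallelic_sites, 1L)
})

test_that("transition bias carries through from simulation to the spectrum", {
  pop <- make_population(8, length = 1000, theta = 0.02, ts_tv_bias = 15, seed = 61)
  ht <- collapse_haplotypes(pop$aln)
  sp <- substitution_spectrum(ht)
  expect_gt(sp$transitions, sp$transversions)
})

test_that("variable-site matrix renders dots and reconstructs the patterns", {
  a <- aln_set(c("ACGTA", "ACCTA", "ACGTG"), c("r", "x", "y"))
  ht <- collapse_haplotypes(a, reference = "r")
  vm <- variable_site_matrix(ht)
  expect_equal(vm$positions, c(3L, 5L))
  expect_equal(vm$reference, c("G", "A"))
  expect_equal(unname(vm$matrix["H1", ]), c("C", "."))
  expect_equal(unname(vm$matrix["H2", ]), c(".", "G"))
  ## reconstruction: dots replaced by the reference recover the patterns
  rec <- vm$matrix
  for (j in seq_along(vm$positions)) rec[rec[, j] == ".", j] <- vm$reference[j]
  pm <- do.call(rbind, strsplit(ht$haplotypes$pattern, ""))
  idx <- match(vm$positions, ht$retained_columns)
  expect_equal(unname(rec), unname(pm[, idx, drop = FALSE]))
  ## zero variable sites -> empty rendering
  same <- collapse_haplotypes(aln_set(c("AAA", "AAA")))
  expect_equal(length(variable_site_matrix(same)$positions), 0L)
})
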