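toy_table <- function(rows, names = NULL) collapse_haplotypes(aln_set(rows, names))

test_that("character condensation keeps variable sites with original positions", {
  mono <- toy_table(c("AAAA", "AAAA"))
  cc <- condense_characters(mono)
  expect_equal(ncol(cc$matrix), 0L)
  ht <- toy_table(c("ACGTAG", "ACCTAG", "ACGTAA"))
  cc2 <- condense_characters(ht)
  expect_equal(cc2$positions, c(3L, 6L))
  expect_equal(colnames(cc2$matrix), c("3", "6"))
  ## duplicate (perfectly correlated) columns are retained separately
  dup <- toy_table(c("AA", "GG"))
  cc3 <- condense_characters(dup)
  expect_equal(ncol(cc3$matrix), 2L)
})

test_that("chain haplotypes give a path with single-position edge labels", {
  net <- median_joining(toy_table(c("AAA", "GAA", "GGA", "GGG")))
  s <- network_summary(net)
  expect_equal(s$observed, 4L)
  expect_equal(s$median_vectors, 0L)
  expect_equal(s$edges, 3L)
  expect_setequal(vapply(net$edges$positions, paste, "", collapse = ","),
                  c("1", "2", "3"))
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(sort(unname(c(deg))), c(1L, 1L, 2L, 2L))  # a path graph
})

test_that("star data keeps the observed center at degree 4 with no medians", {
  net <- median_joining(toy_table(c("AAAA", "GAAA", "AGAA", "AAGA", "AAAG"),
                                  paste0("s", 1:5)))
  s <- network_summary(net)
  expect_equal(s$observed, 5L)
  expect_equal(s$median_vectors, 0L)
  expect_equal(s$edges, 4L)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[["H1"]]), 4L)
})

test_that("a three-haplotype cycle is resolved by one median vector", {
  net <- median_joining(toy_table(c("AAA", "GGA", "GAG")))
  s <- network_summary(net)
  expect_equal(s$observed, 3L)
  expect_equal(s$median_vectors, 1L)
  expect_equal(s$edges, 3L)
  mv <- net$nodes[net$nodes$kind == "median_vector", ]
  expect_equal(mv$pattern, "GAA")   # per-site majority of the triplet
  expect_true(all(net$edges$weight == 1L))
  expect_true(all(mv$name %in% c(net$edges$from, net$edges$to)))
})

test_that("single haplotype yields the trivial one-node network", {
  net <- median_joining(toy_table(c("ACGT", "ACGT", "ACGT")))
  s <- network_summary(net)
  expect_equal(unlist(s[c("observed", "median_vectors", "edges")]),
               c(observed = 1L, median_vectors = 0L, edges = 0L))
  expect_equal(net$nodes$frequency, 3L)
})

test_that("the backbone equals the exhaustive union of minimum spanning trees", {
  set.seed(111)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    m <- do.call(rbind, strsplit(replicate(k, paste(
      sample(c("A", "G"), 8, replace = TRUE), collapse = "")), ""))
    if (anyDuplicated(apply(m, 1, paste, collapse = ""))) next
    d <- mitopop:::hamming_matrix(m)
    got <- mitopop:::msn_edges(d, 0)
    want <- mst_union_oracle(d)
    key <- function(e) sort(apply(t(apply(e, 1, sort)), 1, paste, collapse = "-"))
    expect_equal(key(got), key(want))
  }
})

test_that("tree-like (homoplasy-free) data reduce to the minimum spanning tree", {
  ## mutations on a known star genealogy at globally distinct sites
  pop <- make_population(8, length = 200, genealogy = "star",
                         mutations_per_tip = 1, seed = 112)
  ht <- collapse_haplotypes(pop$aln)
  net <- median_joining(ht)
  s <- network_summary(net)
  expect_equal(s$observed, 8L)
  ## the unobserved ancestor is inferred as the single hub median vector
  expect_equal(s$median_vectors, 1L)
  expect_equal(s$edges, 8L)
  mv <- net$nodes$name[net$nodes$kind == "median_vector"]
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[[mv]]), 8L)
})

test_that("duplicating an individual changes node size but never topology", {
  rows <- c("AAA", "GGA", "GAG", "AAA")
  net1 <- median_joining(toy_table(rows, paste0("s", 1:4)))
  net2 <- median_joining(toy_table(c(rows, "GGA"), paste0("s", 1:5)))
  expect_equal(edge_key(net1$edges), edge_key(net2$edges))
  f1 <- setNames(net1$nodes$frequency, net1$nodes$pattern)
  f2 <- setNames(net2$nodes$frequency, net2$nodes$pattern)
  expect_equal(unname(f2[names(f1)] - f1),
               ifelse(names(f1) == "GGA", 1L, 0L))
})

test_that("every observed haplotype keeps its frequency in the network", {
  set.seed(113)
  pop <- make_population(10, length = 300, theta = 0.02, seed = 113)
  ht <- collapse_haplotypes(pop$aln)
  net <- median_joining(ht)
  obs <- net$nodes[net$nodes$kind == "observed", ]
  expect_setequal(obs$name, ht$haplotypes$name)
  expect_equal(obs$frequency[match(ht$haplotypes$name, obs$name)],
               ht$haplotypes$count)
  expect_equal(sum(obs$frequency), ht$n)
})
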