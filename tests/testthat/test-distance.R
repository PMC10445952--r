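test_that("difference counting splits purine/pyrimidine transitions and transversions", {
  pd <- count_differences("AAAA", "GAAA")
  expect_equal(pd$P1, 0.25)
  expect_equal(pd$P2, 0)
  expect_equal(pd$Q, 0)
  z <- count_differences("ACGT", "ACGT")
  expect_equal(c(z$P1, z$P2, z$Q), c(0, 0, 0))
  ## missing characters shrink the comparable length
  pd2 <- count_differences("AC-T", "GCNT")
  expect_equal(pd2$L, 3L)
  expect_equal(pd2$P1, 1 / 3)
  expect_error(count_differences("--", "AA"), class = "mitopop_empty_input_error")
  set.seed(81)
  for (i in 1:20) {
    a <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
    b <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
    pd <- count_differences(paste(a, collapse = ""), paste(b, collapse = ""))
    ts <- sum(a != b & ((a %in% c("A", "G")) == (b %in% c("A", "G"))))
    tv <- sum(a != b) - ts
    expect_equal(pd$P1 + pd$P2, ts / 100, tolerance = 1e-15)
    expect_equal(pd$Q, tv / 100, tolerance = 1e-15)
  }
})

test_that("the two-parameter distance matches its closed form and saturates loudly", {
  expect_equal(k2p_distance(list(P = 0, Q = 0)), 0)
  expect_equal(k2p_distance(list(P = 0.1, Q = 0)), -0.5 * log(0.8))
  expect_equal(k2p_distance(list(P = 0.1, Q = 0)), 0.111572, tolerance = 1e-5)
  expect_equal(k2p_distance(list(P = 0, Q = 0.1)),
               -0.5 * log(0.9) - 0.25 * log(0.8))
  expect_error(k2p_distance(list(P = 0.5, Q = 0.2), pair = c("a", "b")),
               class = "mitopop_saturation_error")
  ## monotone in P at fixed Q and in Q at fixed P
  ps <- seq(0, 0.3, by = 0.05)
  dP <- vapply(ps, function(p) k2p_distance(list(P = p, Q = 0.05)), 0)
  expect_true(all(diff(dP) > 0))
  dQ <- vapply(ps, function(q) k2p_distance(list(P = 0.05, Q = q)), 0)
  expect_true(all(diff(dQ) > 0))
})

test_that("distance matrices are symmetric and agree with an independent implementation", {
  expect_equal(max(abs(distance_matrix(aln_set(rep("ACGTACGTAC", 3))))), 0)
  set.seed(82)
  pop <- make_population(8, length = 1500, theta = 0.03, seed = 82)
  d <- distance_matrix(pop$aln)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 8))
  ## element-wise recomputation through the pairwise primitives
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(d[i, j],
                 k2p_distance(count_differences(pop$aln$rows[i], pop$aln$rows[j])))
  }
  ## cross-check against ape's K80 distance
  db <- ape::as.DNAbin(strsplit(tolower(pop$aln$rows), ""))
  names(db) <- pop$aln$names
  ref <- as.matrix(ape::dist.dna(db, model = "K80"))
  expect_equal(unname(d), unname(ref[rownames(d), colnames(d)]), tolerance = 1e-9)
})

test_that("K2P estimates recover the true divergence on simulated pairs", {
  set.seed(83)
  L <- 800; t_true <- 0.05
  ests <- replicate(200, {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ## Jukes-Cantor evolution: each site substitutes with prob 3/4(1-e^{-4d/3})
    evolve <- function(s, d) {
      p <- 3 / 4 * (1 - exp(-4 * d / 3))
      hit <- runif(L) < p
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      s
    }
    a <- evolve(anc, t_true / 2); b <- evolve(anc, t_true / 2)
    k2p_distance(count_differences(paste(a, collapse = ""), paste(b, collapse = "")))
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - t_true), 3 * se + 1e-4)
})

test_that("printed substitution matrix obeys the frequency-scaled structure", {
  r <- read_rate_table(extdata("table6_rates.tsv"))
  expect_equal(sum(r, na.rm = TRUE), 100, tolerance = 0.1)
  tp <- transversion_proportionality(r, c(A = 30.26, T = 23.76, C = 32.48, G = 13.50))
  expect_lt(tp$relative_spread, 0.02)
})

test_that("the rate-matrix estimator recovers equal rates from frequency-driven data", {
  ## uniform frequencies with transition probability 1/3 make all three rate
  ## classes equal; the estimator should return k1 = k2 = b within 10%
  pop <- make_population(2, length = 10000, theta = 0.08, ts_tv_bias = 0.5,
                         base_freqs = c(A = 25, C = 25, G = 25, T = 25), seed = 91)
  rm <- tn93_rate_matrix(pop$aln)
  p <- rm$params
  expect_lt(abs(p[["k1"]] / p[["b"]] - 1), 0.10)
  expect_lt(abs(p[["k2"]] / p[["b"]] - 1), 0.10)
  expect_equal(sum(rm$r, na.rm = TRUE), 100, tolerance = 0.1)
  ## transversion entries proportional to target frequencies by construction
  tp <- transversion_proportionality(rm$r, rm$freqs)
  expect_lt(tp$relative_spread, 1e-9)
  ## structure is invariant to duplicating all rows
  dup <- aln_set(rep(pop$aln$rows, 2), paste0("s", 1:4))
  rm2 <- tn93_rate_matrix(dup)
  expect_equal(rm2$r, rm$r, tolerance = 1e-9)
  expect_error(tn93_rate_matrix(aln_set(rep("ACGT", 2))),
               class = "mitopop_estimation_error")
})
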