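## shared fixtures and independent oracles used across test files

extdata <- function(f) system.file("extdata", f, package = "mitopop")

random_aln <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  aln_set(replicate(n, paste(sample(alphabet, L, replace = TRUE), collapse = "")),
          paste0("t", seq_len(n)))
}

## brute-force mean pairwise difference proportion over all sequence pairs,
## computed character-wise with no haplotype collapsing
pi_bruteforce <- function(aln) {
  m <- as.matrix(aln)
  keep <- colSums(matrix(m %in% c("-", "N"), nrow = nrow(m))) == 0L
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(m[i, ] != m[j, ]); np <- np + 1L
  }
  tot / np
}

## exhaustive union of all minimum spanning trees on a small complete graph,
## by enumerating every labeled spanning tree through Prüfer sequences
mst_union_oracle <- function(d) {
  k <- nrow(d)
  stopifnot(k >= 2, k <= 6)
  if (k == 2) return(matrix(c(1, 2), 1, 2))
  prufer_to_edges <- function(p) {
    degree <- rep(1L, k); for (x in p) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, k - 1, 2)
    for (e in seq_along(p)) {
      leaf <- min(which(degree == 1L))
      edges[e, ] <- c(leaf, p[e])
      degree[leaf] <- 0L; degree[p[e]] <- degree[p[e]] - 1L
    }
    rest <- which(degree == 1L)
    edges[k - 1, ] <- rest
    edges
  }
  seqs <- expand.grid(rep(list(seq_len(k)), k - 2))
  best <- Inf; union_edges <- NULL
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_to_edges(as.integer(seqs[r, ]))
    w <- sum(d[ed])
    if (w < best - 1e-9) { best <- w; union_edges <- list(ed) }
    else if (abs(w - best) <= 1e-9) union_edges <- c(union_edges, list(ed))
  }
  keys <- unique(unlist(lapply(union_edges, function(ed)
    apply(t(apply(ed, 1, sort)), 1, paste, collapse = "-"))))
  do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
}

## random tree with safely separated branch lengths, and its exact
## leaf-to-leaf (additive) distance matrix
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE, br = function(n) runif(n, 0.05, 0.3))
  list(tree = tr, d = cophenetic(tr))
}

edge_key <- function(edges_df) {
  sort(apply(edges_df[, c("from", "to")], 1,
             function(r) paste(sort(r), collapse = "--")))
}
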