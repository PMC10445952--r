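#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` (with `R_i` the row sum over active
#' nodes), with branch lengths from the rate-corrected split formula. When
#' several pairs minimize `Q`, the lowest index pair in input order is taken.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch, preserving the joined pair's distance. The result
#' is exact on additive matrices.
#'
#' @param dm symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) mp_stop("need >= 3 taxa", class = "mitopop_size_error")
  if (any(!is.finite(dm))) mp_stop("non-finite distances", class = "mitopop_value_error")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  labels <- rownames(dm)
  ## each active node is represented by its (partial) newick string
  reps <- labels
  d <- dm
  while (length(reps) > 3L) {
    r <- length(reps)
    R <- rowSums(d)
    best <- NULL; bestq <- Inf
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * d[i, j] - R[i] - R[j]
      if (q < bestq) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newrep <- sprintf("(%s:%.12g,%s:%.12g)", reps[i], vi, reps[j], vj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    d <- d2
    reps <- c(reps[keep], newrep)
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", reps[1], v[1], reps[2], v[2],
                 reps[3], v[3])
  ape::read.tree(text = txt)
}

## internal bipartitions of an unrooted tree as canonical split keys; each
## split is identified by the sorted tip set on the side NOT containing
## `anchor`, so identical splits hash identically across trees
tree_splits <- function(tree, anchor = NULL) {
  tips <- tree$tip.label
  if (is.null(anchor)) anchor <- sort(tips)[1]
  n <- length(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tips[p])
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    if (length(side) <= 1L || length(side) >= n - 1L) next  # trivial split
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicates containing it. Replicates whose
#' resampled alignment produces a saturated pair are skipped and counted.
#'
#' @param aln an [aln_set].
#' @param model distance model passed to [distance_matrix].
#' @param reps number of bootstrap replicates (default 1000); `reps = 0`
#'   returns the full-data tree without supports.
#' @param seed optional integer seed.
#' @param gap_policy as in [distance_matrix].
#' @return List of class `nj_bootstrap`: `tree` (the full-data tree with
#'   integer percentage supports in `node.label`, root empty), `supports`
#'   (named vector keyed by split), `reps`, `n_skipped`.
#' @export
bootstrap_support <- function(aln, model = "k2p", reps = 1000L, seed = NULL,
                              gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  full <- nj_tree(distance_matrix(aln, model, gap_policy))
  if (reps == 0L)
    return(structure(list(tree = full, supports = NULL, reps = 0L, n_skipped = 0L),
                     class = "nj_bootstrap"))
  if (!is.null(seed)) set.seed(seed)
  anchor <- sort(aln$names)[1]
  target <- tree_splits(full, anchor)
  count <- stats::setNames(rep(0L, length(target)), target)
  m <- as.matrix(aln)
  skipped <- 0L
  for (b in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    baln <- aln_set(rows_to_strings(m[, cols, drop = FALSE]), aln$names)
    bt <- tryCatch(nj_tree(distance_matrix(baln, model, gap_policy)),
                   mitopop_saturation_error = function(e) NULL,
                   mitopop_degenerate_alignment_error = function(e) NULL)
    if (is.null(bt)) { skipped <- skipped + 1L; next }
    hits <- intersect(target, tree_splits(bt, anchor))
    count[hits] <- count[hits] + 1L
  }
  done <- reps - skipped
  supports <- if (done > 0) round(100 * count / done) else count * NA_real_
  ## attach supports as node labels on the full tree
  tips <- full$tip.label
  lab <- character(full$Nnode)
  parts <- ape::prop.part(full)
  for (k in seq_along(parts)) {
    side <- sort(tips[parts[[k]]])
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    lab[k] <- if (key %in% names(supports)) as.character(supports[[key]]) else ""
  }
  full$node.label <- lab
  structure(list(tree = full, supports = supports, reps = as.integer(reps),
                 n_skipped = skipped),
            class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat(sprintf("NJ tree, %d tips; %d bootstrap replicates (%d skipped)\n",
              length(x$tree$tip.label), x$reps, x$n_skipped))
  invisible(x)
}
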