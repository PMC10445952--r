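## Nei diversity statistics and haplotype-frequency differentiation.

## proportion of differing sites between two patterns, over columns where
## both carry an unambiguous base
pair_prop_diff <- function(p1, p2) {
  a <- seq_to_chars(p1); b <- seq_to_chars(p2)
  ok <- !(a %in% MISSING_CHARS | b %in% MISSING_CHARS)
  if (!any(ok))
    mp_stop("no comparable columns between sequence pair",
            class = "mitopop_empty_input_error")
  sum(a[ok] != b[ok]) / sum(ok)
}

as_hap_table <- function(x) {
  if (inherits(x, "haplotype_table")) return(x)
  if (inherits(x, "aln_set")) return(collapse_haplotypes(x))
  mp_stop("expected an aln_set or haplotype_table", class = "mitopop_value_error")
}

#' Nucleotide diversity (Nei's pi)
#'
#' The average per-site proportion of differences between two randomly drawn
#' sequences, with the small-sample correction:
#' `pi = n/(n-1) * sum_{i<j} 2 x_i x_j pi_ij`, where `x_i` are haplotype
#' frequencies and `pi_ij` the per-site difference proportion between types
#' `i` and `j`. Equivalently, the mean pairwise difference over all
#' `n(n-1)/2` sequence pairs.
#'
#' @param x an [aln_set] or `haplotype_table` (the gap policy used at
#'   collapse time determines the analyzed columns).
#' @return Nucleotide diversity per site (scalar in `[0, 1]`).
#' @export
nucleotide_diversity <- function(x) {
  tab <- as_hap_table(x)
  n <- tab$n
  if (n < 2L) mp_stop("need n >= 2 sequences", class = "mitopop_sample_size_error")
  pats <- tab$haplotypes$pattern
  k <- length(pats)
  if (k == 1L) return(0)
  acc <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    acc <- acc + 2 * tab$x[i] * tab$x[j] * pair_prop_diff(pats[i], pats[j])
  }
  n / (n - 1) * acc
}

#' Haplotype diversity (Nei's h)
#'
#' `h = 2n (1 - sum x_i^2) / (2n - 1)` with `x_i` the haplotype frequencies
#' and `n` the sample size.
#'
#' @param x an [aln_set], `haplotype_table`, or a numeric vector of haplotype
#'   frequencies (then `n` must be given).
#' @param n sample size; only needed when `x` is a bare frequency vector.
#' @return Haplotype diversity in `[0, 1)`.
#' @examples
#' haplotype_diversity(c(0.5, 0.5), n = 4)  # 4/7
#' @export
haplotype_diversity <- function(x, n = NULL) {
  if (is.numeric(x)) {
    if (is.null(n)) mp_stop("n is required with a frequency vector",
                            class = "mitopop_value_error")
    freqs <- x
  } else {
    tab <- as_hap_table(x)
    freqs <- tab$x; n <- tab$n
  }
  if (n < 2L) mp_stop("need n >= 2 sequences", class = "mitopop_sample_size_error")
  if (abs(sum(freqs) - 1) > 1e-9)
    mp_stop("haplotype frequencies must sum to 1", class = "mitopop_value_error")
  2 * n * (1 - sum(freqs^2)) / (2 * n - 1)
}

#' Summary diversity statistics
#'
#' @param x an [aln_set] or `haplotype_table`.
#' @return List of class `diversity_stats`: `S` segregating sites, `H`
#'   haplotype count, `Hd` haplotype diversity, `pi` nucleotide diversity,
#'   `n` sample size and `nc = n(n-1)/2` sequence comparisons.
#' @export
diversity_stats <- function(x) {
  tab <- as_hap_table(x)
  structure(list(S = tab$S, H = nrow(tab$haplotypes),
                 Hd = haplotype_diversity(tab), pi = nucleotide_diversity(tab),
                 n = tab$n, nc = tab$n * (tab$n - 1) / 2),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("n = %d  S = %d  H = %d  Hd = %.6f  pi = %.6f\n",
              x$n, x$S, x$H, x$Hd, x$pi))
  invisible(x)
}

hap_counts <- function(x) {
  if (inherits(x, "haplotype_table"))
    return(stats::setNames(x$haplotypes$count, x$haplotypes$pattern))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  mp_stop("population must be a haplotype_table or named count vector",
          class = "mitopop_value_error")
}

gst_stat <- function(cA, cB) {
  labels <- union(names(cA), names(cB))
  xA <- stats::setNames(rep(0, length(labels)), labels); xA[names(cA)] <- cA / sum(cA)
  xB <- stats::setNames(rep(0, length(labels)), labels); xB[names(cB)] <- cB / sum(cB)
  xbar <- (xA + xB) / 2
  Ht <- 1 - sum(xbar^2)
  Hs <- mean(c(1 - sum(xA^2), 1 - sum(xB^2)))
  if (Ht <= 0) return(list(stat = 0, Ht = 0, Hs = Hs))
  list(stat = (Ht - Hs) / Ht, Ht = Ht, Hs = Hs)
}

#' Haplotype-frequency differentiation between two populations
#'
#' A Gst-style fixation measure on haplotype frequencies:
#' `(Ht - Hs) / Ht`, with `Ht` the gene diversity of the pooled (unweighted
#' mean) frequencies and `Hs` the mean within-population gene diversity.
#' Significance is assessed by randomly reassigning individuals to the two
#' populations (sizes preserved); the p-value uses the `(b + 1)/(m + 1)`
#' convention. This exercises haplotype-frequency population structure; it
#' does not claim equivalence to sequence-distance-weighted Fst/Nst
#' estimators.
#'
#' @param a,b the two populations: `haplotype_table`s (haplotypes matched by
#'   pattern) or named count vectors over a shared label space.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the permutation draw.
#' @return List of class `differentiation_result`: `statistic` in `[0, 1]`,
#'   `p_value`, `n_perm`, `Ht`, `Hs`.
#' @export
differentiation <- function(a, b, n_perm = 1000L, seed = NULL) {
  cA <- hap_counts(a); cB <- hap_counts(b)
  nA <- sum(cA); nB <- sum(cB)
  if (nA < 2L || nB < 2L)
    mp_stop("each population needs n >= 2", class = "mitopop_sample_size_error")
  obs <- gst_stat(cA, cB)
  if (obs$Ht == 0)
    return(structure(list(statistic = 0, p_value = 1, n_perm = 0L,
                          Ht = 0, Hs = obs$Hs), class = "differentiation_result"))
  if (!is.null(seed)) set.seed(seed)
  pool <- c(rep(names(cA), cA), rep(names(cB), cB))
  b_ge <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(pool)
    pA <- table(perm[seq_len(nA)]); pB <- table(perm[(nA + 1L):(nA + nB)])
    if (gst_stat(c(pA), c(pB))$stat >= obs$stat - 1e-12) b_ge <- b_ge + 1L
  }
  structure(list(statistic = obs$stat, p_value = (b_ge + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), Ht = obs$Ht, Hs = obs$Hs),
            class = "differentiation_result")
}
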