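#' Pairwise difference proportions
#'
#' Counts transition and transversion differences between two aligned
#' sequences over the columns where both carry an unambiguous base.
#' Purine transitions (`A` vs `G`) and pyrimidine transitions (`C` vs `T`)
#' are kept separate so the same counts feed both the two-parameter distance
#' (`P = P1 + P2`) and the three-rate model.
#'
#' @param seqA,seqB aligned sequences (equal-length strings).
#' @return List of class `pairwise_difference`: `P1` purine-transition
#'   proportion, `P2` pyrimidine-transition proportion, `Q` transversion
#'   proportion, `L` compared sites.
#' @export
count_differences <- function(seqA, seqB) {
  a <- seq_to_chars(seqA); b <- seq_to_chars(seqB)
  if (length(a) != length(b))
    mp_stop("sequences differ in length", class = "mitopop_shape_error")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  L <- sum(ok)
  if (L == 0L)
    mp_stop("no comparable columns", class = "mitopop_empty_input_error")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  p1 <- sum(diff & a %in% PURINES & b %in% PURINES)
  p2 <- sum(diff & a %in% PYRIMIDINES & b %in% PYRIMIDINES)
  q <- sum(diff) - p1 - p2
  structure(list(P1 = p1 / L, P2 = p2 / L, Q = q / L, L = L),
            class = "pairwise_difference")
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion difference proportion. Saturated pairs (either log
#' argument non-positive) abort with an error naming the pair rather than
#' returning a capped value.
#'
#' @param pd a `pairwise_difference` from [count_differences], or a list
#'   with elements `P1`, `P2` (or a single `P`) and `Q`.
#' @param pair optional character(2) naming the pair for error messages.
#' @return The K2P distance (substitutions per site).
#' @examples
#' k2p_distance(list(P = 0.1, Q = 0))  # -0.5 * log(0.8)
#' @export
k2p_distance <- function(pd, pair = NULL) {
  P <- if (!is.null(pd$P)) pd$P else pd$P1 + pd$P2
  Q <- pd$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    mp_stop("saturated pair",
            if (!is.null(pair)) paste0(" (", pair[1], ", ", pair[2], ")") else "",
            ": P = ", signif(P, 4), ", Q = ", signif(Q, 4),
            class = "mitopop_saturation_error")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise distance matrix
#'
#' @param aln an [aln_set] of at least 3 sequences.
#' @param model distance model; only `"k2p"` is implemented.
#' @param gap_policy `"complete"` removes columns with missing data in any
#'   row before comparing; `"pairwise"` drops missing columns per pair.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
distance_matrix <- function(aln, model = "k2p",
                            gap_policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "aln_set"))
  model <- match.arg(model, "k2p")
  gap_policy <- match.arg(gap_policy)
  rows <- aln$rows
  if (gap_policy == "complete") {
    m <- as.matrix(aln)
    keep <- which(colSums(matrix(m %in% MISSING_CHARS, nrow = nrow(m))) == 0L)
    if (length(keep) == 0L)
      mp_stop("no columns left after complete deletion",
              class = "mitopop_degenerate_alignment_error")
    rows <- rows_to_strings(m[, keep, drop = FALSE])
  }
  k <- length(rows)
  d <- matrix(0, k, k, dimnames = list(aln$names, aln$names))
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d[i, j] <- d[j, i] <- k2p_distance(count_differences(rows[i], rows[j]),
                                       pair = c(aln$names[i], aln$names[j]))
  }
  d
}

#' Tamura-Nei (TN93) instantaneous rate matrix
#'
#' Estimates the three rate classes of the Tamura-Nei model — purine
#' transitions, pyrimidine transitions and transversions, each proportional
#' to the target base frequency — by method of moments on pairwise
#' difference proportions pooled over distinct sequences (so duplicated rows
#' carry no extra weight): the pooled `P1`, `P2`, `Q` are converted to
#' per-class expected substitution counts with the TN93 log corrections, and
#' divided by their frequency weights to give relative rate factors. Base
#' frequencies are estimated from all analyzed columns pooled over
#' sequences. The 12 off-diagonal entries `r(x -> j)` are rescaled to sum to
#' 100. This moment estimator recovers the model structure without a
#' tree-based maximum-likelihood fit.
#'
#' @param aln an [aln_set] with at least 2 sequences.
#' @param gap_policy as in [distance_matrix].
#' @return List of class `rate_matrix`: `r` (4x4 matrix, rows = source base,
#'   columns = target base, in A, T, C, G order, diagonal `NA`), `freqs`
#'   (base frequencies in percent, same order), `params` (relative `k1`,
#'   `k2`, `b` factors), `normalization` (the rescaling constant applied).
#' @export
tn93_rate_matrix <- function(aln, gap_policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "aln_set"))
  gap_policy <- match.arg(gap_policy)
  if (length(aln$rows) < 2L)
    mp_stop("need >= 2 sequences", class = "mitopop_sample_size_error")
  rows <- aln$rows
  if (gap_policy == "complete") {
    m <- as.matrix(aln)
    keep <- which(colSums(matrix(m %in% MISSING_CHARS, nrow = nrow(m))) == 0L)
    if (length(keep) == 0L)
      mp_stop("no columns left after complete deletion",
              class = "mitopop_degenerate_alignment_error")
    rows <- rows_to_strings(m[, keep, drop = FALSE])
  }
  rows <- unique(rows)   # pool over distinct sequences: duplicated rows carry
  if (length(rows) < 2L) # no extra substitution information
    mp_stop("no substitutions observed; cannot estimate rates",
            class = "mitopop_estimation_error")
  comp <- base_composition(rows)
  pf <- comp$percent / 100                      # named A, C, G, T
  if (any(pf == 0))
    mp_stop("base class absent from data (",
            paste(DNA_BASES[pf == 0], collapse = ", "),
            "); cannot estimate rates", class = "mitopop_estimation_error")
  pA <- pf[["A"]]; pC <- pf[["C"]]; pG <- pf[["G"]]; pT <- pf[["T"]]
  pR <- pA + pG; pY <- pC + pT
  k <- length(rows)
  P1 <- P2 <- Q <- 0; npair <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pd <- count_differences(rows[i], rows[j])
    P1 <- P1 + pd$P1; P2 <- P2 + pd$P2; Q <- Q + pd$Q; npair <- npair + 1L
  }
  P1 <- P1 / npair; P2 <- P2 / npair; Q <- Q / npair
  if (P1 + P2 + Q == 0)
    mp_stop("no substitutions observed; cannot estimate rates",
            class = "mitopop_estimation_error")
  w1 <- 1 - pR * P1 / (2 * pA * pG) - Q / (2 * pR)
  w2 <- 1 - pY * P2 / (2 * pC * pT) - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    mp_stop("saturated pooled proportions; cannot invert the model",
            class = "mitopop_saturation_error")
  ## expected substitutions per site by class; each carries the same shared
  ## time factor, which cancels in the normalized relative rates
  s1 <- -(2 * pA * pG / pR) * (log(w1) - pY * log(w3))
  s2 <- -(2 * pC * pT / pY) * (log(w2) - pR * log(w3))
  sv <- -2 * pR * pY * log(w3)
  k1 <- s1 / (2 * pA * pG)
  k2 <- s2 / (2 * pC * pT)
  b <- sv / (2 * pR * pY)
  if (k1 < 0 || k2 < 0 || b < 0)
    mp_stop("negative rate estimate; data inconsistent with the model",
            class = "mitopop_estimation_error")
  bases <- c("A", "T", "C", "G")
  pvec <- c(A = pA, T = pT, C = pC, G = pG)
  r <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
  for (x in bases) for (j in bases) {
    if (x == j) next
    fac <- if (all(c(x, j) %in% PURINES)) k1
           else if (all(c(x, j) %in% PYRIMIDINES)) k2
           else b
    r[x, j] <- fac * pvec[[j]]
  }
  norm <- 100 / sum(r, na.rm = TRUE)
  structure(list(r = r * norm, freqs = pvec * 100,
                 params = c(k1 = k1, k2 = k2, b = b), normalization = norm),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("TN93 instantaneous rate matrix (off-diagonal sum = 100):\n")
  print(round(x$r, 2))
  invisible(x)
}

#' Read a printed substitution-rate table
#'
#' Parses a TSV with a `base` column and columns `A`, `T`, `C`, `G` holding
#' the off-diagonal instantaneous rates (diagonal empty or `NA`).
#'
#' @param path path to the TSV file.
#' @return 4x4 numeric matrix (rows = source base), diagonal `NA`.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
  names(df) <- sub("^t.u$", "T", tolower(names(df)))
  names(df)[1] <- "base"
  names(df)[-1] <- toupper(names(df)[-1])
  m <- as.matrix(df[, c("A", "T", "C", "G")])
  rownames(m) <- toupper(df$base)
  m[c("A", "T", "C", "G"), ]
}

#' Transversion entries vs target base frequencies
#'
#' Under the Tamura-Nei structure every transversion rate equals a single
#' factor times the target base frequency, so the ratios
#' `r(x -> j) / freq_j` must agree across all eight transversion cells. The
#' relative spread `(max - min)/mean` of those ratios measures how well a
#' printed matrix obeys the structure.
#'
#' @param r 4x4 rate matrix (A, T, C, G order).
#' @param freqs named base frequencies (percent or proportions).
#' @return List with `ratios` (eight named values) and `relative_spread`.
#' @export
transversion_proportionality <- function(r, freqs) {
  bases <- c("A", "T", "C", "G")
  ratios <- c()
  for (x in bases) for (j in bases) {
    if (x == j || is_transition_pair(x, j)) next
    ratios[paste0(x, "->", j)] <- r[x, j] / freqs[[j]]
  }
  list(ratios = ratios,
       relative_spread = (max(ratios) - min(ratios)) / mean(ratios))
}
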