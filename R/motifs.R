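#' Find all occurrences of a motif
#'
#' Overlapping occurrences are counted; positions are 1-based and ascending.
#' Standard control-region motifs this is used for include the invariant
#' tetradecamer `AACTATGAATGGTT`, the termination-associated `TACAT` /
#' `TATAT` elements and the interrupted thymine string.
#'
#' @param seq sequence (single string).
#' @param motif literal pattern over `A, C, G, T`.
#' @return Data frame with columns `motif`, `position`, `length`
#'   (zero rows when absent).
#' @examples
#' find_motif("TATATATAT", "TATAT")$position  # 1 3 5
#' @export
find_motif <- function(seq, motif) {
  motif <- toupper(motif); seq <- toupper(seq)
  if (!nzchar(motif)) mp_stop("empty motif", class = "mitopop_value_error")
  if (grepl("[^ACGT]", motif))
    mp_stop("motif must be over A,C,G,T", class = "mitopop_value_error")
  if (nchar(motif) > nchar(seq))
    mp_stop("motif longer than sequence", class = "mitopop_value_error")
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  pos <- as.integer(hits[hits > 0])
  data.frame(motif = rep(motif, length(pos)), position = pos,
             length = rep(nchar(motif), length(pos)), stringsAsFactors = FALSE)
}

#' Find maximal homopolymer runs
#'
#' Reports maximal runs of `base` of length at least `min_len` (e.g. the
#' conserved poly-C and poly-G stretches of the avian control region).
#'
#' @param seq sequence (single string).
#' @param base single base `A`, `C`, `G` or `T`.
#' @param min_len minimum run length, `>= 2`.
#' @return Data frame with columns `motif` (the run), `position`, `length`.
#' @export
find_homopolymer_runs <- function(seq, base, min_len = 5L) {
  base <- toupper(base)
  stopifnot(base %in% DNA_BASES)
  if (min_len < 2L) mp_stop("min_len must be >= 2", class = "mitopop_value_error")
  ch <- seq_to_chars(seq)
  r <- rle(ch == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(motif = vapply(which(keep), function(i) strrep(base, r$lengths[i]), ""),
             position = starts[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Test whether an alignment block is fully conserved
#'
#' A column is conserved when it carries a single non-missing state across
#' all rows (`-` and `N` are missing).
#'
#' @param aln an [aln_set].
#' @param from_col,to_col 1-based inclusive column range.
#' @return List with `conserved` (logical) and `violating_columns`
#'   (1-based positions of variable columns inside the range).
#' @export
conserved_block <- function(aln, from_col, to_col) {
  stopifnot(inherits(aln, "aln_set"))
  if (from_col < 1L || to_col > aln$length || from_col > to_col)
    mp_stop("column range ", from_col, "-", to_col, " invalid for alignment of ",
            aln$length, " columns", class = "mitopop_coordinate_error")
  m <- as.matrix(aln)[, from_col:to_col, drop = FALSE]
  viol <- which(apply(m, 2L, function(col) {
    states <- unique(col[!col %in% MISSING_CHARS])
    length(states) > 1L
  }))
  list(conserved = length(viol) == 0L,
       violating_columns = as.integer(from_col - 1L + viol))
}
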