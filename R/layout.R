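#' Genome layout container
#'
#' Bundles an ordered feature table with the length of the circular molecule.
#' Features must be sorted by start; the genome must be at least as long as
#' the last feature end.
#'
#' @param features a `feature_table` (see [read_feature_table]).
#' @param genome_length length in bp of the circular molecule.
#' @param circular logical; mitogenomes are circular.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(features, genome_length, circular = TRUE) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L)
  if (is.unsorted(features$start))
    mp_stop("features must be sorted by start coordinate",
            class = "mitopop_ordering_error")
  if (genome_length < max(features$end))
    mp_stop("genome_length (", genome_length, ") < max feature end (",
            max(features$end), ")", class = "mitopop_coordinate_error")
  structure(list(features = features, genome_length = as.integer(genome_length),
                 circular = isTRUE(circular)),
            class = "genome_layout")
}

#' Feature length from 1-based inclusive coordinates
#'
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @return Length(s) in bp, `end - start + 1`.
#' @examples
#' feature_length(13071, 14888)  # 1818, the longest protein-coding gene
#' @export
feature_length <- function(start, end) {
  if (any(end < start)) mp_stop("end < start", class = "mitopop_coordinate_error")
  as.integer(end - start + 1L)
}

#' Inter-feature spacing and overlap report
#'
#' For consecutive features the signed gap is
#' `delta = start(next) - end(prev)`: positive deltas are intergenic spacers,
#' deltas `<= 0` are overlaps (a shared boundary, delta 0, counts as an
#' overlap). The true number of shared bases, `end(prev) - start(next) + 1`,
#' is reported alongside for overlapping pairs since published tables mix the
#' two conventions.
#'
#' @param layout a [genome_layout] (or bare `feature_table`) with >= 2 features.
#' @return List of class `adjacency_report`: `pairs` (data frame with
#'   `prev_name`, `next_name`, `delta`, `shared_bases`, `class`), `n_spacers`,
#'   `n_overlaps`, `spacer_range`, `overlap_range`.
#' @export
adjacency_deltas <- function(layout) {
  feats <- if (inherits(layout, "genome_layout")) layout$features else layout
  if (nrow(feats) < 2L)
    mp_stop("need >= 2 features for adjacency", class = "mitopop_shape_error")
  if (is.unsorted(feats$start))
    mp_stop("features must be sorted by start", class = "mitopop_ordering_error")
  i <- seq_len(nrow(feats) - 1L)
  delta <- feats$start[i + 1L] - feats$end[i]
  shared <- ifelse(delta <= 0L, feats$end[i] - feats$start[i + 1L] + 1L, 0L)
  cls <- ifelse(delta > 0L, "spacer", "overlap")
  pairs <- data.frame(prev_name = feats$name[i], next_name = feats$name[i + 1L],
                      delta = as.integer(delta), shared_bases = as.integer(shared),
                      class = cls, stringsAsFactors = FALSE)
  sp <- pairs$delta[pairs$class == "spacer"]
  ov <- pairs$delta[pairs$class == "overlap"]
  structure(list(pairs = pairs,
                 n_spacers = sum(pairs$class == "spacer"),
                 n_overlaps = sum(pairs$class == "overlap"),
                 spacer_range = if (length(sp)) range(sp) else c(NA_integer_, NA_integer_),
                 overlap_range = if (length(ov)) range(ov) else c(NA_integer_, NA_integer_)),
            class = "adjacency_report")
}

#' @export
print.adjacency_report <- function(x, ...) {
  cat(sprintf("adjacency report: %d spacers (%s-%s bp), %d overlaps\n",
              x$n_spacers, x$spacer_range[1], x$spacer_range[2], x$n_overlaps))
  invisible(x)
}

#' Audit printed feature sizes against coordinates
#'
#' Published organization tables sometimes print a size that contradicts the
#' printed coordinates. This quality gate recomputes `end - start + 1` and
#' lists every feature whose `printed_size` disagrees. Nothing is corrected.
#'
#' @param layout a [genome_layout] or `feature_table` carrying a
#'   `printed_size` column.
#' @return Data frame with `name`, `printed_size`, `computed_size` — one row
#'   per discrepancy; zero rows when consistent or when no sizes are printed.
#' @export
audit_printed_sizes <- function(layout) {
  feats <- if (inherits(layout, "genome_layout")) layout$features else layout
  empty <- data.frame(name = character(), printed_size = integer(),
                      computed_size = integer(), stringsAsFactors = FALSE)
  if (!"printed_size" %in% names(feats)) return(empty)
  computed <- feature_length(feats$start, feats$end)
  keep <- !is.na(feats$printed_size) & feats$printed_size != computed
  if (!any(keep)) return(empty)
  data.frame(name = feats$name[keep], printed_size = feats$printed_size[keep],
             computed_size = computed[keep], stringsAsFactors = FALSE)
}

#' Extract start and stop codons of a feature
#'
#' Light-strand (`L`) features are read on the reverse complement. The stop
#' codon honours incomplete termination: for feature lengths `3k + 1` the
#' final base is reported padded as e.g. `"T--"` (completed to a true stop by
#' post-transcriptional polyadenylation), for `3k + 2` the final two bases are
#' padded with one `-`.
#'
#' @param genome genome sequence (single string).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"H"` or `"L"`.
#' @return list with `start_codon` and `stop_codon`.
#' @export
extract_codons <- function(genome, start, end, strand = "H") {
  genome <- toupper(genome)
  if (end > nchar(genome) || start < 1L)
    mp_stop("feature ", start, "-", end, " exceeds genome of length ",
            nchar(genome), class = "mitopop_coordinate_error")
  s <- substr(genome, start, end)
  if (strand == "L") s <- revcomp(s)
  n <- nchar(s)
  start_codon <- substr(s, 1L, min(3L, n))
  rem <- n %% 3L
  stop_codon <- switch(as.character(rem),
    "0" = substr(s, n - 2L, n),
    "1" = paste0(substr(s, n, n), "--"),
    "2" = paste0(substr(s, n - 1L, n), "-"))
  list(start_codon = start_codon, stop_codon = stop_codon)
}

#' Base composition of one or more sequences
#'
#' Counts are pooled over all sequences; gap (`-`) and `N` characters are
#' ignored, case-insensitively.
#'
#' @param seqs character vector of sequences, or an [aln_set].
#' @return List with `percent` (named A, C, G, T percentages summing to 100),
#'   `at` and `gc` aggregate percentages, and `n_bases` counted.
#' @export
base_composition <- function(seqs) {
  if (inherits(seqs, "aln_set")) seqs <- seqs$rows
  ch <- unlist(strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE))
  ch <- ch[ch %in% DNA_BASES]
  if (length(ch) == 0L)
    mp_stop("no unambiguous bases to count", class = "mitopop_empty_input_error")
  counts <- vapply(DNA_BASES, function(b) sum(ch == b), 0L)
  pct <- 100 * counts / sum(counts)
  list(percent = pct, at = unname(pct["A"] + pct["T"]),
       gc = unname(pct["G"] + pct["C"]), n_bases = length(ch))
}
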