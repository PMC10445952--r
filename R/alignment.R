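#' Aligned sequence sets
#'
#' An `aln_set` is the container every analysis stage consumes: an ordered,
#' named collection of equal-length nucleotide rows over the alphabet
#' `A, C, G, T, -, N`. `-` and `N` are both treated as missing downstream
#' (complete-deletion handling excludes columns carrying either).
#'
#' @param rows character vector of aligned sequences (one string per taxon).
#' @param names unique identifiers, one per row.
#' @return An object of class `aln_set` with elements `names`, `rows`
#'   (upper-cased strings) and `length` (number of alignment columns).
#' @examples
#' a <- aln_set(c("ACGT", "ACGA"), c("s1", "s2"))
#' a$length
#' @export
aln_set <- function(rows, names = NULL) {
  if (is.null(names)) names <- paste0("seq", seq_along(rows))
  if (length(rows) == 0L)
    mp_stop("alignment must contain at least one record", class = "mitopop_shape_error")
  if (length(names) != length(rows))
    mp_stop("names and rows differ in length", class = "mitopop_shape_error")
  if (anyDuplicated(names))
    mp_stop("duplicate sequence identifiers: ",
            paste(unique(names[duplicated(names)]), collapse = ", "),
            class = "mitopop_identifier_error")
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    mp_stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
            class = "mitopop_shape_error")
  if (widths[1] < 1L)
    mp_stop("alignment length must be >= 1", class = "mitopop_shape_error")
  bad <- grepl(sprintf("[^%s]", paste(c(DNA_BASES, "N", "\\-"), collapse = "")), rows)
  if (any(bad))
    mp_stop("non-{A,C,G,T,-,N} characters in rows: ",
            paste(names[bad], collapse = ", "), class = "mitopop_alphabet_error")
  structure(list(names = as.character(names), rows = unname(rows),
                 length = unname(widths[1])),
            class = "aln_set")
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf("aln_set: %d sequences x %d columns\n", length(x$names), x$length))
  invisible(x)
}

#' @export
as.matrix.aln_set <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$names
  m
}

#' @rdname aln_set
#' @param m character matrix (rows = taxa) to rebuild a set from.
#' @export
aln_from_matrix <- function(m) {
  aln_set(rows_to_strings(m), rownames(m))
}

#' Read an aligned multi-FASTA file
#'
#' Input order is preserved; ragged alignments, duplicated identifiers and
#' characters outside `A, C, G, T, -, N` are rejected.
#'
#' @param path path to an aligned FASTA file.
#' @return An [aln_set].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) mp_stop("no such file: ", path, class = "mitopop_io_error")
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) mp_stop("no FASTA records in ", path, class = "mitopop_io_error")
  aln_set(as.character(ss), names = sub("\\s.*$", "", names(ss)))
}

#' Write an aligned set as multi-FASTA
#'
#' @param aln an [aln_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aln_set"))
  ss <- Biostrings::BStringSet(stats::setNames(aln$rows, aln$names))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
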