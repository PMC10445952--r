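#' Collapse an alignment into haplotypes
#'
#' Columns containing a gap (`-`) or `N` in any row are removed first
#' (complete deletion — alignment gaps arising from deletion events are
#' excluded from all calculations), then identical remaining rows are merged.
#' Haplotypes are named `H1..Hk` in order of first occurrence. An optional
#' reference row is held out as `H-ref`: it participates in column filtering
#' but is not counted in `n` nor in the segregating sites.
#'
#' @param aln an [aln_set].
#' @param gap_policy `"complete"` (default) drops any column with missing
#'   data in any row; `"pairwise"` retains all columns (missing characters
#'   then remain inside patterns and are handled pairwise downstream).
#' @param reference optional name of the reference row.
#' @return List of class `haplotype_table`: `haplotypes` (data frame with
#'   `name`, `pattern`, `count` and a `members` list-column), `n`, `x`
#'   (frequencies `count / n`), `S`, `sites` (original 1-based positions of
#'   segregating columns), `retained_columns`, `reference_pattern` (or
#'   `NULL`) and `gap_policy`.
#' @export
collapse_haplotypes <- function(aln, gap_policy = c("complete", "pairwise"),
                                reference = NULL) {
  stopifnot(inherits(aln, "aln_set"))
  gap_policy <- match.arg(gap_policy)
  m <- as.matrix(aln)
  if (gap_policy == "complete") {
    keep <- which(colSums(matrix(m %in% MISSING_CHARS, nrow = nrow(m))) == 0L)
  } else {
    keep <- seq_len(ncol(m))
  }
  if (length(keep) == 0L)
    mp_stop("no columns left after complete deletion",
            class = "mitopop_degenerate_alignment_error")
  m <- m[, keep, drop = FALSE]
  ref_pattern <- NULL
  if (!is.null(reference)) {
    ri <- match(reference, aln$names)
    if (is.na(ri)) mp_stop("reference row '", reference, "' not in alignment",
                           class = "mitopop_identifier_error")
    ref_pattern <- paste(m[ri, ], collapse = "")
    m <- m[-ri, , drop = FALSE]
  }
  if (nrow(m) == 0L)
    mp_stop("no sample rows left after removing the reference",
            class = "mitopop_shape_error")
  pats <- rows_to_strings(m)
  first <- !duplicated(pats)
  uniq <- pats[first]
  idx <- match(pats, uniq)
  members <- split(rownames(m), idx)
  counts <- as.integer(table(idx))
  ## segregating sites among sample rows (missing states do not segregate)
  var_cols <- which(apply(m, 2L, function(col) {
    length(unique(col[!col %in% MISSING_CHARS])) > 1L
  }))
  haps <- data.frame(name = paste0("H", seq_along(uniq)), pattern = uniq,
                     count = counts, stringsAsFactors = FALSE)
  haps$members <- unname(members)
  structure(list(haplotypes = haps, n = nrow(m), x = counts / nrow(m),
                 S = length(var_cols), sites = as.integer(keep[var_cols]),
                 retained_columns = as.integer(keep),
                 reference_pattern = ref_pattern, gap_policy = gap_policy),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype table: n = %d, H = %d, S = %d (over %d analyzed columns)\n",
              x$n, nrow(x$haplotypes), x$S, length(x$retained_columns)))
  invisible(x)
}

#' Classify substitutions relative to a reference pattern
#'
#' Each segregating position contributes one unordered base pair per distinct
#' alternate state: `A/G` and `C/T` pairs are transitions, the four remaining
#' pairs transversions. Positions with more than one alternate are counted
#' once per alternate and flagged as triallelic.
#'
#' @param table a `haplotype_table`.
#' @param reference reference pattern over the analyzed columns; defaults to
#'   the table's held-out reference, falling back to the first haplotype.
#' @return List of class `substitution_spectrum`: `counts` (named vector over
#'   `A/G`, `C/T`, `A/C`, `A/T`, `C/G`, `G/T`), `transitions`,
#'   `transversions`, `total`, `multiallelic_sites`.
#' @export
substitution_spectrum <- function(table, reference = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(reference)) reference <- table$reference_pattern
  if (is.null(reference)) reference <- table$haplotypes$pattern[1]
  pats <- table$haplotypes$pattern
  if (any(nchar(pats) != nchar(reference)))
    mp_stop("reference pattern length differs from haplotype patterns",
            class = "mitopop_shape_error")
  ref <- seq_to_chars(reference)
  pm <- do.call(rbind, strsplit(pats, "", fixed = TRUE))
  classes <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  counts <- stats::setNames(integer(6), classes)
  multi <- integer(0)
  for (j in seq_along(ref)) {
    states <- unique(pm[, j])
    states <- states[!states %in% MISSING_CHARS]
    alts <- setdiff(states, ref[j])
    if (length(alts) == 0L || ref[j] %in% MISSING_CHARS) next
    if (length(alts) > 1L) multi <- c(multi, j)
    for (a in alts) {
      pair <- paste(sort(c(ref[j], a)), collapse = "/")
      counts[pair] <- counts[pair] + 1L
    }
  }
  ts <- unname(counts["A/G"] + counts["C/T"])
  structure(list(counts = counts, transitions = ts,
                 transversions = unname(sum(counts)) - ts,
                 total = unname(sum(counts)),
                 multiallelic_sites = table$retained_columns[multi]),
            class = "substitution_spectrum")
}

#' Variable-site matrix (dot notation)
#'
#' Renders haplotypes over the positions at which any haplotype differs from
#' the reference, with vertically printed 1-based positions, the reference
#' row in full bases, and `.` marking identity with the reference.
#'
#' @inheritParams substitution_spectrum
#' @param ref_name label for the reference row.
#' @return List of class `variable_site_matrix`: `positions`, `reference`
#'   (bases at those positions), `matrix` (character matrix, haplotypes x
#'   positions, `"."` for identity) and `text` (printable lines).
#' @export
variable_site_matrix <- function(table, reference = NULL, ref_name = "Reference") {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(reference)) reference <- table$reference_pattern
  if (is.null(reference)) reference <- table$haplotypes$pattern[1]
  ref <- seq_to_chars(reference)
  pm <- do.call(rbind, strsplit(table$haplotypes$pattern, "", fixed = TRUE))
  differs <- which(vapply(seq_along(ref), function(j)
    any(pm[, j] != ref[j] & !pm[, j] %in% MISSING_CHARS), logical(1)))
  positions <- table$retained_columns[differs]
  refrow <- ref[differs]
  m <- pm[, differs, drop = FALSE]
  disp <- m
  for (j in seq_along(differs)) disp[m[, j] == refrow[j], j] <- "."
  rownames(disp) <- table$haplotypes$name
  ## vertically printed positions
  width <- max(nchar(ref_name), nchar(table$haplotypes$name))
  padded <- formatC(positions, width = max(0L, nchar(max(positions, 0L))))
  header <- if (length(positions)) {
    vapply(seq_len(nchar(padded[1])), function(i) {
      paste0(strrep(" ", width + 2L),
             paste(substr(padded, i, i), collapse = ""))
    }, "")
  } else character(0)
  body <- if (length(positions)) c(
    paste0(formatC(ref_name, width = -width), "  ", paste(refrow, collapse = "")),
    vapply(seq_len(nrow(disp)), function(i)
      paste0(formatC(rownames(disp)[i], width = -width), "  ",
             paste(disp[i, ], collapse = "")), "")
  ) else character(0)
  structure(list(positions = positions, reference = refrow, matrix = disp,
                 text = c(header, body)),
            class = "variable_site_matrix")
}

#' @export
print.variable_site_matrix <- function(x, ...) {
  if (length(x$text)) writeLines(x$text) else cat("(no variable sites)\n")
  invisible(x)
}
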