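## In-silico PCR on circular genomes.

## All binding sites of `pattern` on the sense strand of a (possibly
## circular) genome. `exact_end` marks which end of the pattern corresponds
## to the primer's 3'-terminal base: it must match exactly even when
## mismatches are allowed elsewhere. Returns 1-based start positions
## (1..genome length).
primer_sites <- function(genome, pattern, max_mismatch = 0L, circular = TRUE,
                         exact_end = c("last", "first")) {
  exact_end <- match.arg(exact_end)
  g <- toupper(genome); pat <- seq_to_chars(pattern)
  G <- nchar(g); k <- length(pat)
  if (k > G) return(integer(0))
  search <- if (circular) paste0(g, substr(g, 1L, k - 1L)) else g
  sm <- seq_to_chars(search)
  n_pos <- if (circular) G else G - k + 1L
  hits <- integer(0)
  for (p in seq_len(n_pos)) {
    win <- sm[p:(p + k - 1L)]
    mism <- sum(win != pat)
    if (mism > max_mismatch) next
    three_prime <- if (exact_end == "last") k else 1L
    if (win[three_prime] != pat[three_prime]) next
    hits <- c(hits, p)
  }
  hits
}

#' In-silico PCR on a circular genome
#'
#' The forward primer binds the sense strand; the reverse primer binds as its
#' reverse complement downstream. Product length follows the 5'-end to
#' 5'-end inclusive convention (the span between the outermost primer 5'
#' termini), and products may span the origin of a circular molecule.
#' Mismatches, when allowed, are tolerated anywhere except the 3'-terminal
#' base of either primer.
#'
#' @param genome template sequence (single string).
#' @param fwd,rev primer sequences, 5'→3'.
#' @param max_mismatch maximum mismatches per primer (default 0).
#' @param circular treat the template as circular (default `TRUE`).
#' @param on_multiple `"error"` (default) raises an ambiguity error listing
#'   all products; `"shortest"` returns the unique shortest product.
#' @return List of class `amplicon`: `start`, `end` (1-based inclusive, on
#'   the circular coordinates), `length`, `fwd_site`, `rev_site`,
#'   `spans_origin`.
#' @export
insilico_pcr <- function(genome, fwd, rev, max_mismatch = 0L, circular = TRUE,
                         on_multiple = c("error", "shortest")) {
  on_multiple <- match.arg(on_multiple)
  G <- nchar(genome)
  f_sites <- primer_sites(genome, fwd, max_mismatch, circular, exact_end = "last")
  ## reverse primer: its reverse complement appears on the sense strand; the
  ## primer 5' end maps to the LAST base of that match, its 3' end to the first
  r_starts <- primer_sites(genome, revcomp(rev), max_mismatch, circular,
                           exact_end = "first")
  r_len <- nchar(rev)
  r_5p <- ((r_starts + r_len - 2L) %% G) + 1L  # sense-strand coordinate of rev 5' end
  if (length(f_sites) == 0L || length(r_5p) == 0L)
    mp_stop("no amplicon: ", if (length(f_sites) == 0L) "forward" else "reverse",
            " primer finds no binding site", class = "mitopop_no_amplicon_error")
  cand <- expand.grid(f = f_sites, r = r_5p)
  cand$len <- if (circular) ((cand$r - cand$f) %% G) + 1L else cand$r - cand$f + 1L
  ## a physical product must contain both primers without either hanging off
  cand <- cand[cand$len >= max(nchar(fwd), r_len) & cand$len <= G, , drop = FALSE]
  if (nrow(cand) == 0L)
    mp_stop("no amplicon: no reverse site downstream of a forward site",
            class = "mitopop_no_amplicon_error")
  cand <- unique(cand)
  if (nrow(cand) > 1L && on_multiple == "error")
    mp_stop("ambiguous amplification, ", nrow(cand), " products: ",
            paste(sprintf("%d..%d (%d bp)", cand$f, cand$r, cand$len), collapse = "; "),
            class = "mitopop_ambiguous_amplicon_error")
  best <- cand[which.min(cand$len), ]
  structure(list(start = as.integer(best$f), end = as.integer(best$r),
                 length = as.integer(best$len),
                 fwd_site = as.integer(best$f), rev_site = as.integer(best$r),
                 spans_origin = best$r < best$f),
            class = "amplicon")
}

#' Run a primer panel against a genome
#'
#' Applies [insilico_pcr] to every row of a primer table and audits the
#' predicted product length against the table's printed `expected_size` and
#' against the printed position range (`region_end - region_start + 1`).
#'
#' @param genome template sequence.
#' @param primers a `primer_table` (see [read_primer_table]).
#' @inheritParams insilico_pcr
#' @return Data frame with one row per primer pair: `gene`, `region_start`,
#'   `region_end`, `start`, `end`, `length`, `expected_size`,
#'   `matches_printed` and `matches_region` flags.
#' @export
pcr_panel <- function(genome, primers, max_mismatch = 0L, circular = TRUE) {
  stopifnot(is.data.frame(primers))
  res <- lapply(seq_len(nrow(primers)), function(i) {
    amp <- insilico_pcr(genome, primers$fwd[i], primers$rev[i],
                        max_mismatch = max_mismatch, circular = circular)
    data.frame(gene = primers$gene[i],
               region_start = primers$region_start[i],
               region_end = primers$region_end[i],
               start = amp$start, end = amp$end, length = amp$length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$expected_size <- if ("expected_size" %in% names(primers))
    primers$expected_size else NA_integer_
  out$matches_printed <- !is.na(out$expected_size) & out$length == out$expected_size
  out$matches_region <- out$length == out$region_end - out$region_start + 1L
  out
}
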