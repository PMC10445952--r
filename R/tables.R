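#' Read a mitochondrial genome feature table
#'
#' Parses a tab-separated table with columns `name`, `start`, `end`,
#' `strand` and optionally `start_codon`, `stop_codon`, `size`, `anticodon`,
#' `space_overlap`. Coordinates are 1-based inclusive on the heavy-strand
#' numbering; strand is `H` or `L`. A printed `size` column is parsed but
#' never trusted: lengths are recomputed downstream and audited against it
#' (see [audit_printed_sizes]).
#'
#' @param path path to the TSV file.
#' @return data frame of class `feature_table`, rows in file order, with at
#'   least columns `name`, `start`, `end`, `strand`; `start_codon`,
#'   `stop_codon` (`NA` when absent; the incomplete stop is the literal
#'   `"T--"` form), and numeric `printed_size` / `printed_delta` when the
#'   file carries them.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) mp_stop("no such file: ", path, class = "mitopop_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  required <- c("name", "start", "end", "strand")
  miss <- setdiff(required, names(df))
  if (length(miss))
    mp_stop("feature table lacks columns: ", paste(miss, collapse = ", "),
            class = "mitopop_io_error")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    mp_stop("non-numeric coordinates in feature table", class = "mitopop_coordinate_error")
  if (any(df$start < 1L))
    mp_stop("start coordinates must be >= 1 (1-based convention)",
            class = "mitopop_coordinate_error")
  if (any(df$end < df$start))
    mp_stop("end < start for feature(s): ",
            paste(df$name[df$end < df$start], collapse = ", "),
            class = "mitopop_coordinate_error")
  if (!all(df$strand %in% c("H", "L")))
    mp_stop("strand must be H or L", class = "mitopop_value_error")
  if ("size" %in% names(df)) {
    df$printed_size <- as.integer(df$size)
    df$size <- NULL
  }
  if ("space_overlap" %in% names(df)) {
    df$printed_delta <- as.integer(df$space_overlap)
    df$space_overlap <- NULL
  }
  for (col in c("start_codon", "stop_codon"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read a PCR primer table
#'
#' Tab-separated with columns `gene`, `region_start`, `region_end`, `fwd`,
#' `rev` and optionally `expected_size` and `tm_fwd`/`tm_rev` (melting
#' temperatures are carried as metadata only).
#'
#' @param path path to the TSV file.
#' @return data frame of class `primer_table` in file order.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) mp_stop("no such file: ", path, class = "mitopop_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  required <- c("gene", "region_start", "region_end", "fwd", "rev")
  miss <- setdiff(required, names(df))
  if (length(miss))
    mp_stop("primer table lacks columns: ", paste(miss, collapse = ", "),
            class = "mitopop_io_error")
  df$region_start <- as.integer(df$region_start)
  df$region_end <- as.integer(df$region_end)
  df$fwd <- toupper(df$fwd); df$rev <- toupper(df$rev)
  if (any(!nzchar(df$fwd)) || any(!nzchar(df$rev)) ||
      any(grepl("[^ACGT]", c(df$fwd, df$rev))))
    mp_stop("primers must be non-empty strings over A,C,G,T",
            class = "mitopop_value_error")
  if ("expected_size" %in% names(df)) {
    df$expected_size <- as.integer(df$expected_size)
    if (any(df$expected_size < 1L, na.rm = TRUE))
      mp_stop("expected_size must be >= 1", class = "mitopop_value_error")
  }
  class(df) <- c("primer_table", "data.frame")
  df
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are written to six decimals; integer bootstrap supports,
#' when present as node labels, are carried through.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  txt <- ape::write.tree(tree, digits = 6)
  writeLines(txt, path)
  invisible(path)
}

#' Write a haplotype network as GraphML
#'
#' Nodes carry attributes `kind` (`"observed"` or `"median_vector"`) and
#' `frequency`; edges carry `positions`, the comma-separated list of mutated
#' 1-based site positions, and `weight`, the Hamming distance between their
#' endpoints.
#'
#' @param net a `haplotype_network` (see [median_joining]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @return `as_igraph` returns the [igraph::graph] representation.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes),
                            name = net$nodes$name,
                            kind = net$nodes$kind,
                            frequency = net$nodes$frequency)
  if (nrow(net$edges)) {
    idx <- rbind(match(net$edges$from, net$nodes$name),
                 match(net$edges$to, net$nodes$name))
    g <- igraph::add_edges(g, as.vector(idx),
                           positions = vapply(net$edges$positions,
                                              function(p) paste(p, collapse = ","), ""),
                           weight = net$edges$weight)
  }
  g
}

#' Write a named list of statistics as JSON
#'
#' @param stats named list of scalars/vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
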