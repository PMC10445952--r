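#' Condense haplotypes to their variable characters
#'
#' Median-joining operates on segregating sites only; original 1-based
#' positions are retained to label network links.
#'
#' @param table a `haplotype_table`.
#' @return List with `matrix` (character matrix, haplotypes x variable
#'   sites, column names = original positions) and `positions`.
#' @export
condense_characters <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  pm <- do.call(rbind, strsplit(table$haplotypes$pattern, "", fixed = TRUE))
  idx <- match(table$sites, table$retained_columns)
  m <- pm[, idx, drop = FALSE]
  rownames(m) <- table$haplotypes$name
  colnames(m) <- as.character(table$sites)
  list(matrix = m, positions = table$sites)
}

hamming <- function(a, b) sum(a != b)

## pairwise Hamming distances between rows of a character matrix
hamming_matrix <- function(m) {
  k <- nrow(m)
  d <- matrix(0L, k, k)
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    d[i, j] <- d[j, i] <- hamming(m[i, ], m[j, ])
  d
}

## minimum spanning network: all edges (u,v) with d(u,v) <= minimax(u,v) + eps,
## where minimax is the bottleneck (min over paths of the max step) distance.
## With eps = 0 this is exactly the union of all minimum spanning trees.
msn_edges <- function(d, eps = 0) {
  k <- nrow(d)
  mm <- d
  for (x in seq_len(k)) mm <- pmin(mm, outer(mm[, x], mm[x, ], pmax))
  which(d <= mm + eps & upper.tri(d), arr.ind = TRUE)
}

## quasi-medians of three aligned state vectors: per-site majority; a
## three-way tie keeps all three states (cartesian product, capped)
quasi_medians <- function(u, v, w, cap = 1024L) {
  S <- length(u)
  opts <- vector("list", S)
  for (s in seq_len(S)) {
    st <- c(u[s], v[s], w[s])
    tab <- table(st)
    if (max(tab) >= 2L) opts[[s]] <- names(tab)[which.max(tab)]
    else opts[[s]] <- unique(st)
  }
  total <- prod(lengths(opts))
  if (total > cap)
    mp_stop("quasi-median explosion: ", total, " combinations exceed cap ", cap,
            class = "mitopop_quasimedian_cap_error")
  if (S == 0L) return(matrix(character(0), nrow = 1L, ncol = 0L))
  as.matrix(do.call(expand.grid, c(opts, stringsAsFactors = FALSE)))
}

#' Median-joining haplotype network
#'
#' Builds the minimum spanning network over observed haplotypes (keeping all
#' links within `epsilon` of minimal), then repeatedly augments it with
#' quasi-medians — per-site majority consensus sequences of connected node
#' triplets — added as median-vector (`mv`) nodes until no new median
#' arises. Obsolete medians, those lying on no minimal path between observed
#' haplotypes, are deleted to fixpoint. Links are labelled with the mutated
#' 1-based site positions between their endpoints.
#'
#' @param table a `haplotype_table`.
#' @param epsilon relaxation parameter (default 0, the usual default of
#'   median-joining software).
#' @param cap maximum quasi-median combinations per triplet.
#' @return List of class `haplotype_network`: `nodes` (data frame `name`,
#'   `kind` = observed/median_vector, `frequency`, `pattern` over variable
#'   sites), `edges` (data frame `from`, `to`, `weight`, list-column
#'   `positions`), `positions`, `epsilon`.
#' @export
median_joining <- function(table, epsilon = 0, cap = 1024L) {
  stopifnot(inherits(table, "haplotype_table"))
  cond <- condense_characters(table)
  obs <- cond$matrix
  n_obs <- nrow(obs)
  nodes <- obs
  kind <- rep("observed", n_obs)
  if (ncol(obs) == 0L || n_obs == 1L) {
    nodes_df <- data.frame(name = rownames(obs), kind = kind,
                           frequency = table$haplotypes$count,
                           pattern = rows_to_strings(obs),
                           stringsAsFactors = FALSE)
    edges_df <- data.frame(from = character(), to = character(),
                           weight = integer(), stringsAsFactors = FALSE)
    edges_df$positions <- list()
    return(structure(list(nodes = nodes_df, edges = edges_df,
                          positions = cond$positions, epsilon = epsilon),
                     class = "haplotype_network"))
  }
  mv_counter <- 0L
  repeat {
    d <- hamming_matrix(nodes)
    ed <- msn_edges(d, epsilon)
    adj <- vector("list", nrow(nodes))
    for (r in seq_len(nrow(ed))) {
      i <- ed[r, 1]; j <- ed[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    new_pats <- character(0)
    existing <- rows_to_strings(nodes)
    ## connected triplets: two links sharing a node
    for (v in seq_len(nrow(nodes))) {
      nb <- sort(unique(adj[[v]]))
      if (length(nb) < 2L) next
      for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
        qm <- quasi_medians(nodes[nb[a], ], nodes[v, ], nodes[nb[b], ], cap)
        for (q in seq_len(nrow(qm))) {
          pat <- paste(qm[q, ], collapse = "")
          if (!pat %in% existing && !pat %in% new_pats)
            new_pats <- c(new_pats, pat)
        }
      }
    }
    if (length(new_pats) == 0L) break
    add <- do.call(rbind, strsplit(new_pats, "", fixed = TRUE))
    rownames(add) <- paste0("mv", mv_counter + seq_along(new_pats))
    mv_counter <- mv_counter + length(new_pats)
    nodes <- rbind(nodes, add)
    kind <- c(kind, rep("median_vector", length(new_pats)))
  }
  ## prune obsolete median vectors: keep only mv nodes lying on a shortest
  ## path (within the network) between some pair of observed nodes
  repeat {
    d <- hamming_matrix(nodes)
    ed <- msn_edges(d, epsilon)
    g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
    if (nrow(ed)) g <- igraph::add_edges(g, t(ed), weight = d[ed])
    gd <- igraph::distances(g)
    obs_idx <- which(kind == "observed")
    mv_idx <- which(kind == "median_vector")
    if (length(mv_idx) == 0L) break
    keep <- vapply(mv_idx, function(m) {
      for (i in obs_idx) for (j in obs_idx) {
        if (i >= j) next
        if (is.finite(gd[i, j]) && gd[i, m] + gd[m, j] <= gd[i, j] + 1e-9)
          return(TRUE)
      }
      FALSE
    }, logical(1))
    if (all(keep)) break
    drop <- mv_idx[!keep]
    nodes <- nodes[-drop, , drop = FALSE]
    kind <- kind[-drop]
  }
  d <- hamming_matrix(nodes)
  ed <- msn_edges(d, epsilon)
  nm <- rownames(nodes)
  freq <- ifelse(kind == "observed",
                 table$haplotypes$count[match(nm, table$haplotypes$name)], 0L)
  nodes_df <- data.frame(name = nm, kind = kind, frequency = as.integer(freq),
                         pattern = rows_to_strings(nodes), stringsAsFactors = FALSE)
  edges_df <- data.frame(from = nm[ed[, 1]], to = nm[ed[, 2]],
                         weight = d[ed], stringsAsFactors = FALSE)
  edges_df$positions <- lapply(seq_len(nrow(ed)), function(r)
    cond$positions[nodes[ed[r, 1], ] != nodes[ed[r, 2], ]])
  structure(list(nodes = nodes_df, edges = edges_df,
                 positions = cond$positions, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("haplotype network: %d observed, %d median vectors, %d links\n",
              s$observed, s$median_vectors, s$edges))
  invisible(x)
}

#' Integer summary of a haplotype network
#'
#' @param net a `haplotype_network`.
#' @return List with `observed`, `median_vectors`, `edges`,
#'   `max_frequency_node`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  obs <- net$nodes[net$nodes$kind == "observed", ]
  list(observed = nrow(obs),
       median_vectors = sum(net$nodes$kind == "median_vector"),
       edges = nrow(net$edges),
       max_frequency_node = obs$name[which.max(obs$frequency)])
}

#' Plain-text edge list of a network
#'
#' One line per link: `from -- to : positions`.
#'
#' @param net a `haplotype_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  lines <- vapply(seq_len(nrow(net$edges)), function(i)
    sprintf("%s -- %s : %s", net$edges$from[i], net$edges$to[i],
            paste(net$edges$positions[[i]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
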