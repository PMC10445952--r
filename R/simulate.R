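#' Default chicken mitogenome feature table
#'
#' The 19-feature organization of the 16,775 bp chicken mitochondrial
#' genome: control region, two rRNAs, the protein-coding genes and the
#' interleaved tRNAs, with 1-based inclusive heavy-strand coordinates,
#' printed sizes and printed spacer/overlap values carried for auditing.
#' One printed size (ATP6) and one printed delta (COX3) are knowingly
#' inconsistent with the coordinates; they are reported by the audits, not
#' corrected.
#'
#' @return A `feature_table` data frame.
#' @export
default_feature_table <- function() {
  df <- data.frame(
    name = c("D-loop", "rRNA1", "rRNA2", "ND1", "ND2", "tRNA-Cys", "COX1",
             "tRNA-Ser", "tRNA-Asp", "COX2", "ATP6", "COX3", "ND3", "ND4L",
             "ND4", "ND5", "CYTB", "tRNA-Pro", "ND6"),
    start = c(1L, 1297L, 2346L, 4050L, 5241L, 6508L, 6645L, 8124L, 8261L,
              8331L, 9240L, 9923L, 10776L, 11196L, 11486L, 13071L, 14893L,
              16108L, 16184L),
    end = c(1227L, 2272L, 3966L, 5024L, 6281L, 6573L, 8132L, 8258L, 8329L,
            9014L, 9923L, 10706L, 11126L, 11492L, 12863L, 14888L, 16035L,
            16177L, 16705L),
    strand = c("H", "H", "H", "H", "H", "L", "H", "L", "L", "H", "H", "H",
               "H", "H", "H", "H", "H", "L", "L"),
    start_codon = c(NA, NA, NA, "ATG", "ATG", NA, "ATG", NA, NA, "ATG", NA,
                    "ATG", "ATG", "ATG", "ATG", "ATG", "ATG", NA, "ATG"),
    stop_codon = c(NA, NA, NA, "TAA", "TAG", NA, "T--", NA, NA, "TAA", NA,
                   "T--", "TAA", "TAA", "T--", "TAA", "TAA", NA, "TAA"),
    printed_size = c(1227L, 976L, 1621L, 975L, 1041L, 66L, 1488L, 135L, 69L,
                     684L, 884L, 784L, 351L, 297L, 1378L, 1818L, 1143L, 70L,
                     522L),
    printed_delta = c(NA, 70L, 74L, 84L, 217L, 227L, 72L, -8L, 3L, 2L, 226L,
                      -1L, 70L, 70L, -6L, 208L, 5L, 73L, 7L),
    stringsAsFactors = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Default mitogenome base frequencies (percent)
#'
#' A = 30.26, T = 23.76, C = 32.48, G = 13.50 — the global frequency set of
#' the chicken mitogenome alignment used throughout as the simulation
#' default.
#'
#' @return Named numeric vector in A, C, G, T order, summing to 100.
#' @export
default_base_freqs <- function() {
  c(A = 30.26, C = 32.48, G = 13.50, T = 23.76)
}

#' Default control-region motif plan
#'
#' Motifs planted into the simulated D-loop: the invariant tetradecamer at
#' its two canonical positions (264 and 325), the interrupted thymine
#' string, the conserved poly-C and poly-G stretches, and a set of
#' termination-associated TACAT / TATAT elements, all placed clear of the
#' default primer landing sites.
#'
#' @return Data frame with columns `motif` and `position`.
#' @export
default_motifs <- function() {
  data.frame(
    motif = c("AACTATGAATGGTT", "AACTATGAATGGTT", "TTTTATTTTTTAA",
              "CCCCCCCTTTCCCC", "AGGGGGGGT",
              rep("TACAT", 4), rep("TATAT", 9)),
    position = c(264L, 325L, 471L, 500L, 530L,
                 c(560L, 575L, 590L, 605L),
                 c(620L, 630L, 640L, 650L, 660L, 670L, 680L, 690L, 700L)),
    stringsAsFactors = FALSE)
}

## plant a string into a character buffer with conflict detection: writing a
## different base over an already-fixed position is a placement error
plant <- function(buf, s, at, what = "motif") {
  ch <- seq_to_chars(s)
  idx <- at + seq_along(ch) - 1L
  if (any(idx < 1L) || any(idx > length(buf)))
    mp_stop(what, " '", s, "' at ", at, " exceeds genome bounds",
            class = "mitopop_placement_error")
  fixed <- !is.na(buf[idx])
  if (any(fixed & buf[idx] != ch))
    mp_stop(what, " '", s, "' at ", at, " conflicts with previously planted ",
            "sequence at position(s) ",
            paste(idx[fixed & buf[idx] != ch][1:min(3, sum(fixed & buf[idx] != ch))],
                  collapse = ", "),
            class = "mitopop_placement_error")
  buf[idx] <- ch
  buf
}

#' Simulate a circular mitogenome with a known layout
#'
#' Generates a genome realizing a feature table: every protein-coding
#' feature receives its start codon (`GTG` for a feature named `COX1`, `ATG`
#' otherwise) and a stop consistent with its length mod 3 (a complete
#' `TAA`/`TAG` stop, or the truncated 1- or 2-base form completed by
#' polyadenylation); light-strand features are written in reverse
#' complement. Primer landing sites and control-region motifs are planted
#' verbatim with conflict detection; all remaining positions are drawn
#' i.i.d. from `base_freqs`.
#'
#' Reverse-primer sites are placed so the product's 5'-to-5' span equals the
#' primer table's `expected_size` when present (falling back to the printed
#' region range), which keeps overlapping landing sites from adjacent
#' amplicons mutually consistent.
#'
#' @param features a `feature_table` (default [default_feature_table]).
#' @param genome_length circular molecule length (default 16775).
#' @param base_freqs named A/C/G/T percentages (default [default_base_freqs]).
#' @param motifs data frame `motif`, `position` (default [default_motifs]);
#'   `NULL` to plant none.
#' @param primers optional `primer_table`; for every row the forward primer
#'   is planted at `region_start` and the reverse-complemented reverse
#'   primer upstream of the product end.
#' @param seed integer seed; the genome is deterministic given identical
#'   arguments.
#' @return List of class `synthetic_genome`: `sequence` (string), `layout`
#'   (a [genome_layout]), `motifs`, `primers`, `seed`.
#' @export
make_genome <- function(features = default_feature_table(),
                        genome_length = 16775L,
                        base_freqs = default_base_freqs(),
                        motifs = default_motifs(),
                        primers = NULL,
                        seed = 1L) {
  stopifnot(abs(sum(base_freqs) - 100) < 1e-6)
  buf <- rep(NA_character_, genome_length)
  ## feature codons first: they are the layout's load-bearing content
  for (i in seq_len(nrow(features))) {
    sc <- features$start_codon[i]
    if (is.na(sc)) next
    sc <- if (features$name[i] == "COX1") "GTG" else sc
    len <- features$end[i] - features$start[i] + 1L
    stop_print <- features$stop_codon[i]
    full_stop <- if (!is.na(stop_print) && stop_print %in% c("TAA", "TAG", "TGA"))
      stop_print else "TAA"
    stop_seq <- switch(as.character(len %% 3L),
                       "0" = full_stop, "1" = "T", "2" = "TA")
    if (features$strand[i] == "H") {
      buf <- plant(buf, sc, features$start[i], paste0(features$name[i], " start codon"))
      buf <- plant(buf, stop_seq, features$end[i] - nchar(stop_seq) + 1L,
                   paste0(features$name[i], " stop codon"))
    } else {
      buf <- plant(buf, revcomp(sc), features$end[i] - 2L,
                   paste0(features$name[i], " start codon"))
      buf <- plant(buf, revcomp(stop_seq), features$start[i],
                   paste0(features$name[i], " stop codon"))
    }
  }
  if (!is.null(primers)) {
    for (i in seq_len(nrow(primers))) {
      buf <- plant(buf, primers$fwd[i], primers$region_start[i],
                   paste0(primers$gene[i], " forward primer"))
      size <- if ("expected_size" %in% names(primers) && !is.na(primers$expected_size[i]))
        primers$expected_size[i]
      else primers$region_end[i] - primers$region_start[i] + 1L
      rev_site <- primers$region_start[i] + size - 1L  # 5' end of reverse primer
      rc <- revcomp(primers$rev[i])
      buf <- plant(buf, rc, rev_site - nchar(rc) + 1L,
                   paste0(primers$gene[i], " reverse primer"))
    }
  }
  if (!is.null(motifs)) {
    for (i in seq_len(nrow(motifs)))
      buf <- plant(buf, motifs$motif[i], motifs$position[i], "motif")
  }
  set.seed(seed)
  free <- is.na(buf)
  buf[free] <- sample(names(base_freqs), sum(free), replace = TRUE,
                      prob = base_freqs / 100)
  structure(list(sequence = paste(buf, collapse = ""),
                 layout = genome_layout(features, genome_length),
                 motifs = motifs, primers = primers, seed = seed),
            class = "synthetic_genome")
}

## Kingman coalescent topology with exponential waiting times; returns
## nodes as a list of (children ids, branch lengths to children)
rcoalescent <- function(n) {
  active <- as.list(seq_len(n))
  heights <- rep(0, n)
  node_children <- list(); node_blen <- list(); node_height <- numeric(0)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    a <- active[[pick[1]]]; b <- active[[pick[2]]]
    node_children[[length(node_children) + 1L]] <- c(a, b)
    node_blen[[length(node_blen) + 1L]] <- c(t - heights[a], t - heights[b])
    heights <- c(heights, t)
    active <- c(active[-pick], list(nxt))
    nxt <- nxt + 1L
  }
  list(children = node_children, blen = node_blen, n = n)
}

## apply one mutation to a character vector at site s with transition bias
mutate_base <- function(base, bias) {
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < bias / (bias + 1)) partner[[base]]
  else sample(setdiff(DNA_BASES, c(base, partner[[base]])), 1L)
}

#' Simulate a haplotype population with known ground truth
#'
#' An ancestral sequence is drawn from `base_freqs` and evolved on a star or
#' Kingman-coalescent genealogy. Mutations fall on branches as a Poisson
#' process of rate `theta / 2` per site per unit of coalescent time; each
#' mutation is a transition with probability `bias / (bias + 1)` and
#' otherwise a uniformly chosen transversion. Under the coalescent the
#' expected nucleotide diversity per site equals `theta`. Alignments are
#' generated gap-free.
#'
#' @param n number of sequences (>= 2).
#' @param length region length in bp.
#' @param genealogy `"coalescent"` (default) or `"star"` (unit-length tip
#'   branches; exact control for network tests).
#' @param theta per-site mutation parameter.
#' @param ts_tv_bias transition:transversion rate ratio. The default 15
#'   reflects the strong pyrimidine-transition dominance of mitochondrial
#'   control-region data.
#' @param mutations_per_tip star mode only: exactly this many mutations per
#'   tip at globally distinct sites (overrides `theta`), giving homoplasy-free
#'   data by construction.
#' @param base_freqs named A/C/G/T percentages.
#' @param seed integer seed.
#' @return List of class `synthetic_population`: `aln` (an [aln_set] named
#'   `s1..sn`), `tree` (the true genealogy as [ape::phylo]), `mutations`
#'   (data frame `site`, `from`, `to`, `branch`), `mutated_sites`, `theta`,
#'   `seed`.
#' @export
make_population <- function(n, length = 1000L,
                            genealogy = c("coalescent", "star"),
                            theta = 0.01, ts_tv_bias = 15,
                            mutations_per_tip = NULL,
                            base_freqs = default_base_freqs(), seed = 1L) {
  genealogy <- match.arg(genealogy)
  if (n < 2L) mp_stop("need n >= 2", class = "mitopop_sample_size_error")
  stopifnot(theta > 0, ts_tv_bias > 0)
  set.seed(seed)
  anc <- sample(names(base_freqs), length, replace = TRUE, prob = base_freqs / 100)
  tips <- paste0("s", seq_len(n))
  muts <- list()
  seqs <- matrix(NA_character_, nrow = n, ncol = length)
  if (genealogy == "star") {
    if (!is.null(mutations_per_tip)) {
      need <- n * mutations_per_tip
      if (need > length)
        mp_stop("not enough sites for ", need, " distinct mutations",
                class = "mitopop_value_error")
      sites <- sample.int(length, need)
      for (i in seq_len(n)) {
        s <- anc
        mine <- sites[((i - 1L) * mutations_per_tip + 1L):(i * mutations_per_tip)]
        for (site in mine) {
          to <- mutate_base(s[site], ts_tv_bias)
          muts[[length(muts) + 1L]] <- data.frame(site = site, from = s[site],
                                                  to = to, branch = tips[i])
          s[site] <- to
        }
        seqs[i, ] <- s
      }
    } else {
      for (i in seq_len(n)) {
        s <- anc
        nm <- stats::rpois(1, theta / 2 * length)
        for (site in sample.int(length, nm, replace = TRUE)) {
          to <- mutate_base(s[site], ts_tv_bias)
          muts[[length(muts) + 1L]] <- data.frame(site = site, from = s[site],
                                                  to = to, branch = tips[i])
          s[site] <- to
        }
        seqs[i, ] <- s
      }
    }
    tree <- ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
  } else {
    topo <- rcoalescent(n)
    n_nodes <- n + length(topo$children)
    node_seq <- vector("list", n_nodes)
    node_seq[[n_nodes]] <- anc  # root is the last-created internal node
    for (k in rev(seq_along(topo$children))) {
      parent <- n + k
      ch <- topo$children[[k]]; bl <- topo$blen[[k]]
      for (ci in 1:2) {
        s <- node_seq[[parent]]
        nm <- stats::rpois(1, theta / 2 * length * bl[ci])
        for (site in sample.int(length, min(nm, .Machine$integer.max), replace = TRUE)) {
          to <- mutate_base(s[site], ts_tv_bias)
          muts[[length(muts) + 1L]] <- data.frame(
            site = site, from = s[site], to = to,
            branch = paste0(parent, "->", ch[ci]))
          s[site] <- to
        }
        node_seq[[ch[ci]]] <- s
      }
    }
    for (i in seq_len(n)) seqs[i, ] <- node_seq[[i]]
    ## genealogy as newick for reporting
    reps <- as.list(tips)
    for (k in seq_along(topo$children)) {
      ch <- topo$children[[k]]; bl <- topo$blen[[k]]
      reps[[n + k]] <- sprintf("(%s:%.6g,%s:%.6g)", reps[[ch[1]]], bl[1],
                               reps[[ch[2]]], bl[2])
    }
    tree <- ape::read.tree(text = paste0(reps[[n_nodes]], ";"))
  }
  mdf <- if (length(muts)) do.call(rbind, muts)
         else data.frame(site = integer(), from = character(),
                         to = character(), branch = character())
  structure(list(aln = aln_set(rows_to_strings(seqs), tips), tree = tree,
                 mutations = mdf, mutated_sites = sort(unique(mdf$site)),
                 theta = theta, seed = seed),
            class = "synthetic_population")
}
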