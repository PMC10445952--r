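---
title: "Mitogenome population analysis: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome population analysis: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopop)
```

This vignette is the package's account of the science it implements: the
statistics and algorithms, the conventions chosen where the field's
literature is ambiguous, what the synthetic-data generator does and does not
emulate, and the known limitations. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The setting

Mitochondrial DNA is maternally inherited, effectively non-recombining and
fast-evolving in its non-coding control region (D-loop), which makes D-loop
and whole-mitogenome alignments the standard marker for matriline studies
in livestock and wild populations. The analyses around such data fall into
three groups, and the package mirrors them in its modules:

1. *genome organization* — arithmetic over an annotated feature table and
   the molecule itself;
2. *within-sample variation* — haplotypes, diversity statistics,
   substitution spectra;
3. *between-haplotype structure* — model-based distances, trees, and
   haplotype networks.

## Coordinates and gaps: two conventions fixed once

**All coordinates are 1-based inclusive.** Feature tables and primer
positions in the source literature use this convention; the package never
translates to half-open internally, eliminating a standing source of
off-by-one errors. A feature's length is `end − start + 1`; an inter-feature
delta is `start(next) − end(prev)`, positive for spacers. A shared boundary
(delta 0) is classified as an overlap: one base cannot belong "between" two
genes, and this classification is what reconciles the canonical chicken
table's count of 3 overlaps. Because published tables mix the signed-delta
and shared-base conventions, `adjacency_deltas()` reports both.

**Gap and ambiguity characters (`-`, `N`) are missing data.** The default
throughout is complete deletion — any column carrying a missing character in
any row is dropped before haplotypes, diversity or rates are computed —
because alignment gaps in control-region data overwhelmingly stem from
deletion events whose placement is an artifact of the aligner. Pairwise
deletion is available by flag for distance work, where discarding a whole
column for one ragged row wastes information.

## Auditing printed tables rather than trusting them

Published organization tables carry redundant columns (size, spacing) that
sometimes contradict their own coordinates. The package treats printed sizes
as assertions: `audit_printed_sizes()` recomputes lengths and lists
discrepancies, and the bundled 19-feature chicken table demonstrates why —
exactly one row (ATP6) prints 884 where the coordinates give 684. The same
policy governs the primer panel: `pcr_panel()` checks each predicted product
against both the printed size and the printed position range and reports
both flags. Two of the fifteen bundled rows have a printed size equal to
`end − start` rather than `end − start + 1`; the overlap of two adjacent
landing sites in the real sequence shows the printed sizes (not the ranges)
are the self-consistent values there, so the generator plants reverse sites
to honor the printed size when present. Nothing is silently corrected in
either table.

## In-silico PCR

Products are measured 5'-end to 5'-end inclusive — the convention that
reproduces the bundled panel's printed sizes from its printed positions.
Templates are circular by default and products may span the origin (length
`genome_length − start + 1 + end`). `max_mismatch` defaults to 0; when
mismatches are allowed they are tolerated anywhere except the 3'-terminal
base of either primer, the standard heuristic for polymerase extension.
Melting temperatures in primer tables are metadata only; no Tm model is
implemented. If a primer pair admits several products the call fails loudly
with all candidates listed (`on_multiple = "shortest"` opts into the
shortest, which PCR kinetics favor).

## Nei diversity statistics

Nucleotide diversity is computed from the haplotype representation,

$$\pi = \frac{n}{n-1} \sum_{i<j} 2 x_i x_j \pi_{ij},$$

with $x_i$ haplotype frequencies and $\pi_{ij}$ the per-site difference
proportion over the retained columns; this equals the mean pairwise
difference over all $n(n-1)/2$ sequence pairs, and the test suite holds the
two routes to within 1e-12. Haplotype diversity uses the
$h = 2n(1-\sum x_i^2)/(2n-1)$ form, which is bounded strictly below 1 and
approaches $1 - 1/H$ for equal frequencies as $n \to \infty$.

For population differentiation the source literature names Fst/Nst without
an estimator, so the package implements a clearly-labelled Gst-style
statistic on haplotype frequencies, $(H_t - H_s)/H_t$ with $H_t$ the pooled
(unweighted mean) gene diversity and $H_s$ the mean within-population gene
diversity, with significance by random reassignment of individuals
(sizes preserved) and the $(b+1)/(m+1)$ p-value convention so p is never
zero. It exercises haplotype-frequency structure without claiming
equivalence to any particular Fst estimator; a distance-weighted Nst is out
of scope because no defining formula or reported value exists to validate
against.

## Distances and the rate matrix

The Kimura two-parameter distance separates transition (P) and transversion
(Q) proportions; saturated pairs (a non-positive log argument) raise an
error naming the pair instead of returning a capped value — anomalously
scaled distances in published tables are exactly the artifact this refuses
to emulate.

The Tamura-Nei rate matrix is estimated by method of moments rather than
tree-based maximum likelihood: pairwise $P_1$ (purine transitions), $P_2$
(pyrimidine transitions) and $Q$ are pooled over distinct sequences
(duplicated rows carry no extra weight, making the estimate invariant to
resampling of identical individuals), converted to per-class expected
substitution counts via the TN93 log corrections

$$s_1 = -\frac{2\pi_A\pi_G}{\pi_R}\left(\ln w_1 - \pi_Y \ln w_3\right),
\quad s_v = -2\pi_R\pi_Y \ln w_3,$$

and divided by their frequency weights to give the relative factors
$k_1, k_2, b$. Entries are filled as $r(x{\to}j) = k\,\pi_j$ and rescaled so
the 12 off-diagonal rates sum to 100, matching the conventional printed
normalization. All three class estimates share one time factor, which the
normalization cancels, so only relative rates are reported — full ML would
add a tree and likelihood machinery without changing the reported structure.
Base frequencies are estimated globally from all analyzed columns.

## Neighbor joining

Standard Saitou-Nei agglomeration on the Q-criterion with the
Studier-Keppler update. Two behaviors are pinned down deterministically:
ties in Q resolve to the lowest index pair in input order, and negative
branch lengths are clamped to zero with the deficit moved to the sibling
branch so the joined pair's distance is preserved. On additive matrices the
method is exact (topology and path lengths to 1e-9, verified against
randomly generated trees). Bootstrap resamples alignment columns with
replacement; support for each internal bipartition of the full-data tree is
the percentage of replicate trees containing it, replicates with saturated
pairs being skipped and counted. Whether columns are filtered by complete
or pairwise deletion is a flag, since either choice is defensible and the
literature rarely states which was used. Midpoint rooting is a display
concern left to the caller.

## Median-joining networks

The network grows from the minimum spanning network — all links within
`epsilon` of minimal, computed via bottleneck (minimax) distances so that
`epsilon = 0` yields exactly the union of all minimum spanning trees — by
repeatedly adding quasi-medians of connected triplets: per-site majority
state, with all combinations retained on three-way ties (bounded by a cap
of 1024 per triplet with a loud error beyond, relevant only to pathological
multistate data). After the growth fixpoint, median vectors lying on no
minimal within-network path between observed haplotypes are pruned, again
to fixpoint. Links carry the original 1-based positions at which their
endpoints differ, so an edge's label length always equals the Hamming
distance between its endpoints. Observed haplotypes keep their sample
frequencies; proportional-area drawing is left to downstream tools
(the GraphML export carries `kind` and `frequency` attributes for that
purpose).

Note that connections may legitimately route through intermediate observed
haplotypes, so network geodesics can exceed raw Hamming distances — they
are the parsimonious mutational paths, not straight-line distances; and for
mutually equidistant haplotypes the network correctly retains all minimal
alternatives rather than an arbitrary tree.

## The synthetic-data generator

The generator exists to make the pipeline testable end to end with known
ground truth; it emulates the statistical structure the analyses assume,
not a sequencing experiment.

`make_genome()` realizes a 16,775 bp circular molecule from the bundled
19-feature layout: every coding feature receives its start codon (GTG for a
feature named COX1, ATG otherwise) and a stop consistent with its length
mod 3 (`TAA`/`TAG`, or the polyadenylation-completed `T--`/`TA-` forms),
light-strand features written in reverse complement; control-region motifs
(the invariant tetradecamer at 264 and 325, the interrupted thymine string,
poly-C, poly-G, TACAT/TATAT elements) and the primer panel's landing sites
are planted verbatim with character-level conflict detection; remaining
positions are i.i.d. draws from the default frequencies A 30.26 %, T
23.76 %, C 32.48 %, G 13.50 %. Because intergenic fill is random, motif
*counts* in a simulated D-loop exceed the planted counts by chance
occurrences (a 5-mer recurs by chance roughly once per kilobase), so tests
assert planted positions, never exact totals.

`make_population()` evolves an ancestral sequence on a star or Kingman
coalescent genealogy; mutations arrive as a Poisson process at rate θ/2 per
site per unit of coalescent time, so under the coalescent E[π] = θ (the
test suite checks recovery to within 3 standard errors over 200
replicates at θ = 0.01, n = 10, 500 bp). Each mutation is a transition with
probability bias/(bias + 1); the default bias of 15 is the
pyrimidine-transition dominance implied by the structure of published
mitochondrial rate matrices, stated here as a derived default rather than a
measured value. Star mode with `mutations_per_tip` places exactly that many
mutations at globally distinct sites, giving homoplasy-free data where the
true network is known by construction (the unsampled ancestor must be
recovered as the single hub median vector). Alignments are generated
gap-free — indel realism is deliberately excluded, and gap handling is
exercised by hand-made fixtures instead — and nothing read-level
(sequencing error, coverage, chimeras) is simulated, so passing tests
certify the analytics, not robustness to upstream artifacts.

The analysis workflow uses an 8-sequence, 1227 bp population at θ = 0.005 —
a control-region-sized problem matching a small breed panel — and the test
and acceptance runs use problem sizes (hundreds of bp to 10 kb, tens to a
few hundred replicates) chosen to keep the full suite in the tens of
seconds while leaving simulation standard errors well inside the asserted
tolerances.

## Numerical choices and degenerate inputs

* Distances: saturation aborts with the offending pair named; zero
  comparable columns is an error, not a zero.
* NJ requires ≥ 3 finite taxa; the 3-taxon case solves the three-point
  equations in closed form.
* Identical sequences give an estimation error from the rate-matrix fitter
  (there is nothing to fit), a zero distance matrix from K2P, and a
  single-node network from median joining.
* Permutation p-values are never zero by construction.
* Frequencies must sum to 1 (1e-9) and printed rate sums to 100 are checked
  to 0.1, the slack of the published rounding.

## Known limitations

* The differentiation statistic is frequency-based only; no
  distance-weighted (Nst-style) estimator is provided.
* TN93 estimation is moment-based; no gamma rate heterogeneity, no ML tree.
* Median-joining handles multistate sites by majority with tie expansion,
  not the reduced-median preprocessing of binary-recoded data.
* The in-silico PCR model is exact-match-oriented; degenerate bases and
  thermodynamic binding models are out of scope.
* Synthetic data contains no indels, recombination (appropriate for mtDNA),
  rate heterogeneity across sites, or sequencing error.
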