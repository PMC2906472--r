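---
title: "Methods: SRCR receptor domain analysis with srcrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRCR receptor domain analysis with srcrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcrtools)
```

# The analysis

CD163/WC1-family receptors are strings of group-B scavenger receptor
cysteine-rich (SRCR) domains.  Each domain is a ~78–110 residue module
whose group-B form carries eight cysteines pairing as C1–C4, C2–C7,
C3–C8 and C5–C6.  Receptor identity questions (is a predicted gene a
CD163A, a CD163c-α, a WC1, or something in between?) are answered at the
domain level: segment the protein into domains, place each domain on a
phylogeny against domains of known class, read off the per-domain letter,
and compare the resulting N→C architecture string with the canonical
organizations (`h-i-j-k-b-c-d-e-d'` for CD163A, `m-l-b-c-n-d-e-d'` for
CD163c-α, `a-b-c-d-e-d-b-c-d-e-d'` for bovine WC1).  This vignette
records the models, parameter choices and numerical conventions behind
each stage, and what the accompanying tests do and do not demonstrate.

# Domain model and scanning

`build_domain_model()` turns a labelled reference alignment into a
position-specific profile: per-column residue frequencies with a uniform
pseudocount (1/20 per residue), converted to half-bit log-odds against a
uniform background.  Core columns are those occupied in more than half
of the reference rows; the eight cysteine columns are those whose
cysteine frequency is at least 0.5 (majority rule), taken left to right.
Fewer than eight such columns is an error — the reference is then not a
group-B SRCR set.

`scan_protein()` runs affine-gap Smith–Waterman of the profile against
the protein and collects non-overlapping hits greedily by score.
Numerical conventions that matter:

* **Gap penalties for scanning** are steeper (open 12, extension 2 in
  profile units) than for residue alignment.  With cheap extensions a
  single profile pass can "straddle" two adjacent domains across a
  linker, cherry-picking its best columns from each; pricing a
  linker-length insertion above what it can recover keeps every pass
  inside one domain.
* **Envelope completion.** A local alignment trims diverged terminal
  columns, so an accepted hit is first extended outward, one residue per
  missing terminal model column (never into another hit), before its
  span is judged.  Without this, atypical domains with diverged ends
  fall under the minimum-span test and vanish.
* **Acceptance.** A hit is kept if its score reaches
  `score_threshold` (default 40% of the model self-match score) and its
  completed span lies within `[min_span - edge_slack, max_span]`
  (defaults 78, 6 and 110 residues).  The 40% default was calibrated on
  the simulator so that domains as diverged as the most distant
  inter-class pairs (p-distance above 0.8) are accepted while linkers
  and tails are not.  No published numeric inclusion criterion exists
  for "conforms to the group-B consensus"; this threshold is this
  package's operational definition.
* **Cysteine status informs the report, not the decision**: hits missing
  up to several cysteines are reported with `group_call = "B_atypical"`.
* Rejected over-long placements mask only their leading minimum-span
  window, so any domain they straddled remains discoverable in later
  iterations; ties between equal-scoring placements resolve to the
  smaller start coordinate.

# Alignment

Pairwise alignment is Needleman–Wunsch/Gotoh under Gonnet PAM-250 with
gap opening 10.0 and extension 0.10 per residue (a length-k gap costs
`open + k·ext`).  The multiple aligner merges profiles along a UPGMA
guide tree built from pairwise p-distances, scoring column pairs by the
frequency-weighted expected substitution score.  Determinism rules: at
every DP cell the match state is preferred over a gap in the second
object over a gap in the first, so tied optima give identical alignments
on every platform.  Terminal gaps are penalized by default
(`align_params(penalize_ends = FALSE)` switches to end-free overlap
alignment).  `X` (unknown residue) scores zero against everything and is
excluded from identity and distance denominators.

`trim_to_core()` projects any alignment containing reference rows onto
the model's core columns, so downstream distances always use a fixed
column count (78 for the default domain length).  Insertion columns are
dropped; the projection is exact because reference rows are of known
coordinates.

# Divergence and its uncertainty

`p_distance()` is the proportion of differing sites over columns where
neither row has a gap or `X` (pairwise deletion; complete deletion is
available in `distance_matrix()`).  Pairwise deletion is the default
because domains with deletions or dropped cysteines would otherwise
remove columns for every pair.  An empty denominator yields a missing
value, never zero.

`bootstrap_se()` resamples columns with replacement (default B = 1000,
seed mandatory; acceptance work uses B = 10000) and reports the standard
deviation of the resampled distances.  For a p-distance this converges
to the binomial form `sqrt(p(1-p)/L)` implemented in `analytic_se()`,
which the test suite uses as an independent check.  The suite also runs
a data-only consistency check of published domain-divergence tables
against the analytic form at L = 78: the p-values are exact multiples of
1/78 throughout (confirming a fixed 78-column core), while a minority of
the printed standard errors deviate from the analytic values by up to a
few thousandths — the signature of finite-replicate bootstrap estimates,
whose replicate count the source does not state.  That check is asserted
at the strict 0.0005 band and therefore fails on those cells by design;
the failure message quantifies the deviation rather than hiding it.

Corrections: `poisson` applies `-ln(1-p)`; `jtt_like` inverts the
expected-difference curve `p(d) = 1 - Σ_i π_i [e^{Qd}]_{ii}` of the JTT
rate matrix (shipped as plain text, normalized to one expected
substitution per site) by bisection on its eigendecomposition, to
`1e-10` tolerance.  Saturated inputs return `Inf` with a warning.

# Trees and support

`neighbor_joining()` is the standard Saitou–Nei agglomeration.  Ties in
the Q criterion resolve to the smallest (row, column) pair of the
current matrix, making output platform-independent.  Negative branch
lengths are retained with a warning (MEGA-style); `clamp_negative =
TRUE` zeroes them and compensates on the sister edge.  On additive
matrices the method is exact — the tests verify both topology and
leaf-to-leaf path lengths to 1e-9 against simulated additive
genealogies, and against exhaustive least-squares topology search for
4–5 taxa.

`bootstrap_tree()` resamples alignment columns, rebuilds NJ trees and
reports the fraction of replicates containing each internal bipartition.
Zero-length internal edges of the point tree are collapsed first, so
uninformative resolutions (identical sequences) carry no supported
bipartitions.

# Letter assignment

`assign_letters()` works on the unrooted tree: both sides of every
internal edge with support ≥ `threshold` (default 0.70) are candidate
clades.  For each query domain the smallest supported clade containing
it and at least one lettered reference decides: letter-consistent →
that letter; mixing only `d` and `d'` → `d'` if the query is its
protein's C-terminal domain and `d` otherwise (the convention that `d'`
is the membrane-proximal domain); otherwise mixed → fall through.
Queries that fall through and sit in a supported reference-free clade of
two or more such queries share one newly allocated letter; new letters
run alphabetically from `o`, skipping reference letters and `x` (the
rendering of "undesignated"), in order of first occurrence in the
tree's leaf order.  Everything else stays undesignated.  The 0.70
support default is a configuration choice: the original clade calls in
this field used Bayesian posterior probabilities with no stated cutoff,
so no fidelity claim attaches to it.  Trees without support labels are
treated as fully resolved, which lets the pipeline run without
bootstrapping when speed matters.

`positional_refine()` then promotes an undesignated domain whose
assigned flanking letters match exactly one context (left and right
letters, protein termini counting as context) among the reference
architectures.  Clade assignments are never overridden.

# Transmembrane partition and motifs

`predict_tm()` is a transparent stand-in for server-based predictors: a
19-residue sliding window of mean Kyte–Doolittle hydropathy at threshold
1.6 marks candidate cores; runs of qualifying window centers are grown
symmetrically to at least one window length.  It exists to make the
cytoplasmic/extracellular split reproducible offline; user-supplied
coordinates bypass it (`source = "user_supplied"`) when curated
boundaries are available.  `scan_wc1_motif()` reports every tetramer
matching Y-(Q/E)-(D/C/E)-(I/L), overlaps included, and tags
threonine-terminal near-misses separately without counting them as
motifs.

# The simulator: what it emulates, and what it does not

`generate_family()` is a pure function of its seed.  Its defaults are
the study conditions for every benchmark in the test suite:

* 13 letters (a, b, c, d, d', e, h–n), 78-residue domains with the
  8-cysteine scaffold at fixed columns;
* expected inter-letter prototype p-distance 0.55 and within-letter rate
  0.10 — anchored to the published intra-class (≈0.09–0.23) and
  inter-class (≈0.45–0.82) divergence ranges, so classification is
  exercised at realistic difficulty;
* three architectures (bovine WC1, CD163A, CD163c-α organizations), four
  copies each; hydrophilic linkers of 8–15 residues; an optional
  21-residue hydrophobic transmembrane segment; tails carrying YEEL
  (WC1-type), YREM, or nothing; optional single-cysteine dropout.

Prototypes are built by redrawing a fixed fraction of "variable"
columns independently per letter (`n_var = divergence · L · 19/18`),
which concentrates realized pairwise divergences tightly around the
target; sets are redrawn (deterministically, bounded attempts) until all
pairs land within ±0.08.  Copies evolve independently from their
prototype — a star genealogy within each letter — so the family truth
tree is a star of stars.  For benchmarking *tree reconstruction* the
package provides `generate_domain_genealogy()`, which evolves a domain
along a random binary genealogy in infinite-sites fashion (every edge at
least one substitution, every column mutated on at most one edge):
pairwise distances are then exactly additive and NJ provably recovers
the truth, so recovery failures indicate implementation error rather
than statistical noise.

What the simulator does **not** emulate: insertions/deletions inside
domains (real SRCR domains vary 78–110 aa; linkers stand in for length
variation between domains), compositional bias, rate heterogeneity
across sites, gene conversion between paralogs, and non-SRCR domains.
Passing the recovery suite therefore shows the pipeline is correct and
well-calibrated under clean conditions; it does not bound performance on
genomic predictions with fragmented or intron-interrupted domains.

# Problem sizes and seeds used by the test suite

The end-to-end recovery test runs the default family (12 receptors, 112
domains, seed 17), a 26-row labelled reference (two copies per letter at
rate 0.05), B = 100 bootstrap replicates, and asserts ≥95% domain recall
at ≤2-residue boundary error, ≥95% letter accuracy, ≥90% exact
architecture strings, distances within twice the analytic SE of truth,
and exact (RF = 0) recovery of additive genealogies.  Property tests
check the aligner against exhaustive enumeration on ≤8-mers, NJ against
exhaustive topology search on ≤5 taxa, and the motif scanner against the
12-tetramer enumeration.  These sizes are the package's own choices:
small enough to run routinely, large enough that each claim is exercised
on more than one case.

# Known limitations

* Letter assignment quality is bounded by the reference set; a query
  class absent from the references can only earn a new letter or remain
  undesignated.
* The scanner's greedy non-overlapping tiling cannot represent nested or
  overlapping domains (none are known in this family).
* Manual alignment curation, which published tables in this field often
  underwent, is irreproducible; cell-level differences of one or two
  columns against such tables are expected.
* The hydropathy transmembrane rule is deliberately simple; curated
  coordinates should be supplied for publication-grade topology claims.
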