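---
title: "Methods: comparative analytics for insect mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analytics for insect mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp dissects annotated circular mitochondrial genomes of the kind
found in whiteflies (Hemiptera: Aleyrodidae): a ~15 kb circle with 13
protein-coding genes (PCGs), about 21 tRNAs, two rRNAs and one large
non-coding control region (CR), with genes on both strands and heavy
gene-order rearrangement relative to the ancestral insect arrangement.
This vignette explains the models and procedures behind each analysis
stage, the parameters that matter, and the choices made where the
design was genuinely open.

## The annotation model

An annotation is an ordered feature table on a circular molecule:
1-based inclusive coordinates (the GenBank convention), a strand per
feature, and optional *declared* columns (size, intergenic nucleotides,
codons, A+T content) carried alongside whatever can be *computed* from
coordinates and sequence. The two sources are kept strictly separate:
`validate_annotation()` reports every disagreement and nothing is ever
silently "corrected". Published gene-structure tables do contain
internal inconsistencies — in the packaged whitefly table the CR prints
920 bp against a 922 bp coordinate span, one tRNA's declared overlap is
−20 where coordinates give −15, and the origin-wrapping junction prints
1 against a computed 0 — and those disagreements are findings a user
should see, not errors to repair.

Junctions are evaluated in the table's listing order, because that is
how the IGN (intergenic nucleotides) column of such tables is laid out:
each row's IGN is the signed spacer to the *next* row, negative values
meaning overlap, with one wrap junction closing the circle. On the
declared source the packaged table yields 51 bp of overlap across 10
gene pairs and 91 bp of intergenic sequence across 14 pairs, with a
25 bp maximum gap — the compactness profile typical of whitefly
mitogenomes.

## Composition and strand skews

Strand asymmetry uses the standard definitions
AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C), computed on
the strand as given. Ambiguity codes are excluded from every
denominator and counted separately; a zero denominator yields `NA`
rather than a number. Reported percentages follow the field's
convention of one decimal, skews three decimals; internal computation
is at full precision. Per-category table summaries are *unweighted*
means of the declared column — that convention reproduces published
per-category averages exactly (e.g. the 76.7% mean tRNA A+T content of
the packaged table) — while the "combined" A+T content of a gene class
is the length-weighted mean.

## Codon usage and RSCU

The genetic code is fixed to NCBI translation table 5, the invertebrate
mitochondrial code (ATA = Met, TGA = Trp, AGA/AGG = Ser, giving an
8-codon serine family); the table id is a parameter on every relevant
function. Compact mitogenomes truncate some stop codons to `T` or `TA`
at the annotation boundary, completed by post-transcriptional
polyadenylation; `classify_start_stop()` reads these off the CDS length
mod 3 (1 → `T--`, 2 → `TA-`), and `extract_codons()` trims them — and
excludes complete stop codons — before any usage statistics, so RSCU is
always over sense codons. RSCU is the codon count divided by its
synonymous family's mean count; an unobserved family reports 0 for all
members (not `NaN`) so downstream tables and plots stay stable. Ranked
codon lists break ties alphabetically.

## Ka/Ks by Nei–Gojobori counting

`ng86()` implements the NG86 counting estimator with Jukes–Cantor
correction, the classic method behind the per-gene selection screens in
mitogenome papers. Synonymous *sites* per codon are the fractions of
single-nucleotide changes that are synonymous, with changes to stop
codons removed from the denominator; sites from the two sequences are
averaged. *Differences* between aligned codons are averaged over all
orderings of the differing positions; orderings that pass through a
stop codon are dropped and the average renormalized over the rest (if
every ordering is blocked — possible only for a few three-difference
pairs — the average falls back to all orderings, classifying
stop-crossing steps by their amino-acid change). Both proportions are
corrected with d = −(3/4)·ln(1 − (4/3)p); p ≥ 3/4 is reported as a
saturation flag, not a number. Identical sequences report Ka = Ks = 0
with an `identical` flag and an undefined ratio.

Per-gene panels (`kaks_panel()`) run all unordered species pairs and
take the unweighted mean of the *defined* pairwise values; saturated or
identical pairs are excluded from the mean rather than clamped, which
avoids biasing panels by arbitrary substitutes, and their count is
reported. Selection classes follow the Ka/Ks = 1 boundary.

All codon-level quantities are precomputed once per genetic code into
lookup tables, so panel computation is O(alignment length).

## Gene orders and breakpoint distance

A genome's gene order is a signed circular permutation. A circular
molecule has no distinguished origin or strand, so rotation and
whole-molecule reversal (reverse the list, flip every sign) are
quotiented out; both readings of a circle are at distance 0. The
breakpoint distance counts gene adjacencies of one order absent from
the other, in the standard gene-extremity encoding (each gene has a
tail and head; +g is traversed tail→head). This is a rearrangement
*proxy*: the NJ tree built from the pairwise distance matrix
(`nj_order_tree()`, negative branches clamped to zero) is an explicit
stand-in for rearrangement-count tree searches, and is labelled as such
in the report manifest. Exact inversion-distance or DCJ median solving
is out of scope.

`describe_events()` decomposes a query order into maximal runs of genes
consecutive in the reference, read in either direction, requiring a
uniform strand relation within a run (all signs agreeing with the
reference, or all flipped) so a lone strand-flipped gene becomes its
own block. A block is *inverted* when it reads the reference backwards
(or, for sign-only flips, when its strand disagrees) and *translocated*
when its query neighbours are not its reference neighbours. On the
packaged whitefly order against the shipped ancestral insect
arrangement this labels the nad3–trnG–cox3 cluster
`inverted+translocated` — the hallmark whitefly rearrangement — and
reports trnS1 as missing.

The shipped reference (`ancestral_insect_order()`) is the conserved
Drosophila-type insect arrangement, which is also the arrangement of
the most conserved whitefly mitogenomes. Leucine tRNA naming follows
the whitefly-table convention used throughout the package (trnL1 =
L(UUR) between cox1 and cox2; trnL2 = L(CUN) next to rrnL). Any
reference can be supplied through the one-line gene-order text format.

## Control-region dissection

Three detectors feed a tiling step:

* `find_tandem_repeats()` is a deliberately simple seed-and-extend
  finder, not a reimplementation of any external tool's scoring: a
  self-match at lag p sustained over `min(p, 10)` positions seeds an
  array; the first p bases become the consensus; further copies are
  accepted while the best-length edit-distance alignment of the
  consensus (copy lengths p ± `max_indels_per_copy`, default 6) reaches
  `min_identity` (default 0.8, which tolerates a 6 bp deletion in a
  38 bp unit, per-copy identity 32/38 ≈ 0.84). Homopolymer-consensus
  hits are discarded — a poly-T run is trivially periodic at every lag
  and belongs to `find_homopolymers()`. Overlapping candidates are
  resolved longest-first, ties leftmost then smallest period; a
  leftmost-first rule was rejected because a short accidental hit
  starting one base earlier could shadow a long genuine array.
* `find_hairpins()` scans every arm placement with the loop length in
  range, pairing by Watson–Crick plus G·U (flag, default on, since
  mitogenome secondary structures treat G·U as pairing), and reports
  only maximal stems: not extendable outward (one more flanking pair)
  nor inward (consuming two loop bases) within the mismatch budget.
  The default budget is 0: with a nonzero budget the maximality rule
  walks perfect stems into flanking chance pairs (in A+T-rich sequence
  a random position pairs with probability ≈ 0.4 when G·U counts), so
  exact spans are only recovered at budget 0. The budget remains a
  user knob for degenerate real stems.
* `find_homopolymers()` reports maximal single-base runs above a
  length threshold (default 15 in the one-call wrapper, long enough
  that A+T-rich background never triggers it).

`partition_cr()` tiles the CR with the accepted hits under the
precedence repeat-array > stem-loop > poly-T (lower-precedence hits
overlapping an accepted one are dropped) and classifies every remaining
interval by its G+C fraction: above `gc_threshold` (default 0.35,
against a whole-mitogenome background near 0.29) it is `gc-elevated`,
otherwise `spacer`. Segments tile the sequence exactly; the invariant
is enforced. Note that a "low A+T" intervening region between repeat
arrays (G+C ≈ 0.44 in the whitefly CR description) is classified
`gc-elevated` by this rule, like the long G+C-39% block — both are
elevated relative to the genomic background, and the label records
that fact rather than a positional role.

## The synthetic-data generator

`generate_mitogenome()` exists so that every stage can be tested
against planted truth without downloads. The default spec *is* the
whitefly architecture: the 36 genes of the packaged table in their
published order, strands and sizes; coding-strand composition
A 31.0 / T 39.8 / G 16.8 / C 12.4 percent; the invertebrate code; and a
CR built from the published five-part plan (293 bp G+C-0.39 block,
69 bp poly-T, 44 bp stem-loop as 20 bp arms around a 4 nt loop inside a
63 bp segment, two 128 bp repeat copies, a 94 bp G+C-0.44 spacer, three
38 bp repeat copies with a 6 bp deletion in the third). Genes are laid
head-to-tail, so the synthetic genome is about 15.1 kb; junction
spacers are not emulated.

Composition targets are honoured almost exactly rather than in
expectation: unconstrained regions are seeded permutations of
fixed-count base pools, and PCG codons are drawn with deterministic
largest-remainder counts from a codon distribution calibrated by
iterative proportional fitting so that its base marginal equals the
target (plain products of base frequencies would miss the target after
excluding stop codons). Targets apply to the coding strand;
reverse-strand genes are inserted as reverse complements, which
produces genome-level strand asymmetry exactly as mixed-strand layouts
do in real mitogenomes — so whole-genome skew equals the coding-strand
target only for single-strand specs, and the tests check it that way.
Boundary bases adjacent to planted CR elements are constrained (no T
against a poly-T run, no duplicate of a repeat unit's last base before
the array, non-pairing bases flanking hairpin arms) so that planted
elements are exactly maximal and detector recovery is well-defined.

`evolve_cds()` plants substitution ground truth by event counting, not
rate-matrix simulation: proposals are uniform over sites and
alternative bases, stops are rejected, synonymous changes accepted with
relative probability 1 and nonsynonymous with omega, until the target
number of substitutions is realized. The realized synonymous and
nonsynonymous event counts are returned, so recovery tests compare an
estimator against exact planted truth. What the generator does *not*
emulate: indels, rate heterogeneity across sites, transition/
transversion bias, tRNA/rRNA secondary structure, and real
junction-spacer structure — passing recovery tests therefore
demonstrates estimator correctness under the model's own assumptions,
not robustness to every feature of real data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale by design:
omega recovery uses 10,000-codon sequences at 0.1 substitutions per
codon (sampling error on the Ka/Ks ratio ≈ 5–7%, comfortably inside
the 15% recovery band), oracle comparisons use 1,000 random codon
pairs, hairpin-scanner/oracle equality uses sequences up to 200 nt,
and gene-order metric properties use random signed circular orders of
up to 10 genes. Floating-point invariants (site conservation,
RSCU family sums) hold to 1e−9 or exactly; reporting precision
follows the field (percentages to 0.1, skews to 0.001).

## Worked example

```{r example}
ann <- whitefly_annotation()
glance(summarize_junctions(ann, "declared"))
strand_census(ann)$by_category
validate_annotation(ann)$size_mismatches
```

```{r kaks}
set.seed(1)
anc <- paste(sample(sense_codons(), 2000, replace = TRUE), collapse = "")
derived <- evolve_cds(anc, omega = 0.2, expected_subs_per_codon = 0.1,
                      seed = 2)
glance(ng86(anc, derived$cds))
```

```{r cr}
g <- generate_mitogenome(mitogenome_spec(seed = 42))
cr <- extract_feature_seq(g$sequence, g$annotation)[["CR"]]
tidy(dissect_control_region(cr))
```

## Known limitations

* The GenBank reader covers the flat-file subset mitogenome records
  use (single-interval and origin-spanning locations, /gene and /note
  qualifiers); arbitrary multi-interval joins are rejected explicitly.
* The repeat finder is seed-and-extend with per-copy edit-distance
  identity; it is not a reimplementation of alignment-weighted tools
  and will differ from them on low-identity arrays.
* Breakpoint distance under-counts multi-gene rearrangement events by
  design (each event changes at most two adjacencies); the NJ tree on
  those distances is a stand-in, not a rearrangement-scenario search.
* Ka/Ks estimation is counting-based (NG86); no maximum-likelihood
  codon models.
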