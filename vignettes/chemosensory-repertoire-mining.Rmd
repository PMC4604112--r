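---
title: "Mining chemosensory receptor repertoires: models, rules and design choices"
author: "chemorep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining chemosensory receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemorep)
```

# The problem

Chemosensory perception in mammals rests on a handful of GPCR gene
families — olfactory receptors (ORs), trace amine-associated receptors
(TAARs), vomeronasal receptors (V1R/V2R), taste receptors
(TAS1R/TAS2R) — plus single-copy partners such as the gustducin
α-subunit gene *GNAT3*. Comparative questions about these families
("has this lineage lost functional bitter taste?") reduce to a
repertoire census over a draft assembly: how many family members are
present, and is each one an intact gene, a pseudogene, or merely cut off
by a scaffold boundary? `chemorep` implements that census as a pipeline
of explicit, individually tested rules.

# The search model

The translated search is classic seed-and-extend. Each scaffold is
translated in all six frames; exact protein 4-mers shared with a query
become seeds; seeds are clustered by diagonal bands; every seed of a
cluster undergoes ungapped X-drop extension (a cluster survives if any
member extends to score ≥ 25 — a single spurious off-diagonal seed must
not sink a genuine cluster); surviving clusters define windows in which a
full affine-gap Smith–Waterman alignment is computed, iterated with
masking so several genes inside one window are each reported. Raw scores
convert to e-values through Karlin–Altschul statistics
`E = K·m·n·exp(−λS)` with `m` the total translated residues searched and
`n` the total query residues. Because the window always covers the whole
seed cluster plus a 64-residue margin, the reported raw score equals the
unwindowed full-matrix score in practice; the test suite asserts exact
equality against an independent dynamic-programming oracle on 200 random
instances.

Two cutoffs matter and are deliberately familiar: `1e-20` for the large
olfactory families and `1e-5` for taste genes, the conventional screening
thresholds for this kind of census. Both are per-family configurable.
Search statistics use the published gapped defaults (BLOSUM62 with gap
open 11 / extend 1, λ = 0.267, K = 0.041; nucleotide match +1 /
mismatch −2, λ = 1.28, K = 0.46); the historical searches behind these
analyses did not record word sizes or gap penalties, so defaults are
assumed and recorded here. A 12-column tabular adapter
(`read_tabular_hits()`) lets a production search engine stand in for the
internal one without changing any downstream contract.

# Gene calling rules

A candidate locus (merged overlapping same-orientation hits — one locus
is one gene; fragments that never overlap are counted per locus) is
reconstructed against a *family profile*: a curated reference alignment
with annotated TM1..TM7 column ranges. The locus window, extended up to
500 bp on each side (codon-wise, clipped at scaffold ends), is aligned to
the profile consensus by a frameshift-aware protein-to-DNA dynamic
program: a consensus residue may consume 1–5 nucleotides, with penalties
(12 for ±1 nt, 15 for ±2 nt) chosen so that a genuine frameshift is
cheaper than abandoning the downstream alignment but dearer than an
ordinary in-frame gap. The traceback directly yields premature stop
codons (a stop aligned to a consensus column), frameshifting indels
(non-3-nt codons), and per-TM coverage.

The label rules, in order:

1. **pseudogene** if any premature stop, frameshifting indel, or
   completely missing TM segment;
2. **truncated** if the start and/or stop codon is missing *and* the
   locus lies within 1,000 bp of a scaffold end or an N-run ≥ 100 bp
   (truncation is a property of fragmented assemblies, not of genes);
3. **pseudogene** if the start/stop is missing with intact flanking
   sequence (an unfindable terminus in good sequence is itself a
   disruption — a deliberate design decision, since truncation is only
   meaningful as an assembly artifact);
4. **intact** otherwise.

Two numerical subtleties deserve record. First, *"completely missing
TM"* is judged on the segment interior (segment minus two boundary
columns, with at most two covered residues tolerated overall): a deletion
gap exactly the size of a TM segment can slide one or two alignment
columns when flank and segment residues happen to tie, and a
high-scoring single-residue anchor inside a long gap (e.g. a chance
tryptophan match, which outscores the extra gap-open cost) is alignment
noise, not evidence the segment exists. Isolated single-residue anchors
are likewise ignored for coverage. Second, a start codon is only sought
upstream when the alignment actually reached the consensus N-terminus
(within 5 columns); otherwise a chance background ATG would rescue
genuinely decayed 5′ ends.

TM segments are defined as annotated column ranges on the profile —
the decision that makes "lacks a TM region completely" a testable
condition rather than a judgment call.

# Multi-exon audits

Exon presence/absence uses the nucleotide search per exon plus a
reciprocal check against the source locus. A missing exon is *deleted*
when the target distance between the nearest found flanks is smaller
than the reference distance minus half the missing exon length(s) and no
N-run intervenes; an N-run gives *assembly_gap*; a missing flank gives
*unresolved*. (The 0.5 tolerance makes the call conservative: an exon
whose sequence merely diverged beyond recognition, with its genomic
region intact, is not reported deleted.) Inversions are reported for
runs of two or more consecutive exons on the minority strand whose order
along the target is reversed; a single opposite-strand exon is
orientation-indeterminate and never reported.

Dot plots use a deliberately simple cell statistic: the best chained
exact 12-mer run between two mesh windows, converted to percent identity
over the chain span, with the span floored at 50 bp so an isolated
12-mer reads as weak signal rather than 100%. Both orientations are
scored, so inversions appear as anti-diagonal signal. The statistic
underestimates identity for diverged homologs (exact 12-mers thin out
quickly) — it is a synteny visual, not an aligner.

Disruption annotation in reference coordinates aligns each target
globally to a reference CDS (1-based positions along the reference,
codons read from position 1) and reports deletions, insertions and
stop-gains; events present in *every* member of a named group at
identical coordinates are summarized as shared events — the exact-position
convention matches how shared pseudogenizing mutations are conventionally
presented. Note that a 1-bp deletion inside a homopolymer has no unique
alignment placement; positions are reported at the leftmost-parsimonious
column, which is also how the printed positions of such shared mutations
should be read. The in-silico PCR worked example pairs with this: the
published exon-6 primer pair (one R = A/G degeneracy, matched at zero
cost against its expansion set) amplifies a 299-bp primer-inclusive
product on a template carrying the two sites at that spacing.

# Phylogenetic classification

Class I/class II assignment is distance-based: Poisson-corrected
distances (`d = −ln(1 − p)` on shared ungapped columns, capped at
p = 0.95) feed neighbor joining, which is exact on additive matrices —
the suite round-trips 100 random trees. The tree method itself is a
design choice: NJ is deterministic and entirely adequate for a two-class
split that is deep and clean in mammals; no claim is made of matching
any particular published topology, and bootstrap support is out of
scope. For classification the edge holding the midpoint of the longest
inter-class path plays the root; the query's smallest clade containing a
reference decides (`method = "clade"`), falling back to the nearest
labeled leaf by patristic distance, ties broken toward class II (the
overwhelmingly larger class) with a warning. The rooting is performed on
the unrooted tree by reading clades away from the midpoint edge —
resolving a root trifurcation arbitrarily can group the query with the
wrong side, a failure mode the tests cover explicitly.

Truncated genes are placed *one by one*: each fragment is threaded onto
the reference alignment through its best-matching reference row (not a
pooled consensus, which for two deep classes is a chimera that misleads
fragments), distances are computed on the fragment's covered columns
only, and assignments are provably independent of processing order.

Pairwise dN/dS follows the Nei–Gojobori pathway method: synonymous site
fractions per codon (mutations to stop codons count as nonsynonymous),
differences averaged over all mutational pathways that avoid stops
(over all pathways when every one is blocked), Jukes–Cantor correction,
ω undefined at dS = 0. A 9-codon hand-counted oracle is frozen in the
tests. This is a stand-in for whatever selection test accompanied the
original analyses — only the qualitative claim (ω < 1 under purifying
selection, calibrated by simulation) is made, and the large-sample test
on dN − dS is labeled approximate.

# The synthetic world

The generator states the world the pipeline is tested against, and its
defaults are fixed, not tuned: per family, 10 intact, 5 pseudogenized
and 2 truncated genes at 0.1 substitutions/site from a 310-residue
7-TM ancestor (typical chemosensory GPCR length; 0.1 gives ~82% mean
pairwise identity, comfortably within-family), on eight 30-kb scaffolds
with four 300-bp N-runs, uniform i.i.d. intergenic background, and
genes spaced ≥ 1.5 kb apart. Pseudogenes carry exactly one disruptive
mutation (40% premature stop, 30% 1-bp frameshift, 10% 2-bp frameshift,
20% whole-TM deletion), so truth labels map 1:1 to detected disruption
kinds. Truncation is modeled only by scaffold splitting — its stated
cause. What the generator does *not* emulate: repeats, GC structure,
indel evolution within intact genes, tandem arrays closer than the
spacing, and sequencing error. A green planted-truth test therefore
establishes that the rules fire correctly on clean signals of each kind,
not that the pipeline is robust to repeat-rich real assemblies.

Identical specs and seeds give byte-identical genomes and truth tables;
every planted element is recoverable from the truth table by slicing the
genome at its coordinates.

# Degenerate inputs and tie-breaks

Queries shorter than the seed are skipped with a warning, not an error.
Loci with no reciprocal hit at all are discarded with the reason
recorded. Cross-family locus overlaps go to the family with the higher
best bit score, logged. Equal bit-score ties in the reciprocal filter
are resolved permissively (kept if any tied top hit is in-family).
Saturated protein distances are capped with a warning; pairs sharing
fewer than 30 columns are an error naming the pair. IUPAC codes other
than N in assemblies are mapped to N with a warning rather than
rejected. Internal coordinates are 0-based half-open throughout; every
written report (GFF3, TSV) is 1-based inclusive.

# Known limitations

- The search engine is a compact reimplementation: no composition-based
  statistics, no low-complexity filtering (the historical searches were
  run unfiltered anyway), single-threaded semantics.
- The dot-plot statistic saturates downward for diverged homologs.
- dN/dS is pairwise and approximate; no codon-model selection tests.
- The deletion-confirmation rule is numeric where the historical
  confirmation was visual; the 0.5 tolerance is a judgment the tests
  pin down but real loci near the boundary deserve a dot plot.
- Fragmented pseudogenes whose hit fragments never overlap are counted
  per locus, not per ancestral gene; with very decayed families the
  census therefore leans high.
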