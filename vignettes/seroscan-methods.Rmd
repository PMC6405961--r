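---
title: "Seroin classification and modular annotation: methods"
author: "seroscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seroin classification and modular annotation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

Seroins are small secreted proteins of the lepidopteran silk gland — the
third kind of silk protein besides the fibroins that form the filament and
the sericins that glue it. Silk-gland transcriptomes typically contain
several seroin cDNAs per species: products of up to three paralogous genes
(classes Sn1, Sn2 and Sn3, never more than two genes per class per
species) further diversified by alternative splicing. A nascent seroin is
built from modules: a signal peptide of about 20 residues (module A),
conserved blocks rich in Ala, Ser, Glu and Asp that also carry most of the
charged residues (B modules, numbered B1–B3), and shorter, diversified,
mostly Pro-rich linkers (C modules, C1–C2). The long isoform carries the
full set AB1C1B2C2B3; shorter splice versions drop or truncate modules in
class-specific ways.

`seroscan` turns the descriptive criteria used to sort these proteins by
eye in alignments into an explicit, reproducible pipeline: rule-based
class assignment, compositional module segmentation, splice-version
calling, gene grouping, systematic nomenclature, within/between-class
similarity summaries with a neighbor-joining sanity tree, and
class-specific read counting under Karlin–Altschul E-value statistics.
Because the original sequence collections live in public archives, the
package ships a ground-truthed synthetic seroin generator, so every stage
is exercisable — and testable — without downloads.

## Classification rules

Each class signature is a small set of clauses evaluated on the protein,
counted from the initial Met at position 0:

* **Sn1** — a Trp in the window [15, 25) ("about 20 residues after the
  initial Met"); a charged fraction (D, E, K, R; His excluded by
  convention) of at least 0.25 within ±10 residues of that Trp; and a
  downstream 30-residue window (starting within 45 residues after the
  Trp) with Pro fraction ≥ 0.20 — the "distinct Pro-rich region that
  follows". Three clauses of weight 1.
* **Sn2** — the exact motif RYGG anywhere (weight 2) and a Gly fraction of
  at least 0.20 over residues [20, 50) (weight 1).
* **Sn3** — a Trp in [30, 40) (weight 1) and the exact motif VYGE
  (weight 2).

"About 20" and "about 35" are rendered as symmetric ±5 windows. Motifs get
double weight because they are the sharpest single pieces of evidence
reported for these classes. A class score is the weighted fraction of
satisfied clauses; the argmax is called when it reaches `min_score = 0.5`
and leads the runner-up by `min_margin = 0.15`, otherwise the protein is
*unclassified* — an outcome the original, manually curated analysis never
needed, but which any automatic rule system must define. Ties are always
unclassified. Clauses referring to positions beyond a short protein's end
simply evaluate false rather than erroring.

Motif matching is exact string matching; the unknown residue X never
matches anything, including another X.

## Signal peptide and module segmentation

Module A is located hydrophobically: Kyte–Doolittle means over 8-residue
windows are scanned within residues 1–28; the end of module A is the end
of the last window with mean hydropathy above 1.5, plus 3 residues,
clamped to [15, 30]. If no window qualifies, the conventional length 20 is
used and flagged.

The mature region is segmented by composition alone. A 15-residue sliding
window (clipped at the ends) yields a per-position Pro fraction; positions
at or above `pro_threshold = 0.20` are provisionally C, the rest B. A
7-residue majority filter removes speckle, runs shorter than 5 residues
are merged into their longer neighbour, and surviving runs are numbered
positionally (first B run = B1, first C run = C1, ...). If more than 3 B
or 2 C runs remain, the shortest internal run is absorbed until the counts
fit. Degenerate inputs (an all-Pro or Pro-free mature region) legitimately
produce a single module.

Numerical choices worth stating plainly:

* The window/threshold pair (15, 0.20) sets a resolution limit: a B module
  much shorter than ~15 residues flanked by Pro-rich linkers cannot be
  resolved, and detected C-module boundaries are systematically displaced
  ~3 residues outward into the neighbouring B runs (the window crosses the
  threshold while it still overlaps the linker). Version calling corrects
  measured lengths for this known smear (+3 per B/C boundary for B runs,
  −3 for C runs) rather than pretending the boundaries are exact.
* Module completeness is judged by length: a module whose (smear-corrected)
  length falls below half the class-default length for its canonical slot
  is marked incomplete. The test is applied to *every* module, not only
  terminal ones, because the Sn2 terminal splice versions are defined by
  incomplete *internal* modules.
* Class-default module lengths are the midpoints of the generator's
  class-specific ranges (see below); they are the package's
  operationalization of the qualitative size statements ("B1 of Sn1 is
  short", "a large B3 of over 90 residues", ...).

## Splice-version calling

Versions are defined relative to the long isoform: L (full set), N
(AB1C1B2, Sn1), C (AB1C2B3, Sn1 and Sn2), T1 (AB1C1[B2C2]B3, Sn2,
brackets = incomplete), T2 (A[B1C1]B2C2B3, Sn2) and T (AB1C1B3, Sn3).
Segmentation labels runs positionally, so calling a version is a small
combinatorial matching problem: observed B runs are mapped in order onto a
pattern's B slots (likewise C runs), and each candidate pattern is scored
as presence mismatches (1 each) plus completeness mismatches (0.5 each),
with the summed relative deviation of measured lengths from the pattern's
expected module sizes — complete modules only, weight 0.05, capped — as a
deterministic tie-break. The tie-break is what separates, for example, an
Sn1 N version (whose single C run is a long C1) from an Sn1 C version
(whose single C run is a short C2): both match their pattern's module-type
sequence exactly, and only the sizes differ. The best pattern supplies the
canonical relabelling (e.g. the second B run of an Sn1 C version becomes
B3); if the best pattern's cost exceeds 1 the version is *unrecognized*.

## Gene grouping and nomenclature

Proteins of one species and class are grouped into genes under the
rationale that isoforms of one gene share their N-terminus: two records
link when their first 25 mature residues are identical *and* identity over
the both-aligned (non-gap) region of a global alignment reaches 0.95;
single-linkage closure gives the groups, capped at two genes (observed
maximum per class and species), numbered by descending size then smallest
member id. A species whose two genes share identical 5' ends — resolvable
only with genomic sequence — defaults to one gene; a `genomic_split`
argument lets the user impose the split, recorded as genomic evidence.
Known limitation: a short C-terminal isoform whose B1 is shorter than the
25-residue prefix cannot satisfy the N-terminal identity rule and will
split from its sibling isoforms; this mirrors the genuine ambiguity that
motivated the genomic-evidence escape hatch.

Names follow the grammar
`<abbrev> "Sn" <class> ["-" gene] [letter [minor]]`: species abbreviation
(genus initial + first epithet letter, extended letter by letter on
collision — *Helicoverpa assulta* becomes Has only because *H. armigera*
already holds Ha), a hyphenated gene number only in two-gene species,
capital splice-version letters, and minor-variant digits starting at 2.
Splice letters are assigned per gene in order of the lexicographically
smallest member id of each version — a deterministic stand-in for the
unstated ordering convention (likely discovery order) of the source
material; a gene represented by a single record carries no letter. The
typographic en-dash occasionally found in print is normalized to the ASCII
hyphen on parsing, and `parse_name()` is the exact inverse of
`build_name()` over the whole grammar.

## Similarity and the sanity tree

Percent identity between two proteins is matches divided by *all* columns
of an optimal global alignment, gap columns included (BLOSUM62, gap open
10, extend 1, deterministic traceback preferring substitutions over gaps).
This is the conservative denominator; published within-class (31–50%) and
between-class (22.5–25%) similarity ranges were computed from a multiple
alignment with an unstated metric, so the package treats the comparison as
a qualitative ordering — within above between — not a number to reproduce.
The alignment kernel is an affine-gap Gotoh implementation in C++, checked
exactly against an independent implementation in the test suite.

Trees are built by Saitou–Nei neighbor joining on d = 1 − identity/100
(via `ape::nj`); negative branch lengths are clamped to zero with the
deficit moved to the sibling so path lengths are preserved. NJ is exact on
additive distances, which the tests exploit by inverting random trees. The
tree is a *sanity check* that the three classes fall into three deep
clades — it does not replace model-based phylogenetics, which is out of
scope here. Monophyly of a class is tested in unrooted semantics: the tree
is rooted at a leaf outside the class and the class's leaves are checked
for forming a clade.

## Read counting and E-value statistics

The expression protocol mirrors a translated search: each read is
translated in six frames, each frame is aligned to every class query (the
80 C-terminal residues of a class reference; shorter references are used
whole and flagged) by affine-gap Smith–Waterman, and the best hit's
E-value is `E = K·m·n·exp(−λS)` with m the query length and n the
translated read length of the scoring frame — a per-read convention,
stated here because a library-wide n would need the original raw
libraries. A read is counted for the class of its unique best hit with
E ≤ 1e−20 (the standard reading of "e−20"); ties are left unassigned, and
class counts plus unassigned always sum to the total.

λ is the positive root of Σ pᵢpⱼ·exp(λ·sᵢⱼ) = 1, found by bisection to
1e−12 after validating that the expected score is negative and some score
is positive. K is computed numerically from renewal theory for the induced
integer-lattice random walk: the Cramér constant C of the walk's all-time
maximum is read off the ruin recursion u(y) = Σ p(x)·u(y−x), and
K = C·(1 − E[e^{λS_T}])·|μ|/|E[S_T]|, where S_T is the first
descending-ladder height and μ the mean step — the factor in parentheses
converts the all-time-maximum constant to a per-excursion constant and
|μ|/|E[S_T]| is the density of ladder epochs. This computation reproduces
the exact K = 1/3 for the +1/−1 uniform four-letter walk and the published
ungapped BLOSUM62 constants (λ = 0.3176, K = 0.134, H = 0.40 nats) to
three figures; both checks are frozen in the tests. Applying ungapped λ, K
to gapped local scores is the classic approximation; it errs on the
significant side, which for a fixed threshold means slightly permissive
E-values — immaterial here because planted 150-nt reads score around
E ≈ 1e−30 and random reads around E ≈ 1e−3, leaving ten orders of
magnitude of margin on either side of the threshold. The default
background is the standard Robinson–Robinson amino-acid frequency set.

## The synthetic generator: what it emulates, and what it does not

The generator is the package's study-condition definition, not a test
fixture. Each synthetic gene is a full module set drawn once per
(species, class): module A is Met + a hydrophobic core + polar tail
(18–22 residues); B modules are drawn from class-specific
Ala/Ser/Glu/Asp-rich compositions (Gly-rich for Sn2 B1) and carry short
fixed class-conserved anchor blocks at module starts — the generator's
stand-in for the conserved blocks that make real B modules recognizable
across species; C modules are Pro-rich (Pro 0.50–0.55, "very Pro-rich"
for Sn1 C1) with Pro planted at their edges. The class-diagnostic features
are planted deterministically: Sn1's Trp at position A+1 inside a charged
anchor, Sn2's RYGG near the start of B1 with a guaranteed Gly fraction
≥ 0.25 over residues [20, 50), Sn3's Trp at position 34 followed by VYGE.
Splice versions reuse the gene's modules and drop or prefix-truncate them
(incomplete modules at 35% of full length, floored at 16 residues for B
modules so they stay above the segmentation window's resolution, 8 for C
modules); mature length is capped at 250 residues. Module length ranges
per class transcribe the qualitative size statements: e.g. Sn1 B1 12–18,
C1 28–38, B2 46–58, C2 9–14, B3 52–68; Sn2 B1 34–46 (Gly-rich), C1 9–14,
B2 30–44, C2 27–32, B3 90–108; Sn3 B1 38–42, C1 10–20, a central B2C2 of
about 140 residues present only in the long version, B3 55–62.

cDNAs are back-translations with uniform synonymous codon choice, a
single stop, and random UTRs constrained so that the planted ORF is the
unambiguous longest one (the 5' UTR is ATG-free, and codon sampling is
retried in the rare case a chance reverse-strand ORF outruns a short
coding region). Reads are sampled uniformly within a transcript, strand
random, transcript chosen proportional to an abundance weight, with
independent substitution errors.

What the generator does **not** emulate — and therefore what passing
tests do and do not show about real data: there are no indels or
sequencing-quality artefacts, no realistic codon usage, no 5'-truncated
cDNAs; module boundaries are compositionally crisp where real ones are
"not sharply defined"; conservation is concentrated in short anchors
rather than spread diffusely; and background compositions exclude Trp
outside the planted diagnostics, whereas a real proteome supplies chance
Trp residues that would occasionally put the Sn1 rules in play. Perfect
recovery on this generator demonstrates that the rules and the generator
agree and that the machinery is correct and deterministic; accuracy on
real transcriptomes will be lower and should be judged against curated
alignments.

Sequences with no ATG-initiated ORF (e.g. 5'-incomplete cDNAs) are
reported as "no ORF" rather than guessed — the source material does not
state how such inputs were handled, and refusing to guess is the
reproducible choice.

## Problem sizes and runtime

The reference conditions used by the test suite and the acceptance script
are: 300 records (100 per class, every splice version represented,
noise-free, seed 42); 1,000 planted error-free reads of 150 nt from the
C-terminal coding regions of one species' three class references plus
1,000 random reads; 100 random alignment pairs and 1,000 motif-scan
strings against brute-force oracles; 50 random additive 8-leaf trees. The
full suite runs in well under a minute on one CPU; the 300 × 300 identity
matrix (~45,000 global alignments) takes a few seconds through the C++
kernel.
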