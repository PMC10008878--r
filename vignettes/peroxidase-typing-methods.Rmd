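---
title: "Methods: targeted recovery and typing of class II (AA2) peroxidases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted recovery and typing of class II (AA2) peroxidases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Secreted fungal class II peroxidases (CAZy auxiliary activity family AA2)
drive lignin depolymerization by white-rot Agaricomycetes. Three functional
types are distinguished by two structural features of the enzyme: a surface
tryptophan that oxidizes non-phenolic lignin directly, and an acidic
Mn(II)-binding site that oxidizes Mn²⁺ to Mn³⁺. Lignin peroxidases (LiP)
carry the tryptophan, manganese peroxidases (MnP) carry the Mn site,
versatile peroxidases (VP) carry both, and generic peroxidases (GP) carry
neither. On the coordinate system of the *Phanerochaete chrysosporium*
lignin peroxidase isozyme H8 used as the ancestral reference, these features
reduce to four residues: the Mn-binding acidic triad **E37, E41, D183** and
the surface tryptophan **W171**.

`peroxtyper` implements a desk-scale, fully testable pipeline for surveying
these genes in environmental amplicon data: degenerate primers designed on
conserved regions, nested in-silico PCR, read filtering, 97% identity OTU
clustering, translation and alignment of each OTU centroid to the ancestral
reference, catalytic residue calling, and rule-based typing into
MnP / VP / LiP / rest-AA2 / non-AA2, aggregated into stratified abundance
tables with Shannon diversity.

# The typing rules and their totalization

The core decision procedure follows the field's residue logic:

1. **No credible family relationship** — best-frame alignment to the
   ancestral reference below the significance floor *and* nearest-panel
   identity below the panel floor (default 0.6): `non-AA2`.
2. **Insufficient evidence** — fewer than 2 of the 4 framework positions
   covered by the alignment: `rest-AA2`, flagged `low-coverage`.
3. **W171 detected** — `VP` when the Mn site is also evidenced (D183
   detected, or both E37 and E41 detected, or the nearest reference gene is
   an *mnp*, the identity-based tie-break); otherwise `LiP`.
4. **W171 not detected** — `MnP` when at least two of {E37, E41, D183} are
   detected; otherwise `rest-AA2`.

The residue rules alone are not a total function (e.g. a fragment covering
no framework position, or W171 with exactly one Mn residue). The precedence
above totalizes them while preserving each stated rule; inconclusive but
alignable sequences are routed to `rest-AA2` rather than discarded. A
residue found within ±1 column of its canonical position counts as
*detected* but is reported `shifted` with its signed offset and flagged
(`shifted-Trp` for the tryptophan): such enzymes are known to exist and may
have reduced activity, so the label is kept while the evidence is surfaced.
Ties between equally-near shifted candidates prefer the downstream column,
matching the documented downstream-tryptophan case.

# Alignment model

Each amplicon is translated in all six frames and aligned locally
(BLOSUM62, gap opening 10, extension 0.5) against the ancestral protein;
the top-scoring frame wins, with ties broken in frame order +1, +2, +3,
−1, −2, −3. Internal stop codons set a flag but never reject an amplicon —
genomic amplicons may span introns, and the local alignment simply skips
poorly coding stretches.

**Significance floor (default score 100).** Every PCR product necessarily
carries the conserved primer footprints, which align to the ancestral
reference but carry no information about family membership. Calibrating the
floor on plain random DNA (99th percentile ≈ 48 at 500 nt) would therefore
pass essentially every amplified off-target. `calibrate_score_floor()`
instead embeds in-frame back-translations of the primer motifs into random
sequences — the hardest realistic negatives — giving a 99th percentile of
≈ 88; the default of 100 adds margin while staying far below the scores of
genuine family fragments (several hundred even for short, diverged
amplicons). Residue positions outside the aligned span are reported
`uncovered` rather than absent.

**Nearest reference.** Phylogenetic placement is replaced by
nearest-reference assignment: the query protein is aligned end-to-end
against each panel protein (query global, reference locally trimmed, since
amplicons are gene fragments) and the best identity wins, ties to the
earlier panel record. This supplies the *mnp*-tie-break evidence in rule 3
and the identity component of rule 1; it does not build trees.

# Clustering and its identity definition

Reads are dereplicated exactly and clustered greedily in abundance order
(count desc, then length desc, then lexicographic): each unique joins the
earliest-created centroid with identity ≥ 0.97, otherwise founds an OTU.

Identity is computed on an **ends-free (overlap) global alignment**:
internal gaps count against identity, terminal overhangs do not. This choice
matters. Reads in this assay are 3'-length-trimmed (the observed product
range spans 200–568 nt), so two error-free reads of the same gene routinely
differ by >3% in length; penalizing terminal gaps would shatter every gene
into length-stratified OTUs, which is neither the intent of a 97% criterion
nor the behaviour of standard amplicon clusterers. Both denominators —
alignment columns of the overlapping region (default) and shorter-sequence
length — are implemented and configurable, because the choice measurably
shifts OTU counts. The aligner is a small banded dynamic program in C++
(band 24 nt by default, i.e. up to 24 nt of cumulative indel drift, ample
for amplicon reads); Biostrings' general-purpose aligner is used as an
independent cross-check in the tests but is too slow for the ~10⁵ pairwise
alignments a full run needs.

# Choosing what to type: candidates and consensus

Typing an OTU by its greedy centroid alone is fragile under 3' length
trimming: the most abundant unique of a gene is occasionally a truncated
prefix whose alignment cannot reach W171 or D183, and the one error-free
full-length read may occur just once. Each OTU therefore carries a small
set of *typing candidates* — its positional consensus, its three most
abundant uniques and its longest unique — and `classify_otus()` keeps the
candidate whose alignment covers the most framework residues (ties broken
by alignment score, then candidate order). The consensus is a weighted
modal base per position over the OTU's uniques: because reads are
3'-trimmed prefixes of their molecule, ungapped positional voting aligns
them exactly, indel-bearing reads contribute only outvoted noise downstream
of their first indel, and the consensus reconstructs the full-length
error-free sequence whenever at least `max(2, 5%)` of the OTU's reads still
cover a position. Shallow OTUs simply fall back to their reads.

# Read filtering

The stated rules are applied literally: 3' quality trimming at the first
position where a 4-base sliding-window mean drops below Q25 (the window rule
is our documented interpretation of "Q25 trimming"; the window is truncated
at the read end), then removal of reads shorter than 150 nt (boundary
inclusive: 150 nt is kept) or containing any ambiguous base.

# What the synthetic community emulates — and what it does not

`synthesize_reference_panel()` builds the whole study fixture from one seed:

* a 250-aa ancestral protein with E37/E41/W171/D183 planted and four
  conserved 8-aa motifs (two nested forward, two nested reverse) from which
  the primers are designed by back-translation (motif alphabet restricted to
  ≤3-codon amino acids, keeping degeneracy ≤ 64 per primer, well under the
  4096 cap);
* ten AA2 members (4 MnP, 3 VP, 2 LiP, 1 GP) derived from the ancestor by
  8% amino-acid substitution outside motifs and framework (regenerated if
  any pair falls under 5% divergence) with framework residues set by type,
  then back-translated with independent random synonymous codons — so
  members diverge strongly at the nucleotide level while every degenerate
  primer still matches exactly;
* one bacterial-style non-haem off-target: random DNA carrying concrete
  primer binding sites at nested spacings but out of frame, so it amplifies
  (as real off-targets did, in quantity) yet encodes nothing resembling the
  family.

The read simulator draws members by weight (equal by default, an equimolar
pool of 11), forms 1% two-parent chimeras at a uniform breakpoint, applies
0.5% substitutions and 0.1% indels per base, trims to a uniform 200–568 nt
length, and emits constant Q38 qualities (or an optional 3'-decay profile to
exercise the trimmer). Defaults are the validation conditions used
throughout the tests: 11,000 reads, seed-controlled.

What this does **not** model: platform-specific error profiles (homopolymer
errors, quality-correlated miscalls), PCR amplification bias between
members, introns in genomic amplicons, multi-parent chimeras, and the true
taxonomic breadth of a soil community. Passing tests therefore demonstrate
the correctness and internal consistency of each stage and the
recoverability of a defined control — not field performance on real soil
libraries, whose dominant failure modes (primer bias, unknown diversity)
are outside any simulator's reach.

# Numerical and design choices

* **Coordinates** are 1-based inclusive throughout, on the plus strand of
  the template as supplied; residue numbering is relative to whatever
  ancestral sequence the user provides (mature vs pre-protein numbering is
  a curation decision, not a package one).
* **Primer annealing** is Hamming-only (no indels), max 2 mismatches,
  zero in the 3'-terminal 3 nt; product bounds default to 200–600 nt.
  All convergent, bounded site pairs become products — no shortest-product
  heuristic; downstream filtering decides.
* **Primer design** reports degeneracy as the product of per-position IUPAC
  expansion sizes and fails above 4096; the IUPAC expansion covers every
  codon of the motif (it may cover more for split codon boxes, e.g. serine,
  which is the standard cost of single-string degenerate design).
* **Greedy order and ties** are fully documented (abundance, length,
  lexicographic; centroid creation order for assignment), which makes
  clustering permutation-stable — a property the tests assert.
* **Degenerate inputs**: empty read sets, empty panels, all-zero counts and
  missing stage outputs raise structured errors naming the offender; empty
  FASTA/FASTQ files are valid and round-trip.
* **Problem sizes** used in the validation suite: 11,000-read communities
  for end-to-end checks, 30-unique × 100-seed clustering oracle
  comparisons, 50 × 2 kb templates for the PCR oracle; chosen so the whole
  suite documents the method's behaviour at realistic desk scale.

# Known limitations

* Typing rests on per-OTU candidates and consensus; at very low depth
  (a handful of reads per gene) no candidate may cover the full framework
  and the OTU degrades to `rest-AA2` with the `low-coverage` flag rather
  than a confident type.
* Nearest-reference assignment is only as good as the panel; it reports
  identity so users can gate on it.
* The score floor is calibrated for amplicon-length queries against a
  ~250-aa reference; markedly different designs should re-run
  `calibrate_score_floor()`.
* The bundled community description, sample sheet and stratified report
  exist to exercise the reporting conventions (depth layers `b` and `c`
  merged to `b,c`, columns closed to 100%); they are not field data.
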