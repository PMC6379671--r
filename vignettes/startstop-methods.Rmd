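---
title: "Methods: simulating functionally scarless hierarchical DNA assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating functionally scarless hierarchical DNA assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startstop)
```

## The model

`startstop` simulates Golden-Gate-type one-pot restriction–ligation in which
type IIS endonucleases cut outside their asymmetric recognition sites, leaving
short 5' single-stranded protrusions ("fusion sites") that direct the order of
ligation. The package's distinctive subject is the *functionally scarless*
variant of this chemistry: at Level 1, expression units are assembled from
promoter, UTR/RBS, CDS and terminator parts using five 3 bp fusion sites —
alpha (CAG), beta (CCA, placed at the transcription start), gamma (ATG) and
delta (TAA), which are the start and stop codons themselves, and epsilon
(GGA) — so that no foreign sequence is introduced at the scar-sensitive CDS
boundaries. SapI (GCTCTTC, cutting 1/4) supplies the 3 nt overhangs; BsaI
(GGTCTC, 1/5) and BbsI (GAAGAC, 2/6) supply 4 nt overhangs for storage cloning
and the higher assembly levels. The enzyme geometries live in one editable
table (`type_iis_enzymes()`); only the overhang lengths are intrinsic to the
design, the offsets follow the standard enzyme reference.

Digestion is modelled as *complete and simultaneous*: every recognition site
on either strand is cut, each cut severing the top strand at the enzyme's top
offset and the bottom strand at its bottom offset. The bookkeeping convention
is that a fragment's top strand includes its left (top-strand) protrusion and
excludes the bases of its right junction, which belong to the downstream
fragment. Two consequences are used as invariants throughout the test suite:
top-strand lengths are conserved by digestion, and a circular ligation
product's length is the sum of its fragments' top strands with every junction
counted exactly once.

A one-pot reaction is modelled combinatorially, not kinetically. All reagents
are digested with the single active enzyme; fragments become nodes of a
directed graph with an edge wherever a right end's protrusion is the reverse
complement of a left end's protrusion; the simple directed cycles of that
graph are the possible circular products. The terminal-product argument of
one-pot assembly is captured exactly by the *stability dichotomy*: a product
that retains at least one recognition site of the active enzyme (every
re-ligated donor, and every circle containing a stuffer or donor backbone) is
re-cut and classified `relig_donor` or `background`; a product free of such
sites is terminal, and is `intended` when it contains the destination backbone
and one payload per insert position in design order, `misassembly` otherwise.
Relative yields, ligation kinetics, blunt or mismatched ligation, partial
digestion, methylation and star activity are out of scope.

### Orientation and copy bounds

Enumeration keeps every fragment in the orientation produced by digestion and
uses each fragment at most once per circle (one backbone, one copy of each
insert). Re-entry of a fragment in flipped orientation would require a
palindromic overhang or a reverse-complement collision between two junctions —
exactly the situations the fidelity audit (`audit_overhang_set()`,
`fidelity_report()`) flags before assembly, which is why the audit rather than
the enumerator owns them. Concatemers beyond the copy bound are likewise
excluded; the bound keeps enumeration finite and matches the stoichiometric
intent of the 2:1 insert:vector ratio in the bench recipe.

### Fidelity audit semantics

The audit brute-forces all ordered pairs of an overhang set, including each
sequence against every reverse complement. `pass` means no duplicates, no
palindromes and no reverse-complement collisions — the conditions under which
annealing is unambiguous. Near-collisions at a configurable Hamming threshold
(default 1 in `fidelity_report()`) are reported but advisory: the Level 1 set
itself contains alpha = CAG at distance 1 from the reverse complement of
gamma = ATG, an unavoidable consequence of recruiting natural start/stop
codons as fusion sites, and one the wet chemistry tolerates.

## The hierarchy and the planner

Level 0 stores parts in a single vector (pStA0) behind BsaI sites with F/R
storage fusion sites; Level 1 assembles four parts per expression unit with
SapI; Level 2 collects up to five units with BsaI via donor sites A, B, C, D,
E, Z; Level 3 collects up to three Level 2 blocks with BbsI via sites 1–4.
The streamlined feature is the *Z vector*: the last unit of every Level 2
group is assembled in an alternative Level 1 vector whose right donor site is
Z, so every Level 2 assembly lands in the same A/Z acceptor pair and a single
destination vector per organism or context suffices
(`choose_level1_vectors()`).

`plan_assembly()` turns a 1–15-unit design into the full reaction series.
Designs of up to five units default to one Level 2 destination reaction.
Larger designs (or an explicit `destination_level = 3`) are partitioned into
at most three Level 2 groups of at most five units. The default grouping rule
is: **an operon always forms its own Level 2 group**, and runs of
monocistronic units between operons are chunked greedily to five; only if
this exceeds three groups are adjacent atoms merged greedily as a fallback.
The rationale is that an operon is a transcriptional unit the designer chose
deliberately, whereas padding it with an unrelated monocistronic unit to fill
a group is a silent design change; the rule also reproduces both shipped
hybrid library routings — the 4-operon + 1-mono design as groups (4,1) into
pStA313 and the 8-unit hybrid as (4,1,3) into pStA314 — without special
cases. Users who prefer denser packing can regroup explicitly.

Operon configurations substitute 12 bp spacer linkers for internal promoters
and terminators. The published spacer sequences are supplementary-only, so
`make_spacer_linkers()` draws them from a seeded constrained sampler: no
SapI/BsaI/BbsI site on either strand including across the fusion-site
junctions, no ATG on the top strand between a promoter-side linker's alpha
and beta (no spurious start ahead of the RBS), and pairwise Hamming distance
of at least 4 — the package's operationalization of "orthogonal", documented
and adjustable rather than inherited from the original spacer-design service.

Bench recipes (`make_recipe()`) default to 20 fmol destination vector, 40
fmol per insert, 400 U T4 DNA ligase, 10 U endonuclease in 20 µl, cycled
30 × (37 °C 5 min / 16 °C 5 min) with a final 65 °C 20 min step; every field
is overridable.

## Combinatorial libraries

A mixture at a promoter/RBS/terminator slot is one combinatorial position
with k options; the design space is the exact product over positions
(`design_space_size()`), rendered both as an exact integer and in
3-significant-figure scientific notation. Sampling (`sample_variants()`) is
uniform and independent per position — the equimolar-mixture premise — with
optional per-option weights for biased mixtures. Expected coverage under n
transformant clones uses the standard occupancy expectation
S·(1 − (1 − 1/S)^n), evaluated with `log1p` for stability at large S; each
transformation is treated as the only bottleneck, i.e. pooling of
intermediates between levels is modelled as perfect. This is a deliberate
simplification: real hierarchical pooling can bottleneck diversity at every
level, so the coverage numbers are upper bounds.

## The synthetic fixture generator

`generate_fixtures()` emulates the experimental reagent sets so the whole
toolkit is testable offline: six promoters, six RBSs, four terminators, eight
carotenoid-pathway CDS analogues (plus an eyfp reporter analogue) as random
sense-codon strings of 300–1500 nt beginning ATG and ending TAA, 16 spacers,
and concrete sequences for all 15 core vectors. Vector sequences realize the
cassette grammar faithfully — acceptor fusion sites with outward-facing
recognition sites inside a lacZα-placeholder stuffer, donor sites with
inward-facing recognition outside them, T0/T1 terminator placeholders
insulating the cassette, marker and replicon placeholder segments of
realistic lengths — but everything outside the cassette is random neutral
sequence. Sequence counts and formats mirror the experimental sets; promoter
strength, RBS strength, expression, colony phenotypes and real vector
sequence identity are *not* emulated. A green test therefore establishes the
correctness of design, digestion, ligation-order, routing and arithmetic
logic — not any biological activity, and not nucleotide-level agreement with
the deposited plasmids. The F = GCAA / R = TGGC storage sites and the
prefix/suffix grammar (1 nt SapI spacers, default A) are documented synthetic
stand-ins for the same reason.

All randomness flows from a single seed through named substreams (part
specs, raw sequences, vectors, spacers), so each component regenerates
byte-identically and independently.

## Numerical and representational choices

- Coordinates are 0-based half-open throughout; circular arithmetic is
  modular.
- Circular products are reported in canonical rotation (lexicographically
  smallest top-strand rotation), making product comparison a string equality.
- Cut windows that would fall off a linear molecule are skipped with a
  warning; a circular molecule with no sites passes through flagged `uncut`.
- Violations (part validation, destination validation) are data — tibbles
  with machine-readable codes — never exceptions; hard failures (alphabet
  errors, capacity bounds, missing junctions) are classed conditions.
- The NO_PRODUCT diagnostic walks the expected junction chain from the
  backbone and names the first gap by its fusion-site labels.
- CDS validation checks only what the part format defines: start/stop
  codons, forbidden internal recognition sites, and a frame-length warning.
  Internal ATGs or in-frame stops are not policed, and the convention that
  beta sits at the TSS is documented, not enforced (it is not computable
  from sequence alone).

## Known limitations

Ligation yield, transformation efficiency and chromosomal background DNA are
not modelled, so clone-count-based fidelity statistics cannot be reproduced
at the desk; the test suite replaces them with exhaustive combinatorial
checks (brute-force product enumeration on small pools, end-to-end
string-construction oracles for 15-unit builds, stability dichotomy and
length conservation on every enumerated product). Codon optimization and
automatic removal of forbidden sites from natural sequences are out of
scope: offending sites are reported with positions, and fixing them is the
designer's task.
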