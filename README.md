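# startstop

Design, validation and simulation of **functionally scarless Golden-Gate-type
DNA assembly** ("start–stop assembly") for metabolic engineering.

Modular type IIS assembly methods (Golden Gate, MoClo and relatives) are
efficient and combinatorial but leave fixed *scar* sequences at part
junctions — worst of all at coding-sequence boundaries, where a scar sits in
the transcript and perturbs mRNA structure and ribosome binding. The method
this package models removes that constraint by making the start and stop
codons themselves the fusion sites: expression units are assembled from
promoter, UTR/RBS, CDS and terminator parts through five 3 bp junctions

> alpha = `CAG`, beta = `CCA` (at the TSS), gamma = `ATG` (start codon),
> delta = `TAA` (stop codon), epsilon = `GGA`

cut by SapI (3 nt overhangs), then assembled hierarchically: up to 5 units
per Level 2 construct (BsaI, 4 bp sites `A GGAG, B AATG, C AGGT, D GCTT,
E CGCT, Z TACT`) and up to 3 Level 2 blocks per Level 3 construct (BbsI,
sites `1 TGCC, 2 ACTA, 3 TTAC, 4 CGAG`) — 15 genes from 60 parts. A "Z
vector" swap at Level 1 pins every Level 2 assembly to the same A/Z
acceptors, so one destination vector per organism suffices.

The package is for construct and pathway designers who want to check an
assembly **before touching a pipette**: it validates parts and vectors,
simulates every one-pot reaction combinatorially (which circles can form,
which are terminal, which are misassemblies), plans the whole hierarchy with
correct vector choices and bench recipes, and does the design-space
arithmetic for combinatorial libraries, where n positions with six-part
mixtures give a space of size 6^n and expected coverage of n clones follows
the occupancy formula S·(1 − (1 − 1/S)^n).

## What's inside

- **Sequence core** — strict ACGT sequences (`dna()`), type IIS enzyme
  geometry as data, site scanning on both strands of linear and circular
  molecules, complete-digest simulation into cohesive-ended fragments, and
  the annealing rule for 5' protrusions.
- **Parts** — the fusion-site registry (`fusion_sites()`), overhang fidelity
  audit, part validation with machine-readable violation codes,
  domestication into the Level 0 storage format with PCR primer tails, and
  seeded 12 bp spacer linkers for operon configurations.
- **Vectors** — the 15 core vectors as templates (`core_vectors()`), a
  synthetic-sequence generator realizing them as annotated circular
  molecules, and validation of user destination backbones.
- **Assembler** — one-pot product enumeration on the fragment ligation
  graph, stability and classification (intended / misassembly / re-ligated
  donor / background), junction-gap diagnostics, storage-cloning simulation.
- **Planner** — 1–15 units, monocistronic/operon/hybrid, Z-vector
  substitution, Level 2/3 routing, recipes, and in-silico execution of the
  full plan.
- **Combinatorics** — exact library sizes, coverage estimates, seeded
  sampling of concrete variants.
- **Workbench** — a deterministic fixture generator (parts, spacers, all 15
  vectors), FASTA/GenBank/JSON I/O, and a small CLI
  (`inst/cli/startstop`).

## Worked example

```r
library(startstop)

fx <- generate_fixtures(seed = 42)       # parts, spacers, all 15 vectors
design <- carotenoid_designs()$asta_hybrid   # 8 CDSs: 4-op + mono + 3-op

library_size_summary(design)
#> # A tibble: 1 × 4
#>   n_units n_positions      size size_scientific
#>     <int>       <int>     <dbl> <chr>
#> 1       8          11 362797056 3.63 x 10^8

plan <- plan_assembly(design)
plan
#> <stst_plan> 8 unit(s) in 3 group(s): 8 Level 1, 3 Level 2, 1 Level 3
#> reaction(s); 22 Level 0 part position(s); final product: L3 (pStA314)

tidy(plan)[11:12, c("reaction_id", "vector", "insert_summary")]
#>   reaction_id vector  insert_summary
#> 1 L2_g3       pStA234 L1_u06 + L1_u07 + L1_u08
#> 2 L3          pStA314 L2_g1 + L2_g2 + L2_g3

variant <- sample_variants(design, 1, seed = 1)[[1]]
sim <- simulate_plan(plan_assembly(variant), fx)
sim
#> <stst_simulation> 12 reaction(s) executed; final product L3: 9299 bp circular

expected_coverage(design_space_size(design), 2e4)
#> # A tibble: 1 × 4
#>   space_size draws expected_distinct coverage_fraction
#>        <dbl> <dbl>             <dbl>             <dbl>
#> 1  362797056 20000            19999.         0.0000551
```

The design space of the 8-unit hybrid library is 6^11 = 3.63 × 10^8 because
it has eleven six-part mixture positions (3 promoters + 8 RBSs); 20,000
transformants cover a vanishing fraction of it — the library is a sample of
the space, not an enumeration. The 12 simulated reactions are the 8 Level 1
unit assemblies, 3 Level 2 group assemblies (groups of 4, 1 and 3 units into
pStA212/pStA223/pStA234) and the final Level 3 collection in pStA314; the
9,299 bp product is the one stable, backbone-containing circle of the last
pot, annotated with the provenance of every fragment and all 8 CDSs.

Bench-ready recipes print the standard one-pot protocol:

```r
make_recipe("SapI", n_inserts = 4)
#> One-pot restriction-ligation (SapI)
#>   20 fmol destination vector plasmid DNA
#>   40 fmol of each insert (4 insert position(s); insert:vector molar ratio 2:1)
#>   ...
#> Thermocycle: 30 two-step cycles of 37 C for 5 min then 16 C for 5 min,
#> then 65 C for 20 min.
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates the fixture set from the given seed, prints the exact design
spaces of the six shipped library configurations, then plans and simulates
one sampled variant of each (checking that every final product is terminal
for its destination enzyme) and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Notes

Vector sequences, the F/R storage sites, the prefix/suffix grammar and the
spacer set are documented **synthetic stand-ins** (the deposited sequences
are not bundled); users can load real vectors from GenBank files and validate
them with `validate_destination()`. See the methods vignette
(`vignettes/startstop-methods.Rmd`) for the model, its assumptions and its
limitations.
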