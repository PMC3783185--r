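---
title: "Mapping a long-distance intronic RNA structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a long-distance intronic RNA structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldiscan)
```

## The problem

Human *SMN2* predominantly skips exon 7, the molecular lesion behind spinal
muscular atrophy. A cytosine at the 10th position of intron 7 (written
^10^C) engages in a long-distance interaction (LDI) with a sequence
element nearly 300 nt downstream, forming an internal stem (ISTL1) that
sequesters the 5' splice site region and suppresses exon 7 inclusion.
`ldiscan` implements the computational chain by which such an element is
localized and characterized:

1. **Deletion-scan core mapping** — overlapping deletion minigenes scored by
   whether an inhibitory antisense oligonucleotide (L14) retains or loses
   its effect; the core is the intersection-style consensus of the
   abrogating windows.
2. **Helix modeling** — the LDI duplex as an explicit pair table, with
   greedy contiguous extension under point mutations and a bounded
   complementarity scanner in place of free-energy folding.
3. **SHAPE reactivity** — quantification, normalization and classification
   of 1M7 primer-extension band intensities, differential profiles, and
   reverse-transcriptase falloff handling.
4. **ASO effect rules** — direction-only predictions (stimulatory /
   inhibitory / neutral) for (minigene variant, ASO) pairs from sequestration
   geometry and whether the duplex can form.
5. **A seeded synthetic-data generator** standing in for gels and minigene
   assays, so the whole chain is testable without experimental data.

## Coordinates and the reference sequence

Intron positions are signed integers with no zero: +1 is the first intronic
nucleotide and -1 the last exonic one, matching the field's mutant
nomenclature (`Δ281-300` deletes exactly 20 nt, both ends inclusive; `289G`
substitutes G at position 289). `linIndex()` maps this line onto contiguous
integers so spans are plain arithmetic.

No deposited accession exists for the probed construct, so the package
ships a **synthetic reconstruction** (`smn2IntronReference()`): 467
residues, the last 23 exonic positions plus the 444-nt intron. The probing
substrate in the source experiments was built from the exon 7 3' end plus
the full intron; we realize the stated 467-nt length as 23 exonic + 444
intronic residues. Residues fixed by published information:

* intron 1-24 (`GUAAGUCUGC CAGCAUUAUG AAAG`), carrying the 5' splice site
  region and ISS-N1 (positions 10-24);
* the TSL3 stem (pairs 17-25 : 41-33, including the 19U:39G wobble and the
  loop-closing 25U);
* the ISTL2 and ISTL3 strand geometry (5' strands 51-57 and 59-65 paired
  with 289-283 and 281-275);
* positions 282-300: the upstream `GCAGAC` copy (282-287), 288A-289A, LS-1
  (`GCAGAC`, 290-295), 296-297 UU completing the ISTL1 3' strand, and the
  U-rich tract beginning at 296;
* the exon tail ending `...AAGGA` (so -1 is A).

Everything else — the Module 1/2/3 interiors and other unprinted stretches
— is seeded filler, deliberately free of G residues in the 261-274 and
301-330 neighbourhoods so that no spurious complementarity to the
C-anchored query region is introduced where scan deletions shift sequence
around. Conclusions that depend on filler content are therefore out of
scope; every packaged analysis depends only on the constrained positions.

## Core mapping

A scanned position belongs to the core iff it is covered by at least one
tested deletion and **every** covering deletion abrogated the response.
Uncovered positions are never claimed. "To a lesser extent" responses are
three-valued (`partial`) and resolved by an explicit `ScanPolicy`
(`partial_as = "retained"` by default; the 10-nt scan analysis resolves its
partial window as abrogating, which is how the published 15-nt core arises).
Exact recovery of a planted core from a noise-free simulated scan requires
flush evidence — some window ending at `core_start - 1` and another starting
at `core_end + 1` — which the published scan designs provide; otherwise the
inferred interval can overshoot by up to one window width (tested as a
bracketing property).

```{r core}
inferCoreRegion(fig3bDeletionScan(), ref = smn2IntronReference())
```

## Helix modeling

`buildWtIstl1()` anchors the 8-pair wild-type stem (3-10 : 297-290; 16
residues, innermost pair 10:290, enclosing 279 nt). `extendHelix()` applies
a variant, lifts the anchor into mutant coordinates, and grows the stem one
pair at a time at both ends while residues pair canonically; bulges are not
crossed — an interrupted stem is a separate helix, which is exactly the
logic by which the 11:289 mismatch blocks growth until mutated:

```{r helix}
ref <- smn2IntronReference()
wt <- buildWtIstl1(ref)
sapply(c("289G", "288U", "288U/289G", "286G/288U/289G/298A"), function(v)
  helixLength(extendHelix(ref, wt, parseVariantLabel(v),
                          basePairRule(FALSE))))
```

`basePairRule(allow_wobble = TRUE)` is the default (the probed structure
contains a wobble pair), but all ISTL1 arithmetic reported by the package
uses Watson-Crick pairs only; the wild-type stem is all-WC, so the flag is
irrelevant there, and for the quadruple mutant wobble merely adds pairs
beyond the 13-bp Watson-Crick count, which is treated as a lower bound.

`findLdiDuplexes()` is a bounded, exhaustive complementarity scanner over
two disjoint regions, returning maximal contiguous antiparallel duplexes
ranked by pair count and then summed pair-class strength (GC > AU > GU),
with a deterministic positional tie-break. It deliberately replaces
free-energy folding: the decisions the pipeline makes need only duplex
existence, length and composition, and an exhaustive scanner is exactly
testable against a brute-force oracle.

### When does the duplex "form"?

The effect rules need a predicate: can the ^10^C-anchored duplex form in a
given variant? `istl1Forms()` scans the variant sequence for a contiguous
Watson-Crick duplex of at least 6 pairs that pairs position 10, between the
intron 5' end (wild-type -4..14) and the lifted image of the scanned
neighbourhood (wild-type 261..320). Three choices here are load-bearing:

* **Competing-structure masking.** An identical `GCAGAC` copy sits at
  282-287, yet its deletion does not release the interaction while deletion
  of LS-1 does. The mechanistic reading is that the upstream copy is
  already base-paired inside ISTL2's 3' strand (283-289). Accordingly,
  search positions held inside other helices of the model that survive the
  variant intact are unavailable for pairing. This single rule reproduces
  the asymmetry between the two motif copies and the full deletion-scan
  response pattern.
* **Watson-Crick only.** With wobble pairing, a G substitution at 292 would
  retain a 6-bp duplex through 8U:292G, contradicting its observed
  abrogation; the predicate therefore ignores wobble pairs.
* **A travelling search window.** The window is the variant-lifted image of
  positions 261-320, so upstream deletions that merely shift the element
  (including removal of all three independently folding modules) leave the
  predicate true, as observed.

The 6-bp threshold is the smallest count consistent with the scans: single
substitutions inside the 6-nt LS-1 leave at most a 5-bp remnant, while
substitutions flanking it leave at least 6 contiguous pairs.

## SHAPE reactivity

Per position, `raw = max(0, I_1M7 - I_DMSO)` (negative differences are
clamped; negative reactivity is physically meaningless) and values are
normalized per extension primer to the most reactive position. Classes:
high above 0.5, moderate in [0.3, 0.5] (ties at 0.5 are moderate — the
stated band is inclusive), low below 0.3. Normalization is per primer, so
merged multi-primer profiles are comparable class-wise only; at overlaps
the primer whose window center is nearest wins (a declared convention — the
source does not state its reconciliation rule) and conflicts are logged.

Reverse-transcriptase falloffs are stops present in the control lane as
well; `detectFalloff()` flags positions whose DMSO intensity exceeds 3x the
primer-window median (threshold configurable), and flagged positions are
excluded from protected counts and concordance. The differential margin
for protected/exposed calls is 0.15 normalized units by default — the
source gives no number; 0.15 separates the simulated paired/unpaired levels
cleanly while tolerating the default simulation noise, and it is exposed as
a parameter everywhere.

`structureConcordance()` scores a classified profile against a model:
paired positions should be low, unpaired moderate-or-high; the fraction of
consistent evaluable positions quantifies agreement (the 16-residue stem
with moderate calls at 3 and 293 scores 14/16).

## The synthetic-data generator

The probe simulator assigns ground-truth modification propensities from a
structure model: interior paired residues 0.05, helix-terminal and wobble
residues 0.35, unpaired residues 0.6 (defaults chosen to mirror the
qualitative probing pattern: protected stems, reactive loops, partial
reactivity at stem ends). "Terminal" means the outermost pair of each
helix plus wobble-paired residues; the innermost, loop-closing pair is held
by its enclosed loop and simulates as fully protected. Lane intensities are
`amplitude * p + background` (modified) vs `background` (control) with
multiplicative lognormal noise (`noise_cv = 0.2` default) and shared
falloff stops; everything is bit-reproducible under a seed. The model is a
per-position independent-stop model, not a sequential drop-off cascade:
the analysis consumes relative band intensities, so cumulative read-through
adds realism the pipeline would never see.

Two packaged scenarios mirror the published comparisons. The 5'-window
comparison of wild type against the quadruple mutant recovers protection of
exactly {-1, 1, 2, 3, 11, 12, 13, 14}; the mid-window comparison of the
mutant against its ASO-invaded form recovers exposure of 286-299 except
291, with the damped 291C emulated by a per-position propensity override
(`asoD291Override()`) — an observed chemistry effect injected into the
scenario, not derived from structure. Primer windows stop short of the
primer's annealing footprint (the mid-window ends at 299), which is why the
3'-side comparison does not extend to position 300.

The scan simulator plants a core and calls a window abrogated iff it
removes at least one core position, with optional independent call
flipping; recovery degrades monotonically (on average) with flip
probability, which the tests measure by Monte Carlo.

What passing these simulations does **not** show: real lanes have
sequence-dependent RT processivity, ladder misregistration and band
compression that the generator does not model, and real minigene responses
are graded, not three-valued. The generator validates the inference
machinery, not the chemistry.

## ASO effect rules

ISS-N1 is modeled as intron 10-24 (F14 covers 1-14 including ^10^C; L14
covers 11-24 excluding it); ISS-N2 as 275-297, the union of the three ISTL
3' strands. Rules fire in order: R1 — the ASO covers position 10 and
overlaps ISS-N1 (stimulatory); R2/R3 — the ASO overlaps ISS-N1 leaving 10
free, inhibitory iff the duplex forms; R4 — the ASO covers at least 80% of
an ISTL 3' strand (stimulatory); R5 — neutral. R4 is stated over all three
internal stems rather than ISTL1 alone because microwalk ASOs targeting
mostly the ISTL2/ISTL3 strands also stimulate inclusion, consistent with
the silencer being the composite ISS-N2 region. Only response direction is
predicted; baseline splicing of a variant (e.g. the inhibitory 10G single
mutant) is outside what the rules determine. Protein-site release (TIA1,
hnRNP A1/A2B1) is reported by `sequestration()` but carries no weight in
the calls, since the LDI effect persists under knockdown of those factors.

The transcribed response table (`paperSplicingResponses()`, 94 clear rows
across the 20/10/5-nt scans, the point scan, the compensatory series and
the F14 panels) is scored by `responseConcordance()`; the packaged rules
match every clear row, and the three graded rows ("to a lesser extent",
suppression-without-reversal) are listed as excluded rather than scored.

## Numerical and testing choices

* Degenerate inputs: an all-zero lane normalizes to zeros with a warning;
  an all-retained scan returns an empty core with a warning, not an error.
* Duplex ranking ties break on (query start, search start); rule firing is
  deterministic and the fired rule is always reported.
* Problem sizes: property tests run tens of randomized instances with
  regions up to ~120 nt and scans up to 500 positions under fixed seeds;
  the full suite completes in well under a minute on one CPU.
* Intervals are inclusive-inclusive and 1-based throughout; all I/O
  (FASTA `offset=` headers, TSV tables, CT/dot-bracket, JSON reports)
  documents and preserves the convention.

## Limitations

The scanner models contiguous duplexes only; coaxial stacking, tertiary
contacts and thermodynamics are out of scope, so relative stabilities
beyond pair-count/pair-class ordering are not predicted. The ISTL2/ISTL3
and TSL3 pair tables are schematic reconstructions (drawn-only in the
source), supplied as model inputs rather than derived. Exonic structure
(TSL2) is not modeled. The reference outside the constrained positions is
synthetic; analyses of real genomic sequence should supply their own FASTA
via the documented `offset=` header convention.
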