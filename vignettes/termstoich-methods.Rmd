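---
title: "Internal terminators and transcript stoichiometry: models and methods"
author: "termstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal terminators and transcript stoichiometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termstoich)
```

## The biological question

Bacterial ABC importers need their extracellular substrate-binding protein
(SBP) in large molar excess over the membrane translocator (TMD/NBD)
components, yet all of these genes typically sit in one operon under one
promoter. One way cells solve this is an *internal intrinsic terminator*: a
GC-rich RNA stem-loop followed by a U-rich tract, placed in the intergenic
region (IR) just downstream of the SBP gene. A tunable fraction of RNA
polymerases terminates there, so the upstream SBP transcript accumulates
while read-through into the translocator genes is throttled. The
termination efficiency (TE) of the element then *is* the transcript
stoichiometry knob.

This package implements the computational side of that analysis as a
pipeline of small, testable steps: survey cluster architecture, extract
IRs, fold each long IR to its minimum-free-energy (MFE) hairpin, classify
candidate terminators into four structural types, quantify TE from two
assay designs, and test positional enrichment. A synthetic-data generator
produces genomes and measurement tables with known ground truth so every
step has recovery tests.

## Cluster survey

Clusters are maximal runs of adjacent, same-strand genes with transporter
roles (SBP/TMD/NBD), not interrupted by an `other`-role gene and with
adjacent gaps of at most `max_intergene_gap = 300` bp. The chaining rule is
a deliberately conservative operon proxy: 300 bp comfortably exceeds every
within-cluster gap the survey model emulates (means 50-80 bp), while being
far below typical between-operon spacing. Runs need at least two genes and
one SBP; runs longer than 6 genes are not emitted (real importer clusters
have 2-5 genes). "Distance" between genes is the *exclusive* gap in bp —
abutting genes are 0 bp apart, overlaps are negative — because the
quantities of interest (24 bp, 106 bp in the worked examples) are lengths
of intergenic regions. An IR is "long", and worth folding, when its gap is
strictly greater than 50 bp.

All coordinates are 1-based inclusive (GFF3 convention) end to end; the
GenBank reader converts to the same. On the minus strand, transcriptional
order means descending coordinates and IR sequences are
reverse-complemented before the T-to-U transcription, so the whole survey
is strand-symmetric — a property test mirrors entire genomes and requires
identical output.

## The folding model

The MFE search uses an embedded nearest-neighbor thermodynamic model at
37 °C (`energy_params()`, version `nn37-turner2004-style-1.0`): Watson-
Crick and G·U wobble stacking free energies, hairpin-loop initiation for
loop sizes 3-30, bulge initiation for 1-6 nt, internal-loop initiation for
total sizes 2-6, and a +0.50 kcal/mol penalty for a terminal A-U/G-U
closing pair. Larger loops are extrapolated with the Jacobson-Stockmayer
form \(\Delta G(n) = \Delta G(n_{max}) + 1.75\,RT\ln(n/n_{max})\). The
model is deliberately reduced relative to full folding engines — no
terminal-mismatch or dangling-end terms, no special small-internal-loop
tables — so absolute energies differ somewhat from Mfold/ViennaRNA output.
Per-structure published energies are therefore treated as indicative, and
every quantitative gate in the pipeline (the −10 kcal/mol stem-loop
threshold, generator targets) is defined on this internal, self-consistent
scale.

The search space is the *single hairpin*: one terminal loop (≥ 3 nt),
helices interrupted only by bulges or internal loops of at most 6 nt per
side (observed terminator defects are 1-2 nt), at least 3 base pairs, no
multiloops or pseudoknots. Restricting to single hairpins matches the
biological objects and — crucially — keeps the space small enough that an
*exhaustive enumeration oracle* can verify the dynamic program exactly.

Three independent routes compute the same optimum:

1. `min_hairpin()` — bottom-up DP over closing pairs in C++, with a
   pair-count dimension for the minimum-stem constraint;
2. a depth-first exhaustive enumeration in C++ (test oracle);
3. `enumerate_hairpins()` — plain recursive enumeration in R for
   sequences ≤ 30 nt.

All arithmetic is done in integer hundredths of kcal/mol, so the routes
agree *bit-exactly* — equality in the oracle tests is `==`, not a
tolerance. Energy ties are broken toward the larger total stem, then the
5'-most outermost pair, making output identical across platforms. The test
suite checks route agreement on hundreds of random sequences (500 in the
acceptance suite, lengths 12-28 where the enumeration is exhaustive yet
fast) and recomputes every emitted structure's energy from its component
sum.

IRs are folded alone, without flanking gene sequence: the elements of
interest are intergenic, and folding context is an un-modeled uncertainty
either way; a `flank` extension was considered and rejected as a default
because no principled default exists. IRs containing N are excluded from
folding with a warning.

## Terminator typing

`extract_features()` locates the putative 3' U-rich window: if the stem
carries a small unpaired region (1-2 nt bulge/internal loop), the window
starts at the first 3'-arm base distal to it (the 3' strand of the helix
between defect and stem base); otherwise at the first unpaired base 3' of
the stem. The window is 8 nt, counts use its first 7 nt (the conserved
positions in the tail logo), both clipped at the IR end. When several
defects exist, the outermost small one anchors the window, because its 3'
strand is the last paired tract before the stem base.

`classify_type()` is a pinned cascade over crisp thresholds
(`classify_config()`):

1. consecutive-U run ≥ 5 → **Type I** (canonical poly(U) terminator);
2. no stem defect and ≥ 2 U in the window → **Type II** (U-rich but not
   poly(U) tail);
3. 1-2 nt defect, short (≤ 4 bp) *paired*, U-rich distal tract →
   **Type III**;
4. 1-2 nt defect with a long (≥ 5 bp) distal helix or low U content →
   **Type IV**;
5. otherwise **unclassified** — a first-class outcome, since genome scans
   produce hairpins outside the typology.

The published scheme is qualitative ("more than 5 U", "a 1 to 2 base
unpaired region", "longer paired region with a lower content of 3' U");
the numeric thresholds above are the smallest crisp rule set consistent
with every stated property, and they live in configuration, not code. The
III/IV split at 4 vs 5 bp and the "U-rich means ≥ 2 of 7" floor are the
two genuinely free constants. One documented speculation — that Type IV
elements' true U-tracts may sit at the stem bottom — is deliberately *not*
implemented; the cascade flags such stems as IV rather than guessing a
relocation.

The mutation operators reproduce the construct-design logic used to probe
these features: `mutate_delete_5arm()` (5' truncations that strip the
pairing partner of the U-tract), `mutate_stem()` (insert/delete G-C pairs
at the loop-proximal stem end, spanning the tested energy range), and
`mutate_pair_unpaired()` (convert the stem defect to Watson-Crick pairs —
an A opposite a gap gains a U partner — which must strictly lower the
refolded energy, and does, property-tested on generator fixtures).

## Termination efficiency

Northern route: with the upstream-gene probe, the monocistronic band is
the terminated product and the bicistronic band the read-through, so
\(TE = 100\,I_{mono}/(I_{mono}+I_{bi})\). This is scale-invariant (gel
exposure cancels) and complements read-through to exactly 100. Only
upstream-probe lanes are used (both transcript species carry that gene);
downstream-probe lanes serve consistency checks.

qPCR route: relative levels come from
\(E^{(Ct_{ref} - Ct_{target})}\) with configurable efficiency (default 2.0,
perfect doubling; no plate efficiencies are modeled). The mapping
\(TE = 100\,(1 - rel_{down}/rel_{up})\) is not written out in the source
material; it is the only mapping consistent with comparing qPCR-derived TE
against Northern TE on the same constructs, and it is flagged as such in
the documentation. Ratios above 1 (noise) clip to TE 0 with a `clipped`
flag, since a negative termination efficiency is not meaningful.

Replicates aggregate per construct as mean ± sample SD (n−1); single
replicates get SD 0 plus a flag. `correlate()` returns Pearson r, r², and
the least-squares line, and errors on n < 3 or zero variance rather than
returning an undefined coefficient.

## Enrichment statistics

`hypergeom_sf()` computes the exact upper tail by summing log-space
binomial coefficients — no normal approximation — and is verified against
full enumeration of all draws for every population size up to 12 (3091
cases). The positional test is one-sided: the claim under test is
*enrichment* of a feature on one side, so the tail is taken on the side
with the higher hit percentage. No multiple-testing correction is applied
(two tests are reported). With tied percentages the direction is `none`
and the smaller side is evaluated, which makes the result exactly
invariant under swapping the sides. Promoter calls are an input score
table thresholded at > 0.9 (strict); the promoter predictor itself is out
of scope.

## The synthetic-data generator

`gen_genome()` emulates the features of the study system that the pipeline
depends on: ~30 importer clusters per genome with the SBP mostly at the 5'
end (mix 0.70/0.03/0.27 for 5'/middle/3', matching the strong 5' skew of
the surveyed clusters), the SBP-TMD-TMD arrangement dominant, a bimodal
within-cluster gap distribution (uniform 0-20 bp for tightly linked pairs,
61-100 bp for separated SBPs), TMD-NBD pairs seamlessly linked, terminator
type frequencies proportional to the observed tallies (I/II/III/IV/none =
0.11/0.41/0.29/0.08/0.11), and folding energies around the observed
per-type means (−18 for I down to −28 for IV, within −38..−10). Background
GC is 0.35 (Clostridia-like); terminator flanks are AT-rich (GC 0.20), as
real intergenic context is, which also keeps the embedded element the MFE
structure of its IR. Spacers between clusters exceed the 300 bp chaining
gap so clusters never merge, and non-transporter genes are sprinkled
between clusters to exercise run interruption.

`gen_terminator()` builds type-specific templates (GC-rich stem; poly(U),
scattered-U, or defect-plus-distal-arm tails) and tunes stem length until
the *refolded* energy lands within ±2 kcal/mol of target, then rejection-
samples against the real fold + classify stack. The generator thus has no
parallel notion of "Type III": its ground truth is by construction
consistent with the pipeline's own definitions, so downstream recovery
failures isolate pipeline bugs, not generator drift. Template parameters
sit at least one unit away from every cascade boundary (e.g. Type I runs
are ≥ 6 U, Type III distal arms ≤ 3 bp).

Noise models are the simplest consistent with triplicate-SD reporting:
additive Gaussian on band intensities (sd 3 intensity units by default),
Gaussian on Ct values (sd 0.2 cycles). `gen_te_polyU_dataset()` draws
poly(U) lengths 0-8 and sets TE = 10 + 10·x + ε; the residual SD solves
\(r^2 = b^2 s_x^2/(b^2 s_x^2 + \sigma^2)\) for the target r², and the
residuals are centered, decorrelated from x and rescaled so the *sample*
r² equals the target exactly — calibration checks are then deterministic
properties, not coin flips. TE values are left unclipped to keep that
exactness; extreme draws may leave [0, 100] and are documented as
calibration data, not physical measurements.

What the generator does *not* emulate: codon structure or real promoter
motifs, RNA degradation kinetics (transcript-stability effects are
qualitative in the source analysis), BLAST-based role assignment (roles
are written directly into the annotation), and alternative secondary
structures competing with the designed terminator beyond what random
flanks produce. Passing recovery tests therefore demonstrates the
pipeline's internal correctness on realistic input shapes — not that the
genome-wide counts of any particular study are reproduced, which would
require the out-of-scope role-assignment and the exact Mfold
parameterization.

## Problem sizes and runtime choices

The shipped suites use sizes chosen to make the statistical checks sharp
while staying comfortably interactive: 500 random sequences (lengths
12-28) for fold-oracle equivalence, 200 generated terminators per type for
classifier recovery, 30-cluster genomes for survey round-trips, 1000
random records for the TE identities, n = 200 for the correlation
calibration, and the full N ≤ 12 grid (3091 cases) for the hypergeometric
oracle. The complete test suite runs in about two minutes on one CPU; the
acceptance script in well under one.

## Known limitations

* The energy scale is internally consistent but not Mfold-identical;
  per-structure energies should be compared within runs, not to published
  tables.
* Single-hairpin search only: an IR harboring two strong hairpins reports
  the better one; tandem elements are not resolved.
* G·U pairs are allowed in stems but dangling ends are ignored.
* GenBank parsing covers simple and `complement()` locations only.
* The qPCR→TE mapping assumes the upstream reporter level is the correct
  read-through denominator; polar effects beyond termination are not
  modeled.
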