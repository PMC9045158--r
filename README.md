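# termstoich

Internal intrinsic terminators and transcript stoichiometry in bacterial
ABC importer operons.

## The problem

ABC importer operons encode an extracellular substrate-binding protein
(SBP) together with its membrane translocator (TMD and NBD components),
yet the SBP is needed in large molar excess. One mechanism producing that
excess at the transcriptional level is an **internal intrinsic
(Rho-independent) terminator** — a GC-rich stem-loop followed by a U-rich
tract — sitting in the intergenic region (IR) downstream of the SBP gene.
A fraction of transcription events stops there; the rest read through into
the translocator genes. The termination efficiency (TE) of the element
sets the stoichiometric ratio of the flanking transcripts.

`termstoich` is an R package + analysis workflow for this system, aimed at
bacterial regulatory genomics: it surveys importer gene clusters and their
architecture, folds intergenic regions to find candidate stem-loops,
classifies them into four structural terminator types, quantifies TE from
Northern-blot and qPCR data, and tests positional enrichment — with a
synthetic-data generator providing ground-truth genomes and measurement
tables for recovery testing.

## The core quantities

* **Cluster survey.** Clusters are maximal runs of adjacent same-strand
  SBP/TMD/NBD genes (gap ≤ 300 bp, no intervening other gene), labelled by
  SBP position (5', middle, 3'). Gaps are exclusive bp; IRs with gap
  > 50 bp are "long" and are scanned for stem-loops.
* **Folding.** The MFE *single hairpin* of an IR under an embedded
  nearest-neighbor model (Turner-2004-style stacks, loop initiations,
  terminal A-U penalty, Jacobson–Stockmayer extrapolation); a stem-loop is
  called when ΔG < −10 kcal/mol. An exhaustive enumeration oracle verifies
  the dynamic program exactly (integer centi-kcal arithmetic).
* **Typing.** Type I: poly(U) run ≥ 5. Type II: defect-free stem with a
  U-rich (≥ 2 U / 7 nt) 3' tract. Type III: 1–2 nt stem defect with a
  short (≤ 4 bp) paired U-rich distal tract. Type IV: like III but a long
  (≥ 5 bp) distal helix or low U content.
* **Termination efficiency.**
  TE = 100 · I_mono / (I_mono + I_bi) from band intensities, and
  TE = 100 · (1 − rel_mcherry / rel_fbfp) from reference-normalized qPCR
  levels (ΔΔCt with configurable efficiency).
* **Enrichment.** Exact one-sided hypergeometric tail via log-space
  binomial coefficients, P(X ≥ k) over the pooled long-IR population.

## Worked example

```r
library(termstoich)

# simulate a genome with 30 importer clusters and embedded terminators
cfg <- synthetic_config(seed = 220314, n_clusters = 30)
gg  <- gen_genome(cfg, out_dir = "results/simulated")

# survey clusters and extract intergenic regions
bundle   <- read_annotation("results/simulated/genes.gff3",
                            "results/simulated/genome.fasta")
clusters <- find_importer_clusters(bundle)
irs      <- extract_all_intergenic_regions(clusters, bundle)

# fold long IRs and classify terminator candidates
scan  <- scan_ir_table(irs, dG_threshold = -10)
calls <- lapply(scan$structures, terminator_call)
table(vapply(calls, function(x) x$type_label, ""))

# one structure in detail
print(scan$structures[[1]])

# enrichment of stem-loops in 5'-SBP cluster IRs, from survey counts
enrichment_test(221, 85, 193, 20, "stemloop")
```

Running the pipeline on the simulated genome prints, for example:

```
30 clusters; 76 intergenic regions ( 23 longer than 50 bp)
Stem-loops below -10 kcal/mol: 21 of 23 long IRs
dG range: -32.5 .. -15.5 kcal/mol
stemloop: 5' 193/221 (87.3%) vs 3' 20/85 (23.5%); five_prime_enriched, P = 1.73e-26
```

i.e. the survey recovers every embedded cluster, most long IRs downstream
of SBPs carry a stem-loop below the −10 kcal/mol gate, and on the
published survey counts the stem-loops are overwhelmingly enriched in
5'-SBP clusters (87.3% vs 23.5% of long IRs; exact hypergeometric
P = 1.7 × 10⁻²⁶, far below the 10⁻⁴ headline threshold).

The numbered scripts under `analysis/` run the same steps as a narrative
workflow (`01_simulate.R` → `05_enrichment.R`), writing their tables under
`results/`.

## Layout

```
R/                  package code (survey, folding, typing, TE, stats,
                    synthetic data, pipeline orchestrator)
src/fold.cpp        DP folding engine + exhaustive DFS oracle (Rcpp)
analysis/           numbered workflow drivers (simulate ... enrichment)
scripts/acceptance.R headline-quantity reproduction (JSON out)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, assumptions, limitations)
```
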