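# fawstrain

Host-strain diagnostics for the fall armyworm, *Spodoptera frugiperda*.

The fall armyworm comprises two morphologically identical but genetically
distinct host strains — the corn (C) strain and the rice (R) strain — whose
identification matters for pest management, migration studies and
interstrain-hybridization research. Strains can only be told apart
molecularly. `fawstrain` implements a complete diagnostic toolkit around a
six-marker panel for field entomologists and molecular ecologists:

* **TaqMan genotype calling** — allele-specific qPCR calls from FAM/VIC
  quantification-cycle (Cq) tables. FAM reports the R-strain allele, VIC
  the C-strain allele; the replicate-averaged cycle gap ΔCq = |Cq_FAM −
  Cq_VIC| separates homozygotes (ΔCq ≥ 3, or a single fluorophore
  detected) from heterozygous hybrids (ΔCq ≤ 2).
* **Consensus strain assignment** — per-sample combination of the four SNP
  assays (SNP A–D) with the classical COI and Tpi PCR-RFLP markers:
  consensus requires ≥ 5 of 6 markers to agree, with a ≥ 2-marker hybrid
  fallback, maternal-inheritance and Z-linkage validity rules, per-assay
  accuracy and a chi-square homogeneity test.
* **In-silico PCR-RFLP** — IUPAC-aware amplicon prediction (degenerate
  primers supported) and MspI/SacI digestion implementing the reciprocal
  COI cutting rule and configurable Tpi polarity.
* **Diagnostic SNP discovery** — VCF filtering (biallelic SNPs, QUAL ≥ 30,
  complete calls at ≥ 3× depth, unplaced scaffolds dropped), per-site
  Weir & Cockerham (1984) F<sub>ST</sub> between strains, candidate
  ranking at F<sub>ST</sub> > 0.7, and 501-bp N-masked assay-design
  context sequences in `[C/R]` bracket notation.
* **Sensitivity analysis** — standard curves (Cq vs log10 ng), slope,
  intercept, R², amplification efficiency `10^(−1/slope) − 1` and limit of
  detection from serial-dilution data.
* **Synthetic data** — seeded generators for Cq plates, dilution series and
  two-strain population VCF/FASTA fixtures with known truth, so the whole
  workflow is testable offline.

The shipped marker panel (`builtin_assays()`) carries the primer/probe
sequences, strain alleles, chromosomal positions and calling thresholds of
all six markers, and can be overridden via a YAML configuration file.

## Worked example

Simulate a three-moth plate with known genotypes, call it, and combine with
RFLP results into a consensus:

```r
library(fawstrain)

truth <- expand.grid(sample_id = c("moth1", "moth2", "moth3"),
                     assay_id  = c("SNP A", "SNP B", "SNP C", "SNP D"),
                     stringsAsFactors = FALSE)
truth$genotype <- rep(c("CC", "RR", "H"), 4)   # C-strain, R-strain, hybrid

sim   <- simulate_cq_dataset(truth, seed = 101)
calls <- call_plate(sim$records)
calls[, c("sample_id", "assay_id", "call", "delta_cq", "flags")]
#>    sample_id assay_id call delta_cq              flags
#> 1      moth1    SNP A   CC   5.3985
#> 2      moth1    SNP B   CC  18.8891
#> 3      moth1    SNP C   CC       NA SINGLE_FLUOROPHORE
#> 4      moth1    SNP D   CC   5.6463
#> 5      moth2    SNP A   RR       NA SINGLE_FLUOROPHORE
#> 6      moth2    SNP B   RR  18.1608
#> 7      moth2    SNP C   RR  11.3080
#> 8      moth2    SNP D   RR   3.6477
#> 9      moth3    SNP A    H   1.1543
#> 10     moth3    SNP B    H   0.4978
#> 11     moth3    SNP C    H   0.6614
#> 12     moth3    SNP D    H   0.0436
```

Each row is one sample × assay reaction after replicate averaging. `CC`/
`RR` are strain homozygotes, `H` a heterozygous hybrid. The `delta_cq`
column shows the diagnostic cycle gap: large (> 3 cycles, here 3.6–18.9)
for homozygotes, small (≤ 2) for hybrids, and undefined where the
off-target probe never fired at all (`SINGLE_FLUOROPHORE` — itself a
homozygote signature: SNP A never fires VIC in R-strain moths, SNP C never
fires FAM in C-strain moths).

Merging with the two RFLP markers and forming a consensus:

```r
rflp <- data.frame(sample_id = rep(c("moth1", "moth2", "moth3"), 2),
                   assay_id  = rep(c("COI", "Tpi"), each = 3),
                   call      = c("C", "R", "R",   "C", "R", "H"))
long <- rbind(calls[, c("sample_id", "assay_id", "call")], rflp)
consensus_table(long)
#>   sample_id consensus n_agree n_markers
#> 1     moth1         C       6         6
#> 2     moth2         R       6         6
#> 3     moth3         H       5         6
```

moth3's COI marker reads `R` — mitochondria are maternally inherited, so
COI can never see a hybrid — but five of six markers agree on `H`, which
carries the consensus. `marker_accuracy()` on the same objects reports each
assay's agreement with the consensus (here 6/6 assays perfect except COI at
2/3, exactly the expected hybrid blind spot).

The same workflow is scriptable from a shell via the launcher in
`inst/cli/` (subcommands `simulate`, `call`, `consensus`, `rflp`,
`discover`, `context`, `sensitivity`; every run writes a `manifest.json`
with its parameters and seed).

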