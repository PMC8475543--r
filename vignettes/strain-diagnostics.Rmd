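---
title: "Fall armyworm host-strain diagnostics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall armyworm host-strain diagnostics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawstrain)
```

The fall armyworm (*Spodoptera frugiperda*) comprises two morphologically
identical host strains, the corn (C) and rice (R) strains, distinguishable
only by molecular markers. `fawstrain` implements the full diagnostic
workflow around a six-marker panel: four allele-specific TaqMan SNP assays
(SNP A-D), the classical mitochondrial COI PCR-RFLP and the Z-linked Tpi
PCR-RFLP, plus the upstream SNP-discovery machinery used to find such
diagnostic loci in a two-strain genotype matrix and the downstream
sensitivity analysis. This vignette documents the statistical models, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and known limitations.

## The TaqMan calling model

Each TaqMan reaction carries two hydrolysis probes: a FAM-labelled probe
matching the R-strain allele and a VIC-labelled probe matching the C-strain
allele. The instrument reports a quantification cycle (Cq) per fluorophore;
lower Cq means earlier amplification. Reactions are run in technical
duplicate and all calling happens on replicate-averaged Cq values:

* a fluorophore counts as **detected** only when it fired in *every*
  technical replicate; a single no-fluorescence (NF) replicate marks the
  channel not detected. On disk NF is encoded as Cq 0; in memory it is an
  explicit `NA` state so no arithmetic ever touches the sentinel.
* the **deltaCq** of a reaction is the absolute difference between the two
  replicate-averaged Cq values; the leading fluorophore is the earlier one.
  deltaCq is therefore non-negative by construction, invariant to constant
  Cq shifts, and undefined when only one channel fired.

Calls follow a small rule set with three tunable thresholds per assay
(`calling_thresholds()`):

| parameter        | default | units  | rationale                         |
|------------------|---------|--------|-----------------------------------|
| `het_max_delta`  | 2       | cycles | observed heterozygote deltaCq spans 0-2 cycles across all four assays |
| `homo_min_delta` | 3       | cycles | below the smallest homozygous assay lag (SNP D in R-strain, 3.67 minus two SD is about 3.1) |
| `max_valid_cq`   | 30      | cycles | reliability degrades above cycle 30 at low template; flags, never rejects |
| `max_cycles`     | 40      | cycles | length of the cycling program |

FAM-only detection calls `RR`, VIC-only `CC`, neither `INCONCLUSIVE` with a
`NO_SIGNAL` flag. With both channels detected, deltaCq at or below
`het_max_delta` calls a heterozygote (`H`), at or above `homo_min_delta` a
homozygote for the leading fluorophore's strain. The open interval between
the two thresholds is a deliberate dead band returning `INCONCLUSIVE`:
observed homozygote lags never approach 2 cycles and observed heterozygote
gaps never exceed 2, so a value in (2, 3) is more plausibly a QC problem
than a genotype, and forcing a call there would manufacture confidence the
data do not support. A leading Cq above `max_valid_cq` adds a
`LOW_TEMPLATE` flag rather than invalidating the call, since elevated Cq
only *potentially* reduces reliability. All thresholds are overridable per
assay through the YAML assay configuration
(`system.file("extdata", "assays.yaml", package = "fawstrain")`).

Per-replicate calling is intentionally not offered: the reference data for
these assays are replicate-averaged, and averaging first makes the
all-replicates NF rule unambiguous.

## Consensus typing and hybrid detection

Per-marker strain calls are combined per sample by `consensus_strain()`:

1. if at least `min_agree` markers (default 5, counted absolutely against
   the 6-marker panel) agree on one label among C, R, H, that label is the
   consensus;
2. otherwise, if at least two markers independently called H, the sample
   is a putative hybrid;
3. otherwise no consensus (`NONE`).

`INCONCLUSIVE` marker calls are excluded from both the agreement count and
the informative-marker count, but `min_agree` stays absolute: a sample with
two or more uninformative markers cannot reach a C/R consensus except
through the hybrid rule. This matches the design intent of an absolute
"5 of 6" criterion rather than a proportional one. When a non-standard
panel of *m* markers is supplied, `consensus_table()` scales the default to
`ceiling(5/6 * m)`, overridable.

Two biological validity rules are applied before voting. COI is maternally
inherited, so it can never vote H; an H value arriving at COI is demoted to
`INCONCLUSIVE` (`COI_H_INVALID`). Female Lepidoptera are ZW: a female
cannot be heterozygous at a Z-linked marker (SNP A-C, Tpi), so such calls
are demoted with an `IMPOSSIBLE_HET` flag instead of raising an error —
sex metadata in field collections is occasionally wrong, and a flag leaves
the evidence inspectable.

Per-assay accuracy (`marker_accuracy()`) is the proportion of samples whose
marker call matches their consensus, with no-consensus samples removed from
every denominator; homogeneity of accuracies across assays is tested by
Pearson's chi-square on the match/mismatch table
(`chi_square_homogeneity()`, no continuity correction). The published
accuracy comparison statistic cannot be reconstructed exactly because the
full per-assay mismatch table is not printed; the operation is therefore
generic rather than calibrated.

## In-silico RFLP

`find_amplicon()` performs IUPAC-aware primer matching (the degenerate
COI primers collapse `(G/A)`-style groups to IUPAC codes via
`parse_degenerate_primer()`). When mismatches are tolerated, a mismatch at
a primer's 3'-terminal base still disqualifies the site, reflecting the
poor extension of 3' mismatches in PCR. Nested candidate products resolve
to the innermost (shortest) one, mirroring the kinetic advantage of short
products; several non-nested products raise an ambiguity error rather than
guessing.

`digest()` scans the plus strand only. Both shipped enzymes (MspI `C^CGG`,
SacI `GAGCT^C`) have palindromic recognition sites, so plus-strand scanning
finds every double-stranded site; overlapping occurrences each produce a
cut, which is physically debatable for a real partial digest but
deterministic and conservative. Fragment lengths always sum to the input
length, and k sites yield k+1 fragments on a linear molecule.

COI typing applies the reciprocal rule (MspI cuts and SacI does not: C;
SacI cuts and MspI does not: R; anything else `UNRESOLVED` with both digest
results attached). Tpi typing scores MspI cut state; because the expected
fragment sizes and the cut-site polarity are not printed anywhere
authoritative, the state-to-strain map is configuration
(`pattern_map`, default `cut -> C`), and users typing real material should
validate the polarity once against reference individuals. A diploid sample
supplied as two haplotype sequences with discordant cut states is a hybrid.

## SNP discovery

`filter_variants()` applies the discovery filters: biallelic SNPs only,
site QUAL at least 30, a called genotype in every individual at depth at
least 3, and no unplaced scaffolds (configurable regular expression,
default matching "unplaced"). "Minimum PHRED score" is interpreted as site
QUAL rather than per-genotype GQ, the more common reading for
VCFtools-style filtering. The filters commute, and the report counts
removals per filter in a fixed canonical order.

Per-site differentiation uses the Weir & Cockerham (1984) single-locus
theta, computed from group sample sizes, allele frequencies and observed
heterozygosities — the estimator underlying genepop's per-locus Fst, which
is why it is the default here. The unclamped estimator is returned (it is
legitimately negative at undifferentiated sites in finite samples);
`clamp = TRUE` truncates to [0, 1], and a Hudson-style estimator is
available as an independent cross-check. Sites with fewer than two called
individuals in either group are undefined and excluded from scans. All
individuals are treated as diploid at all loci, including Z-linked ones:
the discovery cohort this mirrors was all male (ZZ), and a haploid-aware
mode is out of scope.

`scan_diagnostic()` ranks sites with theta strictly above the threshold
(default 0.7), Fst descending with (chrom, pos) tie-breaks, and labels each
candidate's C- and R-strain alleles by group predominance.
`extract_context()` then emits the assay-design input: the reference
window 250 bp either side of the focal SNP (501 positions), the focal
position rendered `[C_allele/R_allele]` with the C-strain allele first,
and every other known variant position masked as `N` so probe design
avoids polymorphic bases. Windows at chromosome ends truncate with a
warning.

## Standard curves

`fit_curve()` regresses replicate-averaged Cq on log10 template mass (ng)
by ordinary least squares, reporting slope, intercept (Cq at 1 ng),
R-squared, the derived amplification efficiency `10^(-1/slope) - 1`
(a standard quantity of this fit, reported even where the source tables
print only R-squared), and the limit of detection. Log base 10 is the
standard-curve convention. The LOD is the smallest concentration detected
in all replicates subject to all larger concentrations also being
detected; a non-monotone detection pattern warns and returns the smallest
fully detected level above the highest undetected one. Points below
detection are excluded from the fit; at least three detected distinct
concentrations are required.

## The synthetic-data generator

The generator exists so that every stage is testable without sequence
downloads; its defaults are fixed to the documented behaviour of the real
assays and are not tuning knobs.

**Cq plates** (`simulate_cq_dataset()`). A homozygote's target fluorophore
draws Cq from Normal(23.4, 0.5) — the observed per-assay homozygote means
span 22.91-23.93 — and its off-target channel either never fires (the NF
probability is 1 for VIC in SNP A R-strain homozygotes and for FAM in
SNP C C-strain homozygotes, 0 elsewhere) or lags by an assay- and
strain-specific Normal deviate: 7.05 +/- 0.89 (SNP A, C-strain),
16.26 +/- 1.26 / 17.12 +/- 1.38 (SNP B, R/C), 10.32 +/- 0.97 (SNP C,
R-strain), 3.67 +/- 0.29 / 5.77 +/- 0.45 (SNP D, R/C). These lag
parameters describe reactions in which *both* fluorophores were detected,
so the generator treats them as the both-detected deltaCq distribution:
the target draw is truncated so that target + lag stays within the
40-cycle program (an exact inverse-CDF truncated normal, no rejection
loops), rather than discarding late off-target signals, which would
left-truncate the realized lag distribution and bias its mean well below
the configured value for the slow SNP B channel. The practical effect is a
slightly earlier target Cq for SNP B homozygotes (about 0.2 cycles), well
inside the observed range of per-assay means. Technical replicates add
Normal(0, 0.15) jitter around the reaction mean, capped at cycle 40 (a
threshold crossing in the final cycle is recorded at the final cycle);
the replicate-level SD is not printed anywhere and 0.15 was chosen once so
that the realized spread of per-assay mean Cq spans the observed
22.91-23.93 interval. Heterozygotes draw both channels from the target
distribution with the gap rejected into the 0-2 cycle band.

**Dilution series** (`simulate_dilution_series()`). Cq follows
`intercept + slope * log10(ng)` with Normal(0, 0.3) noise, slope default
-3.3219 (100% efficiency; source figures print R-squared 0.982-0.999 but
not slopes), intercept default 28 (consistent with Cq near 23.4 at the
20 ng assay input and with Cq rising above 30 at and below 0.1 ng), and a
hard detection floor at 0.001 ng reproducing the observed sensitivity
limit: the 0.0001 ng level of the standard seven-step series is always NF.

**Populations** (`simulate_population()`). A random reference (default
three chromosomes of 20 kb: Z, 16, and an unplaced decoy scaffold) with
diagnostic loci at a configurable between-strain allele-frequency
differential (default 1, a fixed difference, giving theta = 1), background
loci at shared per-locus Uniform(0.1, 0.9) frequencies, genotypes drawn
under Hardy-Weinberg within strain, optional hybrids as F1 heterozygotes
(a `backcross` switch draws one parental allele from an F1, producing the
homozygous-at-some-loci hybrids seen in real later-generation material),
Poisson(20) depths clamped at 3, QUAL 5000 with a 5% low-QUAL decoy
fraction among background loci, and exactly one background locus on the
unplaced scaffold as a filter decoy. Output is VCF v4.2 text, FASTA,
and label/truth tables; identical configurations yield byte-identical
files.

What the generator does **not** emulate: raw fluorescence curves and
baseline correction (calling consumes instrument-exported Cq only),
sequencing reads and genotyping error, linkage and recombination
structure, allele dropout correlated with DNA quality, and
between-plate batch effects. Passing tests on simulated data therefore
demonstrate the correctness of the calling/consensus/scan arithmetic
under the documented noise model, not robustness to instrument- or
chemistry-level artefacts.

## Problem sizes and determinism

The shipped tests and the acceptance script use cohorts of 800-1000
simulated reactions per assay/strain for deltaCq recovery (Monte-Carlo
standard error about 0.04 cycles for the widest lag distribution), 50
individuals per strain with 100-1000 loci for discovery recovery, and an
exhaustive 81-configuration sweep for the Fst oracle equivalence at
2+2 samples. Every stochastic entry point requires an explicit seed and
is fully reproducible; derived child seeds stay within 32-bit integer
range.

## Known limitations

* Tpi polarity (which strain's amplicon carries the MspI site) ships as a
  configurable default, not a vetted constant.
* The W&C estimator treats Z-linked loci in females as diploid; typing
  mixed-sex discovery cohorts would need a haploid-aware mode.
* `find_amplicon()` is combinatorial, not thermodynamic: no melting
  temperatures, secondary structure or competitive amplification.
* The consensus rule assumes marker independence when counting votes;
  three of the four SNPs and Tpi are Z-linked, so their errors need not be
  independent in real material.
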