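---
title: "Methods: carrier screening and recessive disease-frequency projection for nonsyndromic hearing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier screening for NSHL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nshlcarrier)
```

## The screening model

`nshlcarrier` estimates carrier status for nonsyndromic hearing loss (NSHL)
in a cohort of genome-sequenced individuals who do not themselves have
hearing loss, and projects from carrier frequencies to the expected
population frequency of autosomal-recessive (AR) disease. The analysis is a
composition of deterministic filters followed by counting; nothing in it is
fit or optimized, which is why every stage is testable against brute-force
oracles.

The stages, in order:

1. **Cohort definition.** Samples failing any of eight sequencing QC
   metrics are removed, then individuals whose Human Phenotype Ontology
   terms intersect a fixed hearing-loss term set (`hl_hpo_terms()`) are
   excluded as affected. All denominators downstream refer to the remaining
   unaffected cohort of size $N$.
2. **Panel filtering.** The gene panel is a table of gene × inheritance-mode
   associations with ClinGen-style validity labels. Validity is an *input*:
   gene–disease curation is expert judgement, not an algorithm, so the
   package filters on the label (disputed/refuted removed, per mode) rather
   than recomputing evidence. A dual-mode gene whose recessive association
   is refuted survives as dominant-only.
3. **Sequence-variant screen.** Candidate variants are catalogue records
   (ClinVar-style) in panel genes whose aggregate class is P, LP, or
   conflicting with at least one P/LP submitter; benign and likely benign
   records are never candidates. Genotype calls below the depth threshold
   become missing; variants whose call rate falls below the threshold are
   dropped entirely. Surviving candidates receive an explicit analyst
   decision (final ACMG class); only P/LP survive. A missing decision is an
   error by design — silent pass-through of uncurated variants is the
   failure mode this guards against.
4. **CNV screen.** Events must overlap coding sequence by at least one base
   pair, be at most 1 Mb, and avoid syndromic critical regions (loci of
   contiguous-gene deletion/duplication syndromes); survivors are curated
   like sequence variants. Events identical in (contig, start, end, type)
   across samples are one recurrent CNV with a carrier count.
5. **Counting.** Per variant: heterozygotes, homozygotes, hemizygotes, and
   AF $= (\mathrm{het} + 2\,\mathrm{hom} + \mathrm{hemi})/2N_g$ with $N_g$
   the individuals genotyped at that site. Per gene: allele counts summed
   over the gene's variants, separately for sequence variants, CNVs, and
   both combined. Allele-count aggregation (not AF summing) is
   authoritative: when one individual carries two variants of a gene the
   allele count stays exact while summed AFs would not.
6. **Hardy–Weinberg projection.** For each gene with a recessive mode, the
   projected affected frequency is $q^2$ with $q$ the combined P/LP allele
   frequency. Because $q$ combines all of a gene's pathogenic alleles,
   $q^2$ implicitly counts compound heterozygotes as affected, which is the
   intended interpretation for recessive disease. The observed carrier
   frequency $2pq$ converts to $q$ by halving under $p \approx 1$; an exact
   mode solving $2q(1-q) = \mathrm{cf}$ exists behind a flag for
   sensitivity analysis and differs from the approximation by $O(q^2)$.
7. **ROH / consanguinity.** NROH and SROH count and sum autosomal runs of
   homozygosity at least 1 Mb long; FROH divides SROH by the autosomal
   genome length. SROH thresholds classify consanguinity evidence and are
   reconciled against self-report.
8. **Reference comparison.** Shared variants are compared against a
   reference cohort's allele counts by a two-tailed Fisher exact test with
   Benjamini–Hochberg adjustment over the shared set.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `min_depth` | 20 | reads | calls under this depth become missing; exactly 20 passes |
| `min_call_rate` | 0.95 | fraction | per-variant genotyped fraction; exactly 0.95 is retained |
| `max_cnv_size_bp` | 1,000,000 | bp | events strictly larger are excluded |
| SROH class bounds | 22 / 79 / 123 | Mb | no-evidence / probable-non / probable / evidence |
| `min_roh_len_bp` | 1,000,000 | bp | qualifying ROH segment length |
| `autosome_length_mb` | 2,881 | Mb | FROH denominator (GRCh38 autosomes) |
| `alpha` | 0.05 | — | significance level after FDR adjustment |

Boundary semantics follow the comparators as printed in the underlying
protocol: mapped reads >98 strict, coverage ≥20 inclusive, uniformity ≥80,
contamination <2 strict, callability ≥95, Q30 ≥90, chimeric <5,
duplicates <10. The SROH rules overlap in prose (≤22 is also <79); the
package resolves this by giving the ≤22 rule precedence, making the
classifier a proper step function — a property the tests assert.

The call-rate denominator is configurable and defaults to the cohort being
screened (the unaffected set). This is the one place where the protocol
leaves the denominator ambiguous (whole QC-passing sample versus unaffected
subset); either choice changes no planted-fixture result, and the parameter
makes the choice explicit.

## Numerical choices

- **Rounding.** Report display rounds half *away from zero* to two decimals
  in percent (`round_half_up()`): 30/4,194 = 0.7153% displays as 0.72%.
  Base R's round-half-even would print 0.72 here too but differs on exact
  ties; all internal values are kept at full precision.
- **Full-precision projection.** Hardy–Weinberg projections and the
  combined recessive burden are computed from full-precision allele
  frequencies, not from the two-decimal display values. This matters: for
  the five most frequent genes the burden from exact counts is 0.42 per
  1,000, while summing the squares of the rounded per-gene AFs would give
  0.44.
- **1-in-X formatting.** The headline 1-in-X burden derives from the
  per-1,000 value after display rounding (0.45/1,000 → 1:2,222), matching
  how such figures are conventionally quoted; the exact reciprocal is also
  returned.
- **Fisher exact test.** The two-sided p-value is the point-probability
  definition (sum of hypergeometric outcomes no more probable than the
  observed table, with relative tolerance 1e−7), computed in log space via
  `lchoose` so large allele counts cannot overflow; degenerate tables
  (empty variable margin) return 1. Tests verify equality with direct
  enumeration and with `stats::fisher.test`.
- **BH-FDR.** Implemented as the step-up definition and verified against
  both the literal definition and `stats::p.adjust`; permutation-equivariant
  and monotone.
- **Intervals.** Event tables are 1-based inclusive (size = end − start + 1,
  so the recurrent STRC deletion measures 57,867 bp ≈ 57.9 kb); BED maps
  are 0-based half-open and converted bit-exactly on read. Overlap queries
  run through IRanges and are property-tested against the O(n·m) scan.
- **Degenerate inputs.** Empty cohorts, zero plantings, header-only VCFs,
  and empty CNV/ROH/reference tables flow through every stage and produce
  empty (not erroneous) results; multi-allelic VCF records are rejected
  with instructions to decompose, since downstream matching is
  allele-specific.

## The synthetic cohort generator

`generate_cohort()` emulates the *output* of an upstream alignment and
variant-calling pipeline, not the reads: a multi-sample VCF with GT/DP, a
CNV/SV event table, per-sample ROH segments, phenotype and QC tables, the
variant catalogue, curation decisions, region maps, and reference counts.
All randomness flows from one seed; identical configurations are
byte-identical, and different seeds permute carrier assignment without
changing planted counts, because carriers are planted by sampling without
replacement among QC-passing unaffected individuals.

Decoys are constructed adversarially, one per filter: benign catalogue
records, conflicting records without a P/LP submitter, uncatalogued
variants, an all-low-depth variant, a low-call-rate variant, noncoding-only
CNVs, oversize CNVs, syndromic-region CNVs, and events in affected
individuals. The round-trip tests assert each decoy is removed by exactly
its intended filter across 50 random configurations.

`study_fixture_config()` freezes the study conditions the package is
validated against: 2,199 individuals (13 QC failures, 89 with hearing-loss
terms → 2,097 unaffected), 89 retained P/LP sequence variants across 36
genes (222 heterozygous, 4 homozygous carriers), 29 preselected variants
curated out (28 VUS, 1 LB), decoy counts sizing the variant funnel
996 → 118 → 89 and the CNV funnel 5,285 → 232 → 12 (54 carriers), ROH
class counts (1,478 / 370 / 150 / 71 with 28 samples lacking data), and a
13-variant reference table in which exactly one variant (the OTOA nonsense
allele) is markedly more frequent in the reference. Per-variant counts are
pinned for the most frequent variants; the remainder is distributed to
satisfy the per-gene and cohort totals, a reconstruction documented here
because the per-variant breakdown below the top alleles is not constrained
by the totals alone. The simulated QC metrics, ROH segment placement and
phenotype decoration are uniform-random within realistic ranges (e.g.
mean SROH ≈ 30 Mb); they carry no linkage, population structure, or
depth-genotype correlation, so passing tests validate the *screening
logic*, not robustness to real-data artifacts like allele-balance-driven
genotype errors.

Three reconciliations were needed where the reference description is
internally inconsistent, and the package picks one behavior deliberately:

- The preselected panel is described as 129 genes with seven excluded
  entities and 121 retained, which does not close arithmetically
  (121 + 7 = 128). The built-in panel follows the summary table, which is
  the scientifically binding artifact: 121 retained genes forming 129
  retained associations (eight genes carry both AD and AR modes), with 8
  excluded association rows over 7 excluded gene symbols plus the refuted
  GJB6-AR form.
- The top-five combined burden (0.42/1,000) is reproducible only from
  full-precision allele frequencies (see above); the package therefore
  never projects from rounded values.
- One printed per-variant AF (OTOA c.2359G>T, 0.61%) implies a
  call-rate-reduced denominator (~2 × 2,049) that is not derivable from the
  main totals; the package reports 25/4,194 = 0.60% with the full-cohort
  denominator and exposes the denominator as data (`n_genotyped`), so a
  per-variant reduced denominator reproduces such values when the
  underlying missingness is present.

One further arithmetic note: the per-gene summary counts a gene's combined
unique variants as sequence + CNV (STRC: 1 + 2 = 3); the analogous printed
row lists 2, which is inconsistent with its own mechanism columns and with
the all-gene total (89 + 12 = 101), so the additive definition is used.

## Limitations

- Variants absent from the catalogue are invisible — a deliberate fidelity
  to the screening design, which the original analysis estimated may lose
  on the order of 15% of relevant alleles.
- The Hardy–Weinberg projection assumes random mating and p ≈ 1; founder
  effects, endogamy and inbreeding (an F correction) are out of scope, and
  no confidence intervals are attached to q².
- CNV recurrence is exact-coordinate identity; near-identical breakpoints
  across samples are distinct events. Reciprocal-overlap clustering would
  be invented behavior with no ground truth to validate against.
- Phasing is not modeled: biallelic risk enters only through the q²
  projection, never through observed compound heterozygosity.
- X-linked carrier handling (hemizygote bookkeeping) is implemented and
  tested synthetically, but the validated fixture contains no X-linked
  P/LP variants, mirroring the reference cohort.

## Problem sizes

The test suite generates its cohorts at run time: the frozen fixture
(2,199 samples × ~1,000 VCF sites, 5,285 CNV events, ~12,000 ROH segments)
is built and screened once and shared across tests (≈35 s), and the
round-trip property runs 50 cohorts of 60–100 individuals. The full suite
completes in about a minute on one CPU.
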