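---
title: "heatcross: models, scores and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heatcross: models, scores and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcross)
```

`heatcross` implements the computational layer of a hybrid-breeding
workflow for heat-tolerant tomato: phenotype-based scoring of parental
lines and F1 hybrids, genome-scale genotype comparison, resistance-gene
screening, and in-silico design of the PCR markers used for that
screening. This vignette explains the models behind each component, the
parameters that matter, and the design choices made where the underlying
conventions were genuinely open.

## Phenotypic scores

**Selection index (SI).** Three traits — fruit set (FS, percent of
flowers setting fruit), fruit number per plant (TNF) and yield per plant
(YP, kg) — are mapped onto an arbitrary integer scale in bins of width
ten and summed. The published scale enumerates integer ranges (0–10 → 0,
11–20 → 1, 21–30 → 2, ...), which leaves non-integer values undefined;
`si_trait_score()` uses half-open bins `(10k, 10(k+1)] -> k` with
`[0, 10] -> 0`, which reproduces the integer mapping and is total on the
non-negative reals. YP enters the scale after multiplication by ten, so
3.15 kg/plant is binned as 31.5 (score 3). Because that sentence could
also be read as adding `10·YP` directly to the two binned scores, the
alternative is exposed as `yp_mode = "direct"`; the binned reading is the
default because it keeps SI an integer sum of three like-scaled scores.
SI is always computed per environment (`selection_index_table()`), never
pooled across environments — the two field sites in the motivating
design are reported as separate axes. Missing traits propagate as
explicit `NA` scores; silent zeros would corrupt rankings.

**Mid-parent heterosis.** `heterosis_pct()` computes
`100 (F1 − PM) / PM` on genotype trait means across replicates, with
`PM` the two-parent mean. A zero mid-parent value makes the quantity
undefined and is returned as flagged `NA`, never as zero. The percentage
convention (multiplying by 100) matches how such tables are printed.

**Hybrid index.** Three scores summarize each hybrid: heat tolerance
`HTS = TNF/10 + 10·YP` (the two yield components scaled to comparable
magnitude), fruit quality `QS = TA/0.3 + TSSC/5.5 + TSSC/(TA·12.5)`
(each trait divided by a bibliographic optimum: 0.3 g citric acid/100 g,
5.5 °Brix, and a solids/acidity ratio of 12.5), and a resistance-gene
score `RGS`. Thresholds are the across-hybrid means of each score,
recomputable from the score table. The default elite rule requires a
hybrid to exceed all three thresholds strictly; `"two_of_three"` and
`"hts_qs"` variants are exposed because threshold rules of this kind
vary between programmes. Ties at the threshold are not elite (strict
inequality), which makes the degenerate all-equal case yield no elites
rather than all.

**RGS counting.** With six assayed resistance genes (Mi-1.2, Ph-3,
Sw-5, Tm-2, Ty-3, Ve-1), the default numerator counts loci at which the
genotype carries at least one resistant allele (RR or RS) and the
denominator counts all assayed genes. Two alternatives are implemented:
`"allele"` (resistant-allele dosage over gene count, range [0, 2]) and
`"segregating"` (locus counting over loci that vary in the evaluated
set, excluding uninformative loci such as a gene fixed RR in every
genotype). No mode is labelled canonical: with the packaged call tables
none of the obvious conventions reproduces the single published score of
0.7 for the two best hybrids (locus counting gives 0.5 and 0.67), so the
package reports whichever convention the user selects and never asserts
the unrecoverable value. Failed assays (`NULL` calls) are an error by
default; `on_null = "skip"` drops the gene from numerator and
denominator.

**Titratable acidity.** `titratable_acidity()` implements the titration
formula `G1 = [NaOH]·vol/m · 1000/10` and multiplies by the fixed citric
acid factor 0.070, giving g citric acid per 100 g sample. The function is
linear in titrant volume and inverse-linear in sample mass.

## Genotype matrices and distances

Genotypes are dosage-coded 0/1/2 with `NA` for missing; any VCF genotype
containing `.` — including half-calls — is treated as missing, the
conservative reading used by common filtering tools. Multi-allelic sites
are dropped by default (the analyses are biallelic-SNP based) or split
into per-alternate pseudo-sites on request. All genomic coordinates are
1-based inclusive internally; BED input is converted on read by the
tracklayer importer.

`filter_variants()` mirrors the semantics of the standard VCF filtering
flags: `max_missing = 0.5` *keeps* sites with at least 50 % data (the
flag's inverted convention), `min_mean_dp = 5` drops sites with mean
depth below 5, and monomorphic sites are removed. Matrices without depth
annotation (e.g. array-derived) pass the depth filter with a warning
rather than failing. Filtering is idempotent.

`ibs_matrix()` computes pairwise identity-by-state as the mean of
`(2 − |g_i − g_j|)/2` over jointly non-missing loci — the
dosage-sharing convention of standard distance tools. Because the
upstream tool in this workflow is cited without a printed formula, the
exact-state identity fraction is exposed as an alternative
(`method = "exact_identity"`). Pairs sharing no locus are flagged `NA`.

`prg_scan()` intersects loci with a resistance-gene interval catalog and
reports, per genotype, the SNPs at which it carries an alternate allele,
the genes containing them, and its share of the catalog-wide SNP total.
The packaged catalog transcribed from the study's variant table has no
interval coordinates (none are printed), so it is scanned through
`prg_scan_fixture()` using the per-genotype multiplicities instead;
bracketed counts are parsed as SNP multiplicities, a plain genotype id
as 1, and the per-gene distinct-SNP count is the maximum multiplicity
across genotypes — the only reading under which the printed totals (71
SNPs in 57 genes) are mutually consistent. Note the published summary
itself conflates SNP and gene ratios in one place (38/71 = 53.5 % is a
SNP ratio; the corresponding gene ratio would be 31/57 = 54.4 %); the
fixture scan reports both.

`impact_tally()` consumes impact classes (HIGH/MODERATE/LOW/MODIFIER) as
annotations — effect prediction itself is external software and out of
scope — and prints percentages with half-up rounding, two decimals below
1 % and one decimal otherwise, matching the printed summary convention.

## Marker design and digest simulation

**Binding model.** Virtual PCR matches the forward primer on the plus
strand and the reverse primer's reverse complement downstream, exactly by
default (`max_binding_mismatches = 0`). No melting-temperature or
secondary-structure model is included: the assays this package simulates
are validated by fragment pattern, not kinetics. The product is the
forward primer, the intervening template, and the reverse complement of
the reverse primer — so a dCAPS primer's engineered base is carried into
the product while binding is evaluated with the original base.

**Digest model.** Recognition sites are IUPAC strings scanned on both
strands; a minus-strand match occupying the same interval as a
plus-strand match (palindromic sites) is one double-stranded site. Each
site contributes one cut at `start + offset − 1` bases from the amplicon
5' end (top-strand convention); cut positions are deduplicated and
fragments are the intervals between cuts, so fragment lengths always sum
to the amplicon length. The shipped catalog defines Hpy188I (`TCN^GA`)
and DdeI (`C^TNAG`) — the enzymes of the simulated assays — plus a small
panel of common cutters for design searches, and is extensible via a
delimited file.

**dCAPS search.** `design_dcaps()` enumerates every recognition window
of every candidate enzyme that overlaps the diagnostic SNP and asks
whether the SNP base completes the site for exactly one allele while all
other mismatching window positions can be repaired by primer
substitutions. Engineered substitutions are restricted to the forward
primer, excluding the SNP column and the three 3'-terminal bases
(standard dCAPS practice — a mismatch at the extreme 3' end would kill
amplification). Zero-substitution solutions (a natural CAPS difference)
are preferred; the design is then re-simulated against both allele
templates and must discriminate them, a closure property enforced on
every design and fuzz-tested in the suite.

**SCAR design.** `design_allele_specific_scar()` places each
allele-specific forward primer so its 3' terminus sits on the
discriminating base and pairs both with a common reverse primer in a
monomorphic region, yielding equal-length amplicons for the two alleles.
Calling is by amplification pattern: product in the R reaction only →
RR, S only → SS, both → RS, neither → `NULL`.

**Heterozygote patterns.** A heterozygote's digest is the union of the
two allele patterns with shared fragments collapsed — bands of equal
length co-migrate on a gel — and `call_genotype()` compares band sets
accordingly. An assay whose R and S patterns coincide is reported
uncallable rather than arbitrarily resolved.

**Paralog handling.** Where a close paralog would co-amplify (the
Ve-1/Ve-2 situation: two adjacent genes of ~91 % identity),
`find_specific_windows()` ranks sliding windows by percent identity
between gene and paralog, and the outer primers of a nested assay are
placed in low-identity windows; `nested_pcr()` then raises a specificity
error if the inner pair binds the template outside the outer amplicon.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their spec and a seed.

**Trait tables.** `gen_trait_table()` inverts the heterosis formula:
each F1 trait expectation is `midparent · (1 + e/100)` for planted
effect `e`, with additive Gaussian replicate noise truncated at zero
(traits are non-negative; fruit set is additionally capped at 100). The
defaults mirror the modelled field design: three replicates per genotype
in one environment. No noise model is stated in the motivating work, so
truncated Gaussian was chosen as the simplest model supporting recovery
bounds: with zero noise the planted heterosis is recovered exactly, and
with noise σ over n replicates the recovered mean converges within
3σ/√n.

**Genotype matrices.** `gen_genotype_matrix()` derives every sample from
a base haplotype of homozygous dosages by independent per-locus 0↔2
flips with probability `1 − target`, so expected dosage-sharing against
the base equals the target; a full target matrix is feasibility-checked
against the implied between-sample similarities and rejected with the
offending pair named. Heterozygosity is a knob defaulting to 0 (inbred
lines are near-homozygous). The simulated regime covers the published
range down to the most distant pair (IBS 0.54), recovered within ±0.02
over 5000 loci. The generator deliberately has **no** linkage
disequilibrium, population structure beyond the star-shaped flip model,
or read-level error; passing tests therefore demonstrate correctness of
the distance and filtering arithmetic, not robustness to realistic
genome structure.

**Marker templates.** `gen_marker_templates()` builds allele template
pairs from random background with the assay's restriction sites planted
at offsets chosen to reproduce the published fragment geometries — the
358 bp Hpy188I CAPS with susceptible fragments 133 + 225 and resistant
43 + 133 + 182; the 1016 → 261 bp nested DdeI dCAPS with resistant
156 + 105 and susceptible 130 + 105 + 26; the 206 bp allele-specific
SCAR pair — and the background scrubbed of accidental recognition sites
on both strands (including in the engineered-primer product). Closure is
verified at generation time: templates that fail to reproduce their
specified multisets are an error, not a warning. Two published geometry
details are not jointly derivable from the printed description: the side
of the amplicon on which the CAPS enzyme's single susceptible-allele cut
falls (the fixture fixes 133 from the 5' end), and the exact engineered
dCAPS mismatch offset (the printed fragment lengths imply primer
position 26 under top-strand `C^TNAG` cutting, while the text states
position 22; the fixtures honour the fragment lengths, which are the
quantities the assay is scored by). These templates are synthetic
constructions carrying no database sequence.

## Numerical choices and degenerate inputs

* Bin scores: half-open intervals, strict elite inequalities, and
  half-up percentage rounding are stated above; all are deterministic
  tie-break rules, not tunable parameters.
* `QS` with `TA = 0` is a domain error (division by zero), reported with
  positions; `TSSC = 0` degenerates gracefully to `TA/0.3`.
* IBS with no shared loci, heterosis with a zero mid-parent, and failed
  marker assays all produce flagged `NA`/`NULL` results, never silent
  zeros.
* The demo pipeline's parent trait means are fixed representative values
  derived from the packaged parental classification (fruit-set and yield
  classes HH/H/M/L, quality H/M/L), so the demo is deterministic given a
  seed and its elite set is a constructed truth, not an estimate of the
  published one.
* Problem sizes in the test-suite and acceptance runs — 5000 loci for
  similarity recovery, 30 replicates for noisy heterosis recovery, 1000
  random digest fuzz cases, a few dozen dCAPS design closures — were
  chosen as the smallest sizes at which the statistical bounds above are
  sharp.

## Known limitations

* The published field results (per-site selection-index extremes, the
  top HTS/QS values, the printed per-hybrid heterosis) depend on
  appendix trait tables that are not publicly deposited; they are
  covered by planted-truth recovery properties rather than numerical
  reproduction. The printed heterosis table ships as a fixture and is
  used as planted effects, not as a target.
* The cross-design fixture is only two-thirteenths documented; the
  remaining parentages are plausible synthetic assignments consistent
  with the hybrids' printed marker calls (one printed call, Ph-3 in one
  hybrid, is inconsistent with any parent assignment and with its own
  parental table — the fixture transcribes it as printed).
* Primer binding is exact-match; cross-hybridization, thermodynamics and
  genome-wide off-target amplification are out of scope.
* The impact tally consumes annotations; no variant-effect prediction is
  performed.
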