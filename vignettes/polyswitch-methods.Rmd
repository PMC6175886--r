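---
title: "Methods and design of polyswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of polyswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyswitch)
```

`polyswitch` models the genetics of a nematode mouth-form polyphenism
switch: two opposing, dosage-dependent genes — the X-linked *eud-1*
(Eu-promoting) and the autosomal *seud-1* (St-promoting, duplicated in
*P. exspectatus*) — whose relative functional copy number sets the
fraction of eurystomatous (Eu) versus stenostomatous (St) animals a
genotype produces. This vignette documents the models, the defaults and
their rationale, the numerical choices, and what the synthetic data do and
do not emulate.

## The mapping cascade

Suppressor mutants are mapped by resequencing two independently isolated,
backcrossed alleles and asking which annotated gene carries *non-identical,
potentially harmful* lesions in both. The cascade is:

1. `load_variants()` — SNVs from VCF v4.2 (via vcfR) or a TSV dialect;
   multi-allelic and non-SNV records are skipped and counted, since the
   screen chemistry (EMS) produces point lesions.
2. `quality_filter()` — retain records with `qual >= 20` and `depth >= 5`.
   These defaults are an automated, configurable stand-in for manual
   curation of artefactual calls in a genome browser; they are ordinary
   short-read thresholds, not tuned values.
3. `subtract_shared()` — drop any variant whose (contig, position, ref,
   alt) key occurs in a background strain (the mutagenised parental line
   and a phenotypically marked derivative). The strain field is ignored
   for matching. Subtraction is idempotent and order-independent, and the
   candidate set shrinks monotonically as backgrounds are added.
4. `classify_impact()` — locate each SNV against the gene models, rebuild
   the affected codon from the spliced CDS (alleles complemented on minus
   strands), and translate: same residue = synonymous, premature stop =
   nonsense, other = missense. Intronic variants within 2 bp of an exon
   boundary are splice-site: the canonical GT/AG dinucleotides, a fixed
   window chosen because essentially all spliceosomal introns begin GT and
   end AG. Everything else is noncoding. The reference allele must match
   the genome or the call errors out, because a mismatch means the variant
   table and genome are inconsistent.
5. `harmful_subset()` and `intersect_candidates()` — harmful classes are
   nonsense, missense and splice-site; a gene qualifies if each allele
   contributes at least one harmful call and the two alleles' calls in the
   gene are not the identical variants (independent lesions cannot be the
   same molecular event).

All coordinates are 1-based inclusive (GFF3 and VCF convention), and all
internal arithmetic keeps that convention. Heterozygous versus homozygous
call status is not modelled: all retained calls are treated equally, which
is conservative for backcrossed, rehomozygosed strains.

## The cross engine

Sex determination is XX/XO: XX animals are hermaphrodites/females, XO are
males. Gametes are enumerated exactly: one allele per autosomal slot pair,
all X-linked loci travelling together on the chosen X, and XO fathers
producing X-bearing and nullo-X sperm at 1/2 each (the standard
assumption; the study system's sex ratios from male-sired crosses are not
modelled further). Offspring distributions are the product of the parental
gamete distributions; a paternal X gives an XX daughter, a nullo-X gamete
an XO son. Hermaphrodite selfing is modelled with all-X self sperm — real
selfing produces rare nullo-X sperm and hence rare males, but those are
ignored here because phenotyping panels score hermaphrodites/females only.

The *P. exspectatus* duplicates *seud-1.1*/*seud-1.2* are modelled as two
autosomal loci in one `seud-1` dosage family, both fully functional: the
duplicates are >99% identical at the protein level and under strong
purifying selection, so equal function is the parsimonious default.
*P. pacificus* haplotypes carry an `absent` state at the duplicate locus.
Their physical linkage is not known to us, so they assort independently by
default; `gametes(..., linked = list(c("seud-1", "seud-1.2")))` co-transmits
them if desired.

`functional_dosage()` counts `functional` alleles per family, giving the
E:S ratio of any genotype; the four hybrid designs in
`hybrid_panel_designs()` (wild-type, *eud-1*-null, *seud-1*-null and
double-mutant *P. pacificus* mothers crossed to wild-type *P. exspectatus*
males) yield F1-female classes 2:3, 1:3, 2:2 and 1:2.

One documented tension in the source material: one summary sentence
implies no *eud-1* dosage can produce Eu animals without functional
*seud-1*, while the mutant-phenotype data show *seud-1* nulls to be fully
Eu. The engine follows the mutant-phenotype data: S = 0 (with functional
*eud-1*) is the all-Eu boundary.

Complementation groups are the connected components of the
fails-to-complement graph; consistent data make every component a clique,
and intransitive data (A fails with B, B fails with C, A complements C)
raise an error listing the offending triples rather than guessing a
partition.

## The morph decision model

The synthetic morph decision is logistic in relative log dosage:

P(Eu) = logistic(a + b·log2(E/S)), with hard boundaries P = 1 at S = 0
(functional *eud-1* present) and P = 0 at E = 0; E = S = 0 is an error.

Defaults a = logit(0.9) and b = 2 are an invented calibration, chosen once
so that the balanced 2:2 genotype reproduces the laboratory reference
strain's ~90% Eu phenotype and the enumerated panel spans near-all-St to
near-all-Eu across the observed ratio range (1:3 to 2:1); the underlying
dosage–morph relation in the source system is qualitative (a monotone
gradation), so only the direction and anchor point are empirical.
Intermediate-morph animals arise independently at rate 0.005 — the upper
bound of the "rare, under half a percent" intermediates reported by
phenotype scorers — and are excluded from every analysis denominator
(`n_eu + n_st`).

## Morph statistics

* `eu_fraction()` — exact Clopper–Pearson intervals via the binomial test;
  exact intervals are conservative (coverage at or above nominal), which
  the acceptance checks verify by enumerating the binomial directly.
* `chisq_2x2()` — uncorrected Pearson statistic. No Yates correction: the
  pooled two-proportion Z statistic then satisfies z² = χ², which is the
  identity the multiple-comparison Z tests rely on. Degenerate tables with
  a zero margin report statistic 0 and p = 1 rather than NaN.
* `bh_adjust()` — Benjamini–Hochberg step-up via `p.adjust`.
* `fit_binomial_glm()` — `stats::glm` with binomial errors and logit link
  (IRLS; convergence at relative deviance change < 1e-10, at most 100
  iterations). Complete separation is unavoidable here because all-Eu and
  all-St groups are real dosage boundaries; fitted probabilities are
  clamped to [1e-8, 1 − 1e-8] and flagged `separated` instead of being
  treated as failures. Replicates are pooled within lines for display
  statistics and pairwise tests, and kept as a model term in the GLM when
  requested.

## qPCR quantification

ΔCt is the technical-replicate mean Ct of the target minus the arithmetic
mean of the reference genes' Cts in the same (group, biological replicate)
sample — the arithmetic mean on the Ct scale is the geometric mean of the
linear quantities, and supports one or more reference genes. ΔΔCt
subtracts the control-group mean ΔCt (so control-group ΔΔCt averages 0 by
construction), and log2FC = −ΔΔCt·log2(f). The amplification factor f
defaults to 2 and is otherwise estimated from a 5-log titration as
f = 10^(−1/slope) with the slope from least squares of Ct on log10 input
(at least 3 points spanning at least 2 logs).

Group comparison aggregates technical replicates to biological-replicate
means and applies a one-way fixed-effects analysis with Tukey's honest
significant difference. This replaces a repeated-measures mixed model; for
balanced designs (equal technical replication per biological replicate)
the two give the same group-mean comparisons, which is the design case
here (3 × 3). Technical-replicate outliers are not removed — the wet-lab
equivalent (melting-curve QC) has no in-silico counterpart. Runs with
different primer sets are combined after per-run ΔΔCt, so a run-level Ct
offset cancels exactly.

The Ct generator writes Ct = base − log2FC + sample offset + technical
noise: one cycle per true doubling of template, a per-(group, biological
replicate) offset shared by all genes of that sample (template-amount
variation, cancelled exactly by reference normalisation), and i.i.d.
Gaussian technical noise. It does not emulate amplification inhibitors,
probe saturation, or gene-specific efficiency differences.

## Pairwise dN/dS (NG86)

Site counts: at each codon position the synonymous fraction is the share
of the three possible substitutions preserving the amino acid; mutations
creating a stop count as nonsynonymous (the standard convention), and
s + n = 3 per codon. Differences: averaged over all minimal substitution
pathways between two codons; pathways through stop codons are excluded
with equal reweighting of the survivors. If every pathway passes through a
stop — possible only in multi-difference codons — the end-state amino
acids decide (same residue: all synonymous; different: all
nonsynonymous); the original counting method leaves this case open, and
this rule keeps sd + nd equal to the raw difference count. Proportions
pS = Sd/S and pN = Nd/N are corrected with Jukes–Cantor,
d = −(3/4)·ln(1 − 4p/3), which is undefined at p ≥ 3/4 (an explicit
error) and reduces to p as p → 0. ω = dN/dS is reported as undefined when
dS = 0 — not infinity, since no synonymous divergence means the ratio
carries no information. The universal genetic code is used, without
transition/transversion weighting (unweighted counting, not the modified
method), and a shared terminal stop codon is stripped before counting
because site fractions of a stop codon are not defined under the
convention above. Implementations are validated against an independent
brute-force oracle that re-enumerates sites and pathways from scratch.

## What the synthetic screen emulates

`gen_reference()` builds 2 contigs × 50 genes of spliced, multi-exon,
strand-alternating protein-coding genes (start codon, terminal stop, no
internal stops, canonical GT/AG introns) with ~20% coding density. The
causal gene gets 10 exons so the two planted nonsense lesions can sit in
exons 8 and 1, mirroring the two-allele configuration the mapping cascade
must resolve; its lesion exons are built with at least one
single-base-to-stop site available (minimum 90 bp), since a fixture whose
designated exon cannot host a nonsense change is unusable by construction.

`gen_screen_dataset()` plants one nonsense SNV per mutant (EMS-compatible
G:C→A:T where possible), adds the shared parental background (40 SNVs,
default) to both mutants and to the parental and marker strain tables, and
adds strain-specific EMS background at a Poisson mean of 0.5 per genome
with an 0.85 G:C→A:T transition bias (EMS chemistry; the true spectrum of
the screen is unreported). The background density deserves a note: these
tables emulate *backcrossed* mutants, as resequenced in such screens. A
mutagenised genome carries hundreds of EMS variants, but four to six
rounds of backcrossing retain only ~1–3% of unlinked ones — order ten
variants across a real genome's tens of thousands of genes, i.e. far
below one per hundred genes. Scaled to this 100-gene mini-genome that is
≈ 0.05; the default 0.5 is deliberately ten-fold conservative so the
subtraction and harmful-filter stages stay exercised. At realistic
mutagenised (un-backcrossed) densities a 100-gene genome would produce
chance two-allele coincidences that a 25,000-gene genome makes negligible
— an artefact of miniaturisation, not of the method.

What the fixtures do **not** emulate: read-level data and alignment error,
indels and structural variants, linkage between background variants and
the causal locus (the retained-linked-region structure of real backcrossed
strains), heterozygous residual sites, annotation error, and UTRs (every
exon is fully coding). Passing tests therefore demonstrate the correctness
of the filtering/classification logic and the statistical calibration of
the estimators, not robustness to alignment or annotation artefacts in
real resequencing data.

## Problem sizes and numerical choices

Simulation sizes used by the test suite and the acceptance script — 100
fixture seeds for screen truth-recovery, 10,000 null tables for the χ²
type-I error, 100 seeds × 500 animals per dosage class for GLM slope
recovery, exact binomial enumeration (n = 60) for interval coverage, and
100 seeds of 3 × 3 Ct tables at technical SD 0.2 — were chosen as the
smallest designs whose Monte-Carlo error is well below the tolerances
being checked (3-SE bands for binomial checks; ±10% for slope recovery).
Random draws are reproducible: every generator either takes a `seed`
argument or documents that it consumes the caller's RNG stream.

## Known limitations

* The cross engine ignores recombination, mitochondrial inheritance, and
  hybrid incompatibility; reciprocal hybrid males (known to carry
  asymmetric epistatic backgrounds) are excluded by the females-only
  scoring convention rather than modelled.
* The GLM handles separation by clamping, not by exact or penalised
  methods (Firth-type corrections are out of scope).
* NG86 is the unweighted counting method; likelihood dN/dS and
  codon-model corrections are not implemented, so ω values on strongly
  diverged pairs should be treated as descriptive.
* Quasi-binomial overdispersion and multivariate-t contrast machinery for
  GLMs are not provided.
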