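---
title: "Methods: pedigree-aware rare-variant filtering and segregation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware rare-variant filtering and segregation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

# Scope and model

`famseg` analyses multiplex-family exomes: cohorts of families with two
or more members affected by the same disorder, sequenced together with
unaffected relatives where available. The underlying genetic model is
that such families are enriched for rare variants of relatively large
effect transmitted within the family, so the unit of inference is the
(variant, family) pair, not the population: a candidate is a rare,
plausibly functional variant whose within-family genotype configuration
matches an inheritance pattern — dominant-like sharing among the
affected, de novo mutation, recessive homozygosity, or X-linked
hemizygosity.

The pipeline is deliberately a cascade of deterministic filters rather
than a statistical association test; with a handful of families there
is no power for per-variant association, and the output is a candidate
list plus a gene-set over-representation analysis that aggregates the
weak per-variant evidence at the pathway level.

# Quality control

Genotype calls are kept when read depth is at least `min_dp` (default
10 reads), genotype quality at least `min_gq` (default 20, phred
scale), and — for non-reference genotypes only — the alternative allele
ratio `ad_alt / (ad_ref + ad_alt)` is at least `min_aar` (default
0.25). All bounds are inclusive. A homozygous-reference call passes
the ratio check vacuously: the ratio constrains evidence *for* an
alternate allele. An undefined ratio (zero or missing depths) fails.

Two design points deserve emphasis:

* **Failing calls are demoted to missing, never dropped with the
  site.** A site is removed only when no call survives. This matters
  for de novo classification: a low-quality parental call must *block*
  a de novo assignment (missing parent means no confident
  transmission), which requires the site to survive with the parent
  marked missing.
* **Site-level rules** (FILTER must be `PASS`, i.e. VQSR-passing;
  segmental-duplication regions excluded; variants detected in 20 or
  more samples of an in-house exome cohort excluded as
  platform-dependent artifacts) drop the whole record. The in-house
  rule counts carriers, with the boundary at
  `inhouse_max_detections = 19`: a count of 20 is excluded, 19 kept,
  and variants absent from the table count zero.

QC is idempotent and monotone in its thresholds (tightening any
threshold can only shrink the surviving call set); both properties are
asserted by randomized tests.

# Relatedness verification

Sample swaps and mislabeled pedigrees are the classic failure mode of
family studies, so the pipeline verifies relationships before trusting
them. For each sample pair the KING-robust kinship estimator is
computed over co-called autosomal biallelic sites:

$$\hat\varphi = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{N_{Aa,i} + N_{Aa,j}}$$

with \(N_{Aa,Aa}\) the both-heterozygous site count, \(N_{AA,aa}\) the
opposite-homozygote count and \(N_{Aa,\cdot}\) the per-sample
heterozygous counts. The estimator is robust to population structure
and needs no allele-frequency estimates; duplicates/MZ twins sit at
0.5, first-degree relatives near 0.25, unrelated pairs near 0.
Estimates map to degrees by the standard cutpoints (0.354, 0.177,
0.0884, 0.0442). Numerical choices: a zero denominator (no
heterozygous sites in either sample) yields an undefined estimate,
reported as `NA` with degree `unrelated`, and counted as a mismatch
whenever a relationship was expected; X-chromosome sites are excluded
because male hemizygosity violates the diploid model.

Expected degrees come from the pedigree itself via the classic
path-counting kinship recursion (parent-offspring and full sibs 1/4;
half-sib, avuncular and grandparental 1/8; first cousins 1/16;
consanguineous loops handled exactly), mapped through the same
cutpoints. Kinship is estimated on QC-passed but *pre-rarity-filter*
genotypes: the estimator needs common variants, which the rarity filter
would remove. The verification report is informational — it lists
mismatching pairs but does not gate the pipeline, since the right
remedy (dropping or relabeling samples) is a judgment call.

# Rare-variant filters

Three conjunctive, order-independent predicates:

* **Consequence** — nonsynonymous, stopgain, stoploss,
  frameshift/in-frame indel or splicing consequences pass; synonymous
  variants pass only when flagged as splice-site (synonymous changes
  can disrupt exonic splice enhancers), controlled by
  `include_splice_synonymous`.
* **Frequency** — allele frequency at most `max_af` (default 0.01) in
  *every* configured database (defaults: 1000G_ALL, ExAC_ALL, ExAC_EAS,
  HGVD, jMorp — a mix of global and Japanese panels, since rare
  variants are population-specific). A missing frequency means the
  variant was never observed there and passes; a configured database
  missing entirely from the annotation is a configuration error, not a
  silent pass.
* **Gene constraints** — at least one overlapped gene must have RVIS
  percentile ≤ `max_rvis_percentile` (default 25; low percentile =
  intolerant of functional variation) and brain normalized expression
  ≥ `min_brain_nx` (default 1). ANY-gene semantics were chosen for
  multi-gene variants (the alternative, ALL-gene, would discard a
  variant hitting one intolerant brain gene merely because it also
  touches a tolerant neighbor); gene-level outputs then attribute the
  variant to its passing genes.

Annotation is consumed, not computed: the pipeline starts from a
per-variant TSV (gene, consequence class, per-database frequencies,
segmental-duplication flag) and a per-gene TSV (RVIS percentile, brain
expression), as produced by upstream annotation tools.

# Segregation classification

Genotypes are first recoded into sex- and chromosome-aware states: on
the non-pseudoautosomal X, any alternate-bearing male call becomes
`hemi_alt` (variant callers emit hemizygous males as diploid `0/1` or
`1/1`, so both recode); the GRCh37 pseudoautosomal regions
(X:60001–2,699,520 and X:154,931,044–155,260,560) stay autosomal-like.
Per family:

* **shared_het** — at least two sequenced affected members carry, and
  (default `"all"` mode) every affected member with a non-missing call
  carries. Small multiplex pedigrees justify the all-affected rule;
  `"min2"` mode relaxes to any two carriers for larger or
  phenocopy-prone families. Both modes are first-class.
* **de_novo** — an affected member carries while both parents are
  pedigree members, sequenced, *unaffected*, and confidently homozygous
  reference. The unaffected-parents restriction exists because an
  affected parent's variants are expected to be transmitted, not de
  novo, and would be double-counted by the shared route.
* **homozygous_recessive** — the affected members (two or more; all
  called affecteds in `"all"` mode) are alternate homozygotes and no
  sequenced control is; heterozygous carrier parents do not block. The
  family's consanguinity flag is carried as metadata, not required —
  recessive candidates are legitimate in outbred families too.
* **hemizygous_x** — every called affected male is `hemi_alt` (at
  least one exists), every called affected female is a heterozygous
  carrier, and no unaffected male is hemizygous. Unaffected
  heterozygous females are permitted: they are the expected carrier
  mothers of X-linked recessive transmission.

When several predicates fire, a fixed precedence resolves the class:
de_novo > hemizygous_x > homozygous_recessive > shared_het, so each
(variant, family) gets exactly one label. Two candidate sets are
built: the *all* set over every pedigree with lenient sharing, and the
*strict* set restricted to control-bearing pedigrees with the
additional rule that no sequenced control carries the variant. Counts
deduplicate variants by `(chrom, pos, ref, alt)` across families and
take the union of gene sets.

One pedigree shape needs comment: an affected mother whose own parents
are available can legitimately host de novo candidates of her own while
simultaneously acting as the carrier mother of her sons' X-linked
variant. The bundled fixture of the published candidate variants
realizes exactly this configuration — the grandmother carries the X
variant, so it is blocked from the de novo route and classified
hemizygous, while the mother's autosomal variants remain de novo
against her homozygous-reference parents.

# Enrichment

Candidate genes are tested for over-representation in GMT gene sets by
the exact one-sided hypergeometric tail
\(P(X \ge k)\) for \(X \sim \mathrm{Hypergeom}(N, K, n)\), with
Benjamini–Hochberg Q-values across sets and significance declared at
\(Q < \alpha\) (strict, default 0.05). The universe defaults to the
genes bearing both RVIS and expression annotations — the space the
filters actually searched; using all genes ever annotated would
overstate significance. Set members are intersected with the universe
before testing (coverage is reported as `k/K` on the intersected
size), and query genes outside the universe are dropped with a
warning. Because the test is discrete, its achievable level at nominal
0.05 is below 0.05; the test suite verifies the tail against exhaustive
enumeration for all universes up to size 12 and Monte-Carlo-calibrates
the null rejection rate on a fixture (universe 400, set size 40, query
50) whose achievable level, 0.0458, was computed analytically from the
tail beforehand.

# The synthetic cohort generator

`simulate_cohort()` emulates the inputs of a 14-family study: 39
sequenced members (30 affected, of whom one carries a different
psychiatric diagnosis, plus 9 within-family controls in exactly seven
families), one consanguineous family whose sequenced parents are first
cousins, one quartet with sequenced unaffected parents, and one family
with an affected mother and two affected sons. Defaults:

* 20,000 independent autosomal background sites, allele frequencies
  uniform on [0.05, 0.5]; founders drawn in Hardy–Weinberg proportions,
  non-founders by single-locus Mendelian transmission. These anchor
  the kinship estimates and are removed by the frequency filter (their
  annotated frequencies equal their simulated frequencies).
* Planted candidates: 8 shared het, 3 de novo, 1 recessive homozygous,
  1 X-linked hemizygous — the scale of the candidate classes a cohort
  of this size yields. Every planted variant receives a
  Mendelian-consistent carrier path (the carrier line runs het through
  the relevant ancestors), except de novo plants, which are deliberate
  transmission violations.
* 8 decoys, each violating exactly one rule: common frequency,
  non-splice synonymous consequence, tolerant gene, non-brain gene,
  segmental duplication, VQSR failure, low depth at carrier calls, and
  in-house commonness.
* Read depths from an overdispersed negative binomial (mean 60, size
  8), so allele-ratio boundary cases arise naturally at background
  sites; planted calls get fixed depth 60 so their fate is decided by
  the rules under test, not sampling noise.

The truth table records each planted variant's class and expected
membership in the all and strict candidate sets; notably, shared
variants whose obligate carrier mother is herself a sequenced control
(the quartet and the consanguineous family) are expected in the all set
but *not* the strict set — the simulator encodes the strict rule's
consequences rather than assuming recovery. `add_genotype_noise()`
perturbs calls at a configurable per-call rate (depth collapse, quality
collapse, or genotype flip with consistent allelic depths) and records
every perturbation in a ledger, so tests can require that each
end-to-end false negative is traceable to a specific corrupted call.

What the simulator does **not** model — and therefore what passing
tests do not show about real data: linkage disequilibrium and
recombination (sites are independent), X-chromosome transmission for
background sites (the X carries only planted variants), sequencing
error profiles beyond the noise model, population stratification,
annotation errors, and realistic mutation-rate variation. The
simulator validates the *logic* of the pipeline, not the calibration of
upstream callers.

# Problem sizes and determinism

The test suite runs the full pipeline on 20 seeded default-size cohorts
(20,000 background sites each) for exact planted-truth recovery,
calibrates the kinship estimator on 20 replicate pairs of 10,000
independent sites per relationship class, sweeps the hypergeometric
oracle exhaustively to universe size 12, and replays 1,000 null
enrichment replicates — sizes chosen so the whole suite completes in
well under a minute per component while keeping Monte-Carlo standard
errors far inside the asserted bands. Every stochastic step is seeded;
a bundle is byte-reproducible from its seed, and file-based runs are
deterministic (no timestamps in outputs), so reports can be diffed.

# Known limitations

* Compound heterozygosity and phasing are out of scope; the recessive
  class covers homozygous genotypes only.
* The all-affected sharing rule is sensitive to phenocopies in large
  sibships; use `"min2"` mode there.
* The enrichment universe question has no single right answer; the
  default (annotated genes) is overridable, and denominators from
  other annotation systems will not be comparable.
* Kinship degrees beyond third are not distinguished from unrelated,
  matching the estimator's resolution at exome site counts.
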