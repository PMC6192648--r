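---
title: "Methods: screening, profiling and association testing of function-unknown protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, profiling and association testing of function-unknown protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic testbed does and does
not establish.

## The screening model

The input is a catalog of pre-clustered protein families: a multi-FASTA of
amino-acid sequences plus a membership table recording, for every sequence,
its family, the taxon of the source genome, and whether the underlying gene
call had a start and a stop codon. The package never re-clusters; families
arrive as given.

**Quality filter.** A family passes when it has at least `min_unique = 3`
distinct member sequences and at most `max_truncated_frac = 0.5` truncated
members. Both constants are exposed; their defaults are the screening
thresholds the package is built around. Two readings were pinned
deliberately:

* *truncated* means missing a start **or** a stop codon (inclusive or) —
  the plain reading of "lacks a start or stop codon";
* the truncation bound is a strict inequality, so a family with exactly
  half its members truncated passes, and `n_unique = 2` fails while 3
  passes. Both boundaries are pinned by tests.

Sequences are normalized before any comparison: uppercased, exactly one
trailing translation-stop `*` stripped. An internal `*` is rejected rather
than repaired — it usually marks a pseudogene or frameshifted gene call,
and silently "fixing" it would let a corrupt sequence participate in
exact-match screening. Normalization is idempotent.

**Annotation status.** A family counts as annotated when any member is
*exactly* identical, over its full length, to a database sequence that
carries at least one domain accession. Because the criterion is 100%
identity over the full length, string equality on normalized sequences is
sufficient and bit-exact, so the package uses a hash index
(`build_annotation_index()`) instead of an aligner. This is a deliberate
restriction: the families are assumed to derive from genomes that the
annotation databases have already processed, so homology search would add
nothing but false positives. A `homology` mode is declared in the
configuration for catalogs whose genomes are *not* in the databases
(metagenome-assembled families, for instance) but is not implemented and
raises an error, so the restriction is explicit rather than silent.

An exact hit to a database entry with an *empty* domain list (a catalogued
but domain-less protein) is recorded in the hit table for transparency but
does not set the annotated flag: the definition of "annotated" here is
domain-centric, and a hit that assigns no domain tells us nothing about
function.

## Phylogenetic breadth and selection

For each family, `breadth_profile()` counts the distinct named taxa among
members at each of the eight ranks species, genus, family, order, class,
phylum, kingdom, domain. Distinctness is by taxon *name* at the rank, not
by taxonomy-id path: the lineage table is name-based, and two genomes
sharing a class name count once. A member whose taxon is absent from the
lineage table, or whose lineage is unnamed at a rank, contributes nothing
at that rank; a family of lineage-less members has breadth 0 everywhere
and can never be selected. This is the conservative choice — unnamed
lineages never inflate breadth.

A **FUnkFam** is a family that passes the quality filter, is unannotated,
and spans at least `min_distinct = 2` distinct taxa at
`breadth_rank = "class"`. No canonical ranking function exists for "most
phylogenetically diverse", so the package defines one and labels it as its
own convention in output headers: lexicographic on (distinct domains,
distinct phyla, distinct classes, number of unique sequences), all
descending, with ascending family id as the final deterministic tiebreak.
Selection is invariant under permutation of input rows.

## Metagenome profiling

Alignments arrive as standard 12-column BLAST/Diamond tabular files (m8).
Per read, the best hit is the one with the highest bit score; ties break by
lower e-value, then lexicographically smallest subject id, so results do
not depend on file order. A read then counts toward its best-hit family iff
its identity is at least `min_identity = 99` percent **and** the alignment
covers the whole read. The m8 format carries no query length, so "whole
read" is operationalized as `align_len >= read_length` with `read_length` a
per-sample metadata constant — appropriate for the fixed-length short-read
data this statistic was designed for. Identity is taken from the `pident`
column as reported by the aligner; the package does not recompute it.

Presence is `count >= 1`. Abundance is RPKG:
`count / (mean member length in aa x 3 / 1000) / genome_equivalents`.
The family length enters in nucleotide-equivalent kilobases (aa x 3 /
1000) because reads are DNA and the statistic is per kilobase of gene;
genome equivalents (library depth divided by average genome size) are a
required metadata column, estimated upstream by tools such as average-
genome-size estimators — the package consumes, never computes, them.

Ecology summaries: per-environment prevalence; binary presence entropy in
bits (maximal at 50% prevalence), used to pre-filter families with enough
presence variation to be testable — families at or above the empirical
75th percentile of entropy are retained (`stats::quantile` type 7, linear
interpolation; ties at the threshold retained); a phylum pre-filter keeps
families spanning at least `min_phyla = 2`. Bray–Curtis dissimilarity
(`1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`) is computed pairwise by the
closed form and, for matrices, via `vegan::vegdist`; the two routes are
cross-checked in the tests. Two all-zero abundance vectors have no defined
dissimilarity and are an error, not a 0. The claim "beta diversity is
higher between environments than within" is backed by a one-sided
Mann–Whitney U test of the between-pair distribution against the pooled
within-pair distributions — the package's choice of test, made because the
comparison is of two dissimilarity distributions with no distributional
model attached.

## Association testing

For each stratum (body site, size fraction, …) and each covariate that
passes eligibility, one logistic regression is fitted per family:
`presence ~ intercept + adjustment terms + covariate`.

* **Eligibility**: after dropping missing values, at least two covariate
  values must occur more than four times (i.e. count >= 5). The same rule
  applies to numeric covariates via their distinct values, so a continuous
  covariate whose values never repeat is ineligible; in practice
  phenotype-style covariates are discretized measurements and this is the
  intended behaviour.
* **Coding**: categorical covariates are treatment-coded against the most
  frequent level; numeric covariates are standardized (mean 0, sd 1)
  within the stratum for conditioning, and reported coefficients are on
  that scale (stated in the output metadata).
* **Fitting**: maximum likelihood by iteratively reweighted least squares
  (`stats::glm.fit`, convergence tolerance 1e-8, at most 100 iterations).
  Rank-deficient designs are an error naming the collinear terms. Perfect
  or quasi-separation — a fitted probability within 1e-10 of 0 or 1
  together with a coefficient magnitude above 10 — is flagged and the fit
  excluded, rather than "rescued" by penalization: the package reports the
  stated model or nothing. Families whose presence is constant within a
  stratum are skipped (there is nothing to fit); the skip shares the
  `SKIPPED_INELIGIBLE` status with failed eligibility, keeping the status
  vocabulary closed.
* **Inference**: Wald t statistics (coefficient / SE) with Student t
  reference on `n - p` degrees of freedom — t rather than normal z because
  the per-stratum sample sizes are modest. Benjamini–Hochberg correction
  (`stats::p.adjust`) is pooled across families within each
  (stratum, covariate) pair, the narrowest pool consistent with fitting
  separate models per stratum; a single global pool is available as
  `fdr_pool = "global"` without endorsement. Only covariate terms are
  reported and pooled; adjustment terms are nuisance.

Samples are treated as independent observations. Repeated visits from one
subject violate this; the output metadata carries the caveat, and
mixed-effects modelling is out of scope.

## The synthetic testbed

The generator emulates the *structure* of a family catalog plus two
metagenome cohorts at toy scale, not their biology:

* Sequences are i.i.d. uniform over the 20 standard amino acids, at
  lengths drawn around 250 aa (typical full-length bacterial proteins);
  within-family homology is simulated by single-residue substitutions of a
  family ancestor. This suffices because no operation in the package
  measures similarity other than exact equality.
* Families are planted in four classes — passing + annotated, passing +
  unannotated + broad (the planted FUnkFams, guaranteed to span two
  classes), passing + unannotated + narrow (one class), and failing (too
  few unique, or 3 of 4 members truncated). Annotated families have one
  member copied verbatim into a database with a domain accession; one
  narrow family also matches a domain-less database entry, exercising the
  recorded-but-not-annotating rule.
* Two environments (`ENV_A`, `ENV_B`) with balanced binary covariates;
  presence follows per-family logistic models with environment affinity;
  planted covariate effects are symmetric log-odds contrasts
  (±beta/2 around the family baseline), so the group log-odds difference
  is exactly beta and neither group saturates. Accepted reads have
  identity ≥ 99% and whole-read alignments; decoy hits (sub-threshold
  identity or short alignments) and duplicate lower-scoring hit rows are
  injected and must never change counts. Genome equivalents are drawn
  uniformly in 5–50, read length is 100 bp.
* One seed determines every emitted data byte; the ground-truth manifest
  records expected filter decisions, annotation flags, breadth counts, the
  FUnkFam set, and per-(family, sample) accepted-read counts.

What passing tests show: the pipeline's bookkeeping is exact (counts,
presence, selection all match ground truth bit-for-bit), its boundary
behaviour matches the stated thresholds, and its statistics are calibrated
on data that satisfy the model's assumptions. What they do not show:
robustness to real-data pathologies — homologous but non-identical
database entries, variable read lengths, chimeric alignments, lineage
errors, population structure among samples — none of which the generator
emulates.

## Problem sizes and calibration

The default fixture is 20 families (5 planted FUnkFams) profiled in 2 × 10
samples — small enough that an end-to-end run takes a few seconds, yet
every planted feature is exercised. Association calibration and power use
dedicated presence-level simulations of 200 families × 100 samples over 20
seeded replicates: under the null the raw p < 0.05 rate sits inside the
99% binomial band around 0.05 and q < 0.05 discoveries are (essentially
always) zero; a planted log-odds-3 effect is recovered with the correct
sign at q < 0.05 in ≥ 19/20 replicates. A Wald power analysis explains the
scale: with a 200-family BH pool the rank-1 discovery threshold is
p ≈ 2.5 × 10⁻⁴, so a log-odds-2 effect at n = 100 (Wald z around 4.4)
is detected only ~70–80% of the time — recovery claims in this package are
therefore stated at effect size 3, and weaker effects at this sample size
should be expected to need larger strata or wider pools.

## Known limitations

* Annotation screening is exact-match only; it answers "has this exact
  protein been annotated", not "can this family be annotated".
* Whole-read coverage relies on a single per-sample read length; mixed
  read lengths within a sample are not representable in m8 input.
* The entropy pre-filter quantile is computed among the families given to
  it (the selected FUnkFams in the pipeline), so adding families changes
  the cut.
* FDR pooling granularity materially affects q-values; both provided
  poolings are defensible and neither is canonical.
* Repeated-measures designs are not modelled.
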