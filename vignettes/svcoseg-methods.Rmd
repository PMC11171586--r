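---
title: "svcoseg: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svcoseg: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcoseg)
```

## The question the package answers

Multiplex families — several affected relatives, sequenced together with
unaffected members — let one filter variants by *co-segregation*: a variant
carried by every affected member and by no obligate non-carrier. Any pedigree
will produce such variants by chance, so the filter must be paired with a
null model that says how often a neutral variant would show the same pattern.
`svcoseg` implements both halves: the filtering pipeline over structural
variant (SV) call sets, and the null probabilities.

## The null transmission model

`p_seg_enumerate()` conditions on the variant having entered the family
through exactly one founder, as a single heterozygous copy, with all other
founders non-carriers. Every parent-to-child transmission then passes the
allele independently with probability 1/2 (autosomal Mendelian gene
dropping). P(seg) for a segregation scheme is the probability that the
resulting carrier set among genotyped individuals contains all obligate
carriers and excludes all obligate non-carriers; unconstrained members
(e.g. a permitted asymptomatic carrier) are ignored.

Assumptions worth stating explicitly:

* **Single origin.** Two independent introductions of the same variant into
  one family are ignored; for the rare variants the pipeline prioritizes this
  is the overwhelmingly dominant case.
* **Origin founder unknown.** The published convention this package follows
  reports the *maximum* over candidate origin founders — the most favorable
  origin — which reproduces the (1/2)^(informative meioses) pattern of
  published per-family values (0.250 = 2^-2 down to 0.000976 = 2^-10). The
  per-founder vector is returned alongside for anyone wanting a different
  aggregation (e.g. averaging over founders).
* **Autosomal only.** All transmissions are Bernoulli(1/2); X-linked dosage
  is not modeled. Sex is carried in the pedigree but never used by the
  engine.
* **No penetrance or phenocopy model, no genotyping error.** The scheme is a
  hard constraint; softening it is the job of the unconstrained set, not of
  probabilities.

Exact enumeration uses depth-first recursion over the allele counts of
non-founders in pedigree order, branching only on meioses from carrier
parents and pruning a branch the moment a constrained individual's final
count violates the scheme. The default cap is 22 meioses (2^22 ≈ 4M raw
outcomes; pruning visits far fewer), which covers families of the size of
the motivating study (4–14 genomes). Above the cap, `p_seg_montecarlo()`
simulates `n_draws` gene drops per founder (binomial standard error
reported); `p_seg()` picks the method automatically.

## The composite statistics

* Single-family exonic: `P(obs) = P(seg) × P(exvar)`, with `P(exvar)` the
  study-wide fraction of SVs that are exonic (coding exon or UTR;
  `estimate_p_exvar()`); 0.0388 in the motivating study. Single-family
  *non-exonic* candidates get `NA` — with thousands of non-coding SVs per
  genome, a single-family non-coding co-segregation is unremarkable and the
  statistic is defined only for the exonic subset.
* Multi-family, k of F families: `P(obs) = ∏ P(seg_i) × P(anyvar) ×
  maf^(k−1) × C(F, k)` where `maf` is the control carrier fraction and
  `C(F, k)` (`bonferroni_factor()`) corrects for the number of family
  combinations that could have shown the recurrence.

Two design points here were genuinely open:

* **P(anyvar).** The source convention defines it as one minus the
  probability of a variant in the first family with frequency below 5%,
  which is not computable from published quantities; recomputing the
  published multi-family values shows they are reproduced exactly with
  P(anyvar) = 1. The package therefore defaults to 1.0 and exposes the
  factor as an argument.
* **maf = 0.** For a variant absent from controls the recurrence frequency
  has no estimate, and the published values for such rows imply an unstated
  effective frequency we cannot derive. Default policy: report `NA`; a
  substitute can be supplied via `zero_maf_pvar`.

### Rounding

Reported probabilities use `round_pobs()`: half-away-from-zero at 4 decimal
places, falling back to one significant digit below 0.0001 (so 0.00485 →
0.0049 and 3.6e-05 → 4e-05), matching the mixed precision conventional in
published tables. Published sources are not perfectly self-consistent here —
one worked example requires rounding an exact half up while two others were
evidently truncated (0.10416… printed as 0.1041). We use one deterministic
rule rather than per-row mimicry; the one-ulp consequences are documented in
the test suite.

## The filtering pipeline

* **Clustering** (`cluster_svs()`): two calls are "the same variant" when
  they share chromosome and type and meet the `match_params()` criteria —
  reciprocal overlap ≥ 0.5 *and* both breakpoints within 50 bp for
  DEL/DUP/INV; breakpoint distance ≤ 50 bp and length ratio ≥ 0.5 for
  insertions. Clusters are connected components (single linkage), so
  membership is independent of input order; identical calls are deduplicated
  into sites first, which changes nothing semantically but makes the
  pairwise stage scale with distinct coordinates. Breakends (BND) are kept
  as flagged singletons. The source study did not state its cross-sample
  matching rule; these defaults follow common SV-merging practice and are
  fully exposed.
* **Frequency** (`control_frequency()`): carrier individuals over control
  individuals — forced by the published "(1/102)" convention with 102
  control subjects; despite the column label "MAF" the arithmetic is
  per-individual, not per-allele. Controls without a call count as
  non-carriers, so frequencies are lower bounds. Tier boundaries are strict
  (`<1%`, `<5%`): 1/102 = 0.98% is RARE, an exact 1% is UNCOMMON.
* **Scheme evaluation** (`evaluate_scheme()`): missing genotypes at obligate
  positions fail by default (a strict reading of "all patients");
  `missing_as_unknown` relaxes obligate non-carriers only, never carriers.
  Multiple schemes per family combine by OR.
* **Annotation** (`classify_context()`): strand-agnostic overlap on the
  inclusive span, insertions by their single insertion point; precedence
  coding exon > UTR > intron > intergenic across all overlapped genes, all
  gene names kept with the max-precedence one marked primary. Exon/intron
  numbering uses the transcript with the most exonic bases, numbered 5'→3'
  on the transcript strand. Exons of CDS-less transcripts count as
  non-coding exonic (reported as 3'UTR) — a fallback chosen so that
  "exonic" for P(exvar) means the same thing everywhere.

## The synthetic cohort generator

`simulate_cohort()` states the world the tests run in; its defaults are the
motivating study design, not tuning knobs:

* 17 families; per-family genome counts drawn from the published family
  sizes (4–14, mean 7.3 — so cohorts average ≈124 genomes); ≥2 affected per
  family (multiplex) with phenotypes produced by an actual fully penetrant
  single-founder gene drop, so every family's default scheme is satisfiable
  by construction.
* 102 unrelated controls.
* 300 background SVs per genome — deliberately ~1/9 of the study's 2726 per
  genome so the full pipeline runs in seconds; the panel size is calibrated
  so the *expected* per-genome call count hits the target given the
  frequency spectrum.
* Type mix DEL/DUP/INV/INS = 154/34/11/7 (normalized), the published
  uncommon-candidate composition.
* Founder allele frequencies from Beta(0.2, 1.8) (mean 0.1, strongly
  rare-skewed) — a conventional shape for an SV site-frequency spectrum.
* 5 injected truth variants, heterozygous in exactly the obligate carriers
  of their family, absent from controls and from every other family, placed
  inside synthetic genes to hit configured contexts (coding exon, 3'UTR,
  intron, intergenic).
* A 5 × 10 Mb synthetic genome; no reference download.
* Per-file breakpoint jitter (≤10 bp) on background variants when writing
  VCFs, so cross-sample clustering is actually exercised.

What the generator does *not* emulate: realistic SV length spectra,
repeat-context placement, caller false negatives/positives, genotyping
error, population structure in controls. A green end-to-end test therefore
establishes that the pipeline's logic recovers planted signal and respects
tier boundaries — not that it is robust to caller noise.

One test-design note: the type-mix goodness-of-fit invariant is evaluated
family-wise across its 10 seeds (Bonferroni), because ten independent
chi-square tests each at α = 0.01 would falsely reject a correct generator
with ~10% probability by construction.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout (VCF convention); insertions
  carry `end = pos` and their inserted length in `svlen`; deletions carry
  negative `svlen`.
* `END` missing on an interval variant is inferred as `pos + |SVLEN|`;
  records with neither are skipped with a warning.
* Scheme files and CLI configs are JSON (`jsonlite`); no YAML parser is part
  of the package's dependency footprint.
* All randomness flows from a single seed; seeded helpers save and restore
  the caller's RNG state. VCF, GFF3, PED and report writers emit bytes
  deterministically (binary connections, fixed ordering), so identical seeds
  give identical files.
* Cluster ids are assigned after sorting by consensus coordinates, which is
  what makes clustering permutation-invariant down to the identifier level.

## Known limitations

* P(seg) maximizes over a single unknown origin founder; pedigrees with
  strong inbreeding loops are handled correctly by the engine (allele counts
  are tracked, not just carrier flags) but the single-origin conditioning
  itself becomes questionable there.
* The per-family probabilities of the motivating publication cannot be
  recomputed directly because its pedigree structures are not public; the
  engine is validated against a brute-force enumeration oracle and by the
  reachability of the published power-of-two values instead.
* Multi-family P(obs) treats the control carrier fraction as a known
  frequency; its sampling error (k/102) is not propagated.
* Enrichment analysis is out of scope by design: the pipeline exports gene
  lists for external tools and computes nothing downstream of them.
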