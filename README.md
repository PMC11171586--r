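# svcoseg

Familial co-segregation analysis of structural variants (SVs) in multiplex
pedigrees.

## The problem

In families with several members affected by a heritable condition (the
motivating design: 17 multiplex tic-disorder families, 124 sequenced genomes,
102 unrelated controls), a variant shared by every affected member and absent
from unaffected obligate non-carriers is a candidate risk allele — but any
pedigree will show some co-segregating variants by chance. `svcoseg`
implements the full prioritization pipeline for whole-genome SV call sets and
quantifies how surprising each co-segregation observation is under neutral
Mendelian transmission.

The pipeline stages:

1. **Ingestion** — per-family and control SV VCFs (`SVTYPE`/`END`/`SVLEN`,
   symbolic ALTs) via `read_sv_vcf()`.
2. **Clustering** — cross-sample single-linkage matching (50% reciprocal
   overlap, ±50 bp breakpoints by default) via `cluster_svs()`, so "the same"
   SV can be tracked across genomes.
3. **Frequency tiering** — control-cohort carrier frequency
   (`control_frequency()`, carrier individuals / control individuals) mapped
   to tiers ABSENT (0%), RARE (<1%), UNCOMMON (<5%), COMMON (≥5%) by
   `assign_tier()`.
4. **Scheme filtering** — `evaluate_scheme()` accepts a cluster in a family
   iff every obligate carrier (by default, every genotyped affected member)
   has ≥1 alternative allele and no obligate non-carrier has any.
5. **Annotation** — genomic context (coding exon, 5'/3' UTR, intron,
   intergenic) against GFF3/GTF gene models.
6. **Statistics** — null co-segregation probabilities and composite P(obs).

## The statistics

**P(seg)** — the probability, under the null that the variant entered the
family through a single heterozygous founder and every meiosis transmits it
independently with probability 1/2 (gene dropping), of observing exactly the
family's accepted carrier pattern. Computed exactly by enumeration
(`p_seg_enumerate()`, up to 22 meioses) or by Monte Carlo
(`p_seg_montecarlo()`); the unknown origin is handled by maximizing over
founders. For a fully informative pedigree this is (1/2)^m with m informative
meioses.

**Single-family exonic P(obs)** = P(seg) × P(exvar), where P(exvar) is the
study-wide fraction of SVs that are exonic (0.0388 in the motivating study).

**Multi-family P(obs)** for a variant co-segregating in k of F families with
control carrier fraction `maf`:

    P(obs) = ∏ᵢ P(seg, famᵢ) × P(anyvar) × maf^(k−1) × C(F, k)

with P(anyvar) = 1 by default and the binomial coefficient C(F, k) the
Bonferroni correction over family combinations (`bonferroni_factor(17, 2)` =
136, `bonferroni_factor(17, 3)` = 680).

## Worked example

```r
library(svcoseg)

# family J: P(seg) = 0.250 (from study_overview()), exonic deletion
p_obs_single(0.250, 0.0388)$p_obs
#> [1] 0.0097

# deletion shared by families G and H, 2/102 control carriers
r <- p_obs_multi(c(0.250, 0.125), maf = 2/102, n_families_total = 17)
round_pobs(r$p_obs)
#> [1] 0.0833
r$bonferroni
#> [1] 136
```

`0.0097` is the chance that some exonic variant co-segregates in family J by
luck alone; `0.0833` is the corrected chance of the same variant
co-segregating in both G and H given its control frequency — small values
flag variants unlikely to co-segregate by chance.

End-to-end on synthetic data with known truth:

```r
sim <- simulate_cohort(sim_config(), seed = 1)   # 17 families, 102 controls
found <- find_candidates(cluster_svs(cohort_records(sim)),
                         sim$pedigrees, sim$schemes, sim$control_ids)
found$summary          # type x nested-tier counts (uncommon >= rare >= absent)
```

Or from the command line (simulate → run → reports):

```sh
Rscript exec/svcoseg simulate --seed 7 --out sim/
Rscript exec/svcoseg run --family-vcfs sim/ --control-vcfs sim/controls.vcf \
    --ped sim/cohort.ped --schemes sim/schemes.json --gff sim/genes.gff3 \
    --out out/ --p-exvar 0.0388 --total-families 17
```

`out/` then contains `family_overview.tsv` (per-family P(seg)),
`exonic_candidates.tsv`, `multifamily_candidates.tsv` and `gene_list.txt`.

## Vignette

`vignettes/svcoseg-methods.Rmd` documents the model and its assumptions, the
synthetic-data generator, numerical choices (rounding, tie-breaking,
enumeration caps) and known limitations.
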