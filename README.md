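# MRDassoc

Genomic association analysis stratified by measurable residual disease (MRD)
for *ETV6::RUNX1* childhood B-cell acute lymphoblastic leukemia.

In this leukemia subtype, the fraction of residual blasts in bone marrow —
measured at mid-induction (~day 15), end of induction (EOI, ~day 29) and end
of consolidation (EOC, ~day 79) — is the established predictor of relapse
risk, but no genomic biomarker of therapy response is in routine use.
`MRDassoc` implements the statistical machinery for finding such markers in
a multi-omic cohort: it classifies patients into response groups from their
MRD values, then asks which copy-number variants, gene mutations, mutational
signatures and expression programs differ between fast and slow responders.

The package is aimed at statistical genomics analysts working with cohort
data of this shape (per-patient MRD values, CNV segment calls from one or
more assays, somatic SNV/InDel calls, expression counts). Because such
cohorts are access-restricted, every stage is exercisable on a bundled,
seeded synthetic-cohort generator that plants known effects.

## Methods at a glance

* **Response groups.** On the fraction scale, mid-induction: fast iff
  MRD < 0.10; EOI: slow iff MRD ≥ 0.001, fast iff MRD = 0, intermediate
  between; EOC: negative iff MRD = 0. Dichotomies (slow vs rest, fast vs
  rest, EOC positive vs negative, mid slow vs fast) drive all two-group
  tests.
* **CNV association.** Deletions/gains > 1 Mb are retained after ENCODE-style
  blacklist filtering (removal when ≥ 50 % of a segment overlaps blacklist),
  multi-assay calls are harmonized so each patient contributes one source
  (WGS > array > panel), and per-locus carrier status (≥ 1 bp overlap) is
  tested against the dichotomy. Significance comes from an empirical p-value:
  in each of *B* iterations the segment coordinates are re-drawn uniformly
  within their chromosome arm **and** the group labels are permuted, the
  per-locus statistic (absolute carrier-fraction difference) is recomputed,
  and *p* = (1 + #{null ≥ observed}) / (*B* + 1).
* **Mutation prevalence.** Per gene, carriers (patients with ≥ 1 coding,
  non-synonymous SNV/InDel) are compared across the dichotomy with a
  two-sided Fisher's exact test (DNA-level significance threshold 0.1);
  CRISPR-screen hit sets are tested via deletion burden (rank-sum and
  any-hit Fisher) with a random-gene-set empirical p.
* **Mutational signatures.** SNVs are binned into the 96 pyrimidine-strand
  trinucleotide channels from a reference FASTA, exposures are refit against
  a signature catalog by non-negative least squares
  (min ‖y − Sw‖₂, w ≥ 0), and contribution fractions are correlated with
  MRD (Spearman).
* **Expression.** log₂(CPM + 1) normalization; gene-set module scores
  against expression-matched control genes (S-phase, G2M, regulons) with a
  label-permutation empirical p against MRD; per-gene Welch tests of copy-
  number dosage on expression with BH-FDR tiers and a concordance filter
  (deletion → lower, gain → higher expression; RNA-level threshold 0.05).

## Worked example

```r
library(MRDassoc)

# a seeded synthetic cohort at study scale (358 patients)
bundle <- simulateCohort(simConfig(seed = 11))
bundle$cohort
#> MRDCohort with 358 patients
#>   mid: fast=313 slow=45 (0 missing)
#>   eoi: fast=116 intermediate=158 slow=84 (0 missing)
#>   eoc: negative=306 positive=52 (0 missing)

# CNV filtering, harmonization, and the within-arm randomization test
segs <- harmonizeAssays(filterSegments(bundle$segments, bundle$annotation),
                        assays = patientAssays(bundle$cohort))
grp  <- dichotomize(bundle$cohort, "fast_vs_rest")
res  <- cnvEmpiricalP(segs, geneLoci(bundle$annotation), grp,
                      bundle$annotation, cnv_type = "del",
                      B = 1000, seed = 3)
res[res$locus == "KRAS", ]
#>     locus carriers_a carriers_b n_a n_b  observed empirical_p
#> 109  KRAS         52         23 116 242 0.3532345 0.000999001
```

The generator plants a 12p deletion in 45 % of fast vs 10 % of slower
responders; the locus covering *KRAS* shows a carrier-fraction difference of
0.35 and the smallest attainable empirical p at B = 1000 (1/1001). Signature
exposure and gene-set scoring behave analogously:

```r
fit <- fitExposures(countContexts(bundle$snvs, bundle$reference),
                    syntheticSignatureCatalog())
exposureMrdCorrelation(fit, bundle$cohort, "mid")
#>   signature        rho            p  n
#> 1      SBS1  0.6838235 1.149180e-05 33
#> 2      SBS2 -0.5982620 2.357025e-04 33
#> ...
```

The APOBEC-like SBS2 exposure falls with rising mid-induction MRD (fast
responders carry more APOBEC signal), while the clock-like SBS1 rises —
the planted directions.

A full run of every stage, written as TSVs plus a JSON manifest:

```r
runPipeline(pipelineConfig(out_dir = "results/run1", seed = 42))
```

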