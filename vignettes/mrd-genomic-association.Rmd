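---
title: "MRD-stratified genomic association: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRD-stratified genomic association: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MRDassoc)
```

# The analysis problem

*ETV6::RUNX1* B-cell acute lymphoblastic leukemia responds well to induction
chemotherapy on average, yet the minority of slowly clearing cases carries
most of the relapse risk. Measurable residual disease (MRD) — the fraction
of leukemic blasts remaining in bone marrow at fixed treatment days — is the
clinical readout of that clearance. `MRDassoc` provides the statistics for
asking which somatic genomic features, present at diagnosis, separate fast
from slow responders: copy-number variants (CNVs), gene mutations,
mutational-signature exposures, and transcriptional programs.

This vignette documents the models behind each stage, the tunable
parameters with their defaults and units, what the synthetic-cohort
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical claim that the test
suite does not itself compute.

# Response-group model

MRD is stored as a fraction in $[0, 1]$; percent-scale files must be
converted at the I/O boundary (one internal scale avoids threshold bugs).
The classification rules, with all boundaries closed exactly as written,
are:

| timepoint | groups |
|---|---|
| mid-induction (~day 15) | fast iff MRD $< 0.10$; slow iff MRD $\ge 0.10$ |
| end of induction (~day 29) | slow iff MRD $\ge 0.001$; fast iff MRD $= 0$; intermediate otherwise |
| end of consolidation (~day 79) | negative iff MRD $= 0$; positive otherwise |

A missing MRD value yields a missing label and silently excludes the
patient from that timepoint's analyses (cohort sizes legitimately differ by
timepoint); only out-of-range values are errors. Discordant MRD assays for
one patient are assumed reconciled upstream — the input table carries one
value per timepoint.

Two-group splits are named schemes (`dichotomize`): `slow_vs_rest` and
`fast_vs_rest` on the EOI three-group classification, `mid_slow_vs_fast`,
and `eoc_pos_vs_neg`.

# CNV association

**Filtering.** A segment qualifies as a CNV when strictly longer than
`min_len_bp` (default $10^6$ bp) and when less than
`max_blacklist_overlap` (default 0.5) of its length lies in blacklist
intervals. The 50 % blacklist rule is a package choice — the filtering
convention in this field states only that blacklist-overlapping calls are
excluded, without a fraction — and it is exposed as a parameter. Filtering
is idempotent and logs removal counts per reason.

**Harmonization.** When a patient has CNV calls from several assays, only
the highest-priority source is used (default `wgs > array > panel`, in
decreasing resolution order), so each patient contributes exactly once.

**Carrier rule.** A patient carries a (locus, type) feature when any
segment of that type overlaps the locus by at least 1 bp. No reciprocal-
overlap fraction is imposed; with > 1 Mb segments and ~100 kb gene models,
1 bp overlap is effectively gene-touching. Coordinates follow the BED
convention on disk (0-based half-open) and `GRanges` in memory; an abutting
segment does not overlap.

**The within-arm randomization null.** For each locus the statistic is the
absolute difference in carrier fraction between the two response groups
(`freq_diff`; a per-locus Fisher p is available as `fisher_p` but costs a
2×2 exact test per locus per iteration). In each of $B$ iterations the
segment start positions are re-drawn uniformly over all placements that
keep each segment inside its original chromosome arm — preserving patient,
arm, length and type exactly — *and* the group labels are permuted. The
empirical p-value uses add-one smoothing,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, so it is never zero and
never understates the resolution of $B$. Coupling both randomizations in
the same iteration is the default because the null being rejected is "this
locus's carrier pattern could arise from generic arm-level CNV pressure
placed anywhere, in anyone"; `randomize = "labels"` and `"coords"` are
available as diagnostic nulls. $B$ defaults to 1000 (the smallest
attainable p is then $1/1001$); the statistic and $B$ are parameters
because neither is canonical.

Two degenerate cases are handled explicitly: a segment longer than its arm
is pinned to the arm bounds with a warning (it has a single feasible
placement), and a segment spanning exactly its arm keeps its position.
Loss-of-heterozygosity segments are carried through I/O but excluded from
deletion/gain association.

**Locus sets.** For association, loci default to gene intervals flagged as
expressed (testing response association only where an expression
consequence is observable); for frequency-curve displays, fixed 1 Mb bins
tile a chromosome.

# Mutation prevalence and screen sets

Variants are reduced to carrier indicators per (patient, gene) after
keeping coding, non-synonymous classes (missense, nonsense, frameshift,
splice, in-frame indel — the whitelist is configurable because "predicted
impact on protein function" admits several operationalizations). The
two-sided Fisher exact test uses the "sum of hypergeometric probabilities
≤ that of the observed table" convention; one-sided variants are available
by flag since the sidedness convention in published analyses of this kind
is often unstated. DNA-level tests are read at the 0.1 threshold, and BH
q-values are reported alongside raw p.

CRISPR-screen hit sets (top-100/top-200 by rank or FDR < 0.25) are tested
two ways: per-patient counts of deleted screen genes across the dichotomy
(rank-sum on mid-ranks; exact enumeration below 12 total observations,
normal approximation with tie correction above), and any-hit carrier
status (Fisher). A random-gene-set empirical p draws $B$ sets of the same
size uniformly without replacement from the gene universe — by default the
genes with at least one observed deletion, to avoid padding the null with
undeletable genes — and compares the any-hit fraction difference.

# Mutational signatures

Catalogs are 96-channel counts over pyrimidine-strand trinucleotide
contexts in the conventional order (six substitution classes × 16 flanks,
alphabetical within class). Purine-reference SNVs are reverse-complemented
before binning; reference mismatches, contig-edge positions and unknown
contigs are record-level errors, collected and reported, never fatal.

Exposure refitting solves $\min_w \|y - Sw\|_2,\ w \ge 0$ per sample
(Lawson–Hanson NNLS) and reports contribution fractions $w/\sum w$ plus a
cosine-distance reconstruction residual. NNLS is deterministic and
testable; the sparsity-seeking assignment heuristics of dedicated
signature-assignment tools are intentionally not reproduced, because the
downstream quantity of interest here is the exposure–MRD correlation, not
per-case attribution. A zero catalog yields zero exposures with a flag
rather than an error.

The package ships `syntheticSignatureCatalog()`, a *synthetic* stand-in
catalog whose five columns carry the headline channel structure of the
signatures relevant in this leukemia (clock-like C>T at NpCpG; APOBEC-like
C>T and C>G at TpCpN; a broad C>A signature; a flat background). It is for
simulation and testing; real catalogs load through `readSignatures`, which
matches rows by context label so any row order is accepted.

# Expression scoring

Normalization is $\log_2(1 + \mathrm{CPM})$ with library size = column
sum. No compositional (TMM-style) correction is applied — a deliberate
simplification adequate for the within-gene, between-group contrasts made
here; analyses sensitive to composition should normalize upstream.

Gene-set scores use expression-matched controls: genes are ranked into
`n_bins` (default 25) bins of average expression; each set member is
compared to `n_ctrl` (default 50, capped at bin size) control genes drawn
from its bin with all set members excluded from the candidate pool. The
member exclusion matters: with it, a set uniformly upshifted by +1 in a few
samples scores ≈ +1 there; without it, controls leak signal and the score
is biased low. A second, smaller attenuation is inherent to bin matching:
when many samples share the shift, the members' average expression — the
binning variable — itself rises, controls are matched to that higher
average, and part of the shift is absorbed (e.g. a +1 shift in 10 % of
samples costs ≈ 0.1 of score). Scores of random sets on exchangeable data
center at zero. The control draw is seeded.

Score–MRD association reports the Spearman correlation (mid-ranks, t
approximation for p) plus a label-permutation empirical p on $|\rho|$ with
$B$ permutations of the MRD values across samples.

Copy-number dosage tests use Welch's two-sample t-test per gene, altered
(the gene's dominant alteration; ties favour deletion) versus copy-neutral
samples, with BH-FDR across tested genes and the reporting tiers
q < 0.01 / 0.05 / 0.1. Genes lacking two samples in both states are
skipped and logged. A moderated (empirical-Bayes) linear model would gain
power at very small group sizes; Welch was chosen as assumption-light and
sufficient at the cohort sizes targeted here. The post-filter
`selectExpressedCnvGenes` keeps genes whose mean normalized expression
reaches `floor` (default: mean log2(CPM+1) ≥ 1 in at least one response
group — the floor is a package choice, since "lowly expressed" has no
canonical cutoff) and whose effect sign is concordant with the CNV
direction.

# The synthetic cohort generator

`simulateCohort` produces a complete bundle — MRD table, per-assay CNV
segments, variant calls, per-sample SNV lists with a reference FASTA,
expression counts, gene sets, screen rankings, and a truth file recording
every planted parameter — deterministically from one seed (stage seeds are
derived from it, so stages are individually reproducible).

**MRD model.** One latent severity $z_i \sim N(0,1)$ per patient; at each
timepoint the correlated quantile $u = \Phi(0.8 z + 0.6\varepsilon)$ maps
to MRD $= 0$ below a point mass $p_0$ and through a log-normal tail above
it, capped at 1. Defaults target the EOI composition 116 fast / 156
intermediate / 84 slow per 356 — the group sizes of the cohort this
analysis design is meant for — via $p_0 = 116/356$ and a tail placing 35 %
of positives at or above 0.001. Mid-induction defaults put ~15 % of
patients at MRD ≥ 0.10 and EOC ~15 % positive, chosen once as realistic
for this disease.

**CNVs.** Four planted recurrent regions with EOI-group-dependent carrier
probabilities: a 25 Mb 12p deletion (fast 0.45, others 0.10), a short
proximal 12 Mb 12p gain (slow 0.40) mirroring the derivative-chromosome
gain that presents as a short 12p gain, a 9q deletion and a 21q gain
(slow-enriched). Breakpoints jitter ±1 Mb within the arm. Background
segments are Poisson per patient (rate 3, matching the few-CNVs-per-genome
character of this subtype), log-uniform lengths 0.3–8 Mb straddling the
1 Mb filter so size filtering is exercised, uniform within arms, with 5 %
centred inside blacklist intervals so blacklist filtering is exercised.
Patients draw assay sets (WGS ≈ 9 %, array 25 %, panel 75 %) and segments
are emitted once per assay so harmonization is exercised.

**Mutations.** Planted per-gene carrier probabilities per dichotomy follow
the prevalence contrasts reported for this disease (e.g. ARID5B 0.059 vs
0.010 mid-induction; NF1 0.111 vs 0.013 at EOC), plus Poisson passenger
variants including synonymous and non-coding calls so functional filtering
is exercised.

**Signatures.** Exposure fractions are
$\max(0.01,\ \text{base} + \text{slope}\cdot z_s + N(0, 0.06))$
normalized, where $z_s$ standardizes $-\log_{10}(\text{MRD}_{mid} +
10^{-6})$ ($\varepsilon = 10^{-6}$ handles MRD $=0$). The APOBEC-like
slopes are positive (more exposure in fast responders), clock-like
negative. The noise term gives inter-patient exposure variability beyond
the MRD link; without it, correlations would be near ±1 rather than the
moderate values real cohorts show. Mutation counts are log-normal around
1900 per genome; channel counts are multinomial from the mixed profile and
each SNV is materialized at a reference position whose trinucleotide
matches its channel on either strand, so context counting round-trips
exactly.

**Expression.** Negative-binomial counts (dispersion size 8) with
log-normal baseline means; genes under a deletion/gain are scaled by
$2^{\mp 1}$ per the dosage effect (default −1/+1 log2 unit per lost/gained
copy); S-phase and G2M programs shift by loading × $z_s$ (0.5 and 0.25
log2 units per SD) plus $N(0, 0.8)$ MRD-independent program activity —
again so the score–MRD correlation is moderate, not deterministic.

**What it does not emulate** — and hence what passing tests do not show
about real data: breakpoint microhomology and RAG-motif structure,
subclonal heterogeneity, batch and library-size artefacts, assay-specific
resolution differences (all assays see identical true segments),
linkage between mutation burden and CNV burden, and compositional effects
in counts. The toy genome has three chromosomes at realistic Mb scale but
a sparse, evenly spaced gene map; real annotation loads through the same
readers.

**Coordinate space vs sequence.** CNV analysis needs only coordinates, so
the toy genome carries no sequence; the mutational-signature stage uses a
separate ~120 kb synthetic FASTA as its coordinate space, long enough that
all 32 pyrimidine-strand contexts occur thousands of times. Materializing
hundreds of Mb of sequence would add nothing statistically.

# Numerical choices and problem sizes

* Empirical p-values always use add-one smoothing; ties count as extreme
  (conservative).
* Exact rank-sum enumeration up to 12 total observations (924 subsets at
  the cap); beyond, normal approximation with mid-rank tie correction.
* Spearman p from the t approximation; $|\rho| = 1$ returns p = 0 rather
  than an overflow.
* The Fisher two-sided p uses the conventional "probability ≤ observed"
  rule with the standard $1 + 10^{-7}$ relative tie tolerance.
* The NNLS residual is reported as cosine distance, 0 whenever the catalog
  lies in the non-negative column span of the signatures.
* Test-suite problem sizes were chosen to make each statistical property
  measurable at desk scale: calibration at 200 patients × 200 loci ×
  B = 500; power at 20 replicates × B = 1000; signature round-trips at 30
  samples × 2000 mutations; dosage recovery at 25 samples per copy-number
  state. The default pipeline run (358 patients, B = 1000) completes in a
  few minutes on one CPU and is byte-reproducible under a fixed seed.

# Known limitations

* The calibration of the coupled coordinate+label null is exact only when
  true segment placement is exchangeable within arms; strongly recurrent
  breakpoints (which the generator plants deliberately) make the null
  narrower than the data at those loci — that is the intended test, but it
  means the empirical p is a measure of "recurrence + group linkage", not
  group linkage alone. The `randomize = "labels"` diagnostic isolates the
  latter.
* Welch t on log-CPM ignores count-level mean–variance structure; at very
  low counts a negative-binomial model would be preferable.
* The screen-set burden analysis treats screen rankings as fixed
  annotation; uncertainty in the screen itself is not propagated.
* One marker at a time: no multivariate or joint classifier is fitted.
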