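---
title: "Methods: serial ctDNA clonal monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial ctDNA clonal monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaclone)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the assumptions behind them, the tunable
parameters and their defaults, what the bundled simulator does and does not
emulate, and the numerical and design choices that were genuinely open.

## Setting and data model

The package targets longitudinal plasma sequencing of treated cancer
patients: per patient, a baseline (day 0) and serial on-treatment samples
every 2-5 weeks, each yielding somatic variant calls from an ultra-deep
(~3000x deduplicated) targeted panel (default 637,000 bp across 329 genes).
A call is a `chrom:pos:ref:alt` key with alt/ref read counts; the VAF is
always recomputed as `alt / (alt + ref)` from the counts and never taken
from a caller's `AF` field. Coordinates are 1-based as in VCF throughout;
multi-allelic records are split into one call per ALT with positionally
matched allelic depths, which keeps per-variant VAFs well defined. Calls
below a total depth of 100 (configurable; a loose floor given the ~3000x
design) are dropped at parse time.

Upstream steps — trimming, alignment, deduplication, raw variant calling,
copy-number segmentation — are out of scope: the pipeline starts at variant
calls, and consumes copy number only as a per-variant logR annotation.

## Filter cascade

Somatic status is decided by four steps, in a fixed order, per patient:

1. **Common germline.** A variant whose maximum population allele frequency
   across the consulted databases is at least `af_threshold` (default
   0.001, i.e. 0.1%, inclusive) is removed. Variants absent from the
   database are kept — the panel is small and the database lookup is a
   blacklist, not a whitelist.
2. **Matched normal.** A variant with more than `max_normal_reads`
   (default 2) alt reads in the patient's white-blood-cell library is
   removed. This step absorbs both residual germline variants and clonal
   hematopoiesis; no separate CHIP classifier exists, because WBC evidence
   is the direct measurement for both.
3. **Private germline.** A variant detected (alt reads > 0) at *every* one
   of the patient's time points with VAF strictly above `vaf_threshold`
   (default 0.20) at every time point is removed from all samples. The
   all-time-points condition is essential: a variant absent, or at low VAF,
   at any single time point cannot be germline, and absence anywhere vetoes
   removal. Removal is patient-global, since a germline call cannot be
   somatic at another time point. With a single time point the rule still
   applies and a caution is logged. Using the patient-combined series
   instead of a per-sample 20% VAF cap deliberately retains genuinely
   high-VAF somatic variants (e.g. under loss of heterozygosity) as long as
   they dip below the threshold somewhere in the series; the trade-off is
   that a somatic variant that stays above 20% at every sampled time point
   is lost. This rule also serves as the aneuploidy guard for MSAF, so no
   additional per-sample cap is applied there.
4. **Review flag.** A variant whose VAF range across the series (absent
   time points counting as 0) exceeds `delta_threshold` (default 0.02) is
   flagged, not removed — the automated replacement for a manual
   inspection step. Whether manual review ever removed variants in practice
   is unknowable from here, so the artifact only flags.

Each removed call keeps its *first-failing* label only; a variant present
both in the population database and in the WBC evidence is
`common_germline`. Per sample, `input = removed(common) + removed(normal) +
removed(private) + passing` — the conservation invariant checked on every
run and in the acceptance suite.

## Burden metrics

`MSAF` is the maximum VAF over passing calls (0 for an empty set), all
effect classes included — synonymous variants measure tumor fraction just
as well. `bTMB` is the passing-call count per megabase of panel; synonymous
calls are included by default (the numerator is deliberately the same set
MSAF draws from; a flag restricts to nonsynonymous). The survival split uses
*baseline* (day 0) bTMB only; on-treatment mutational burden reflects
treatment response, not the pre-treatment antigen load the split is meant
to capture. The patient-level `mean MSAF` averages the on-treatment
samples.

A subtlety the test design must respect: MSAF is a *maximum* over ~10-20
passing calls, taken after a filter that itself depends on the read draws.
Its sampling distribution is therefore upward-shifted and wider than a
single binomial draw at the top clone's expected VAF. The calibration check
(`planted_msaf_band()`) consequently simulates the exact planted null —
binomial draws for every planted somatic variant, the detection floor, the
combined-VAF removal, then the per-day maximum — and asserts the observed
MSAF inside the central 99.73% (3-sigma) band, allowing the nominal number
of tail misses across a cohort (at most 2 in ~44 samples).

## Clonal deconvolution

The model: mutation \(i\) in cluster \(k\) at time point \(t\) has

\[ a_{it} \sim \mathrm{Binomial}\!\left(n_{it},\; \phi_{kt}\, m_i / c_i\right) \]

with cellular prevalence \(\phi_{kt} \sim \mathrm{Uniform}(0,1)\), total
copy number \(c_i \in \{1,2,3\}\) discretized from logR (1 below −0.25, 3
above 0.25, 2 in between; both boundaries and missing logR map to 2),
multiplicity \(m_i = 1\) (total copy number is all the input provides; no
minor-allele decomposition is attempted), and a Chinese-restaurant-process
prior with concentration \(\alpha = 1\) on the partition. \(\phi\) is
interpreted as prevalence within tumor-derived DNA; no separate
purity/tumor-content term is modeled, because serial plasma samples have no
stable purity to estimate against.

Binomial (not beta-binomial) emission is a deliberate simplification: with
molecular-identifier deduplication at ~3000x, residual overdispersion is
small relative to the between-cluster separation the method needs, and the
binomial model admits a much simpler, fully checkable sampler.

**Inference.** Gibbs sampling with defaults of 5000 sweeps, 1000 burn-in,
thinning 5 (all in `dp_control()`). Prevalence updates draw from the exact
conditional discretized on a 512-point mid-point grid (resolution ~0.002,
below the binomial noise floor `sqrt(p(1-p)/3000)` for any p of interest);
the same grid computes the marginal likelihood of a singleton cluster
(prevalence integrated out) used when a mutation considers opening a new
cluster. A mutation undetected at a time point contributes 0 alt reads with
that sample's median depth as the trial count — absence at depth 3000 is
strong evidence of low prevalence and must not be dropped. Patients need at
least `min_timepoints = 3` samples: with fewer, trajectories cannot
separate clusters reliably.

**Reporting.** Cluster labels in a DP mixture are arbitrary and the
partition itself mixes, so the reported partition is the consensus of the
posterior similarity matrix (fraction of retained sweeps co-clustering each
pair), cut by average-linkage clustering at similarity 0.5; reported
\(\phi\) are posterior means (with 95% intervals) given that consensus
partition, recomputed on the grid. Identical seed and inputs give identical
output. All tests compare partitions, never labels.

**Reference at small scale.** For up to 8 mutations, `map_partition()`
enumerates every set partition and maximizes the same marginal posterior;
the test suite requires the Gibbs consensus to match it on at least 9 of 10
seeded 6-mutation instances, and prevalence recovery error below 0.05 at
depth 3000. The test and acceptance runs use shorter chains
(1500/400/thin 2) than the defaults; at the tested sizes (up to ~20
mutations, 2-4 time points) the small-instance agreement and recovery
checks confirm those chains suffice.

## Clone trees, emergence, lead time

The *crossing rule* — a descendant clone's prevalence never exceeds its
ancestor's at any time point — and the *sum-up rule* — children's
prevalences sum to at most the parent's — are necessary conditions on any
valid clonal tree. What a human analyst does with them informally, the
package encodes as a deterministic greedy algorithm: place clusters by
decreasing mean prevalence; attach each to the already-placed candidate with
the *smallest* mean prevalence (the most specific valid ancestor) that
satisfies both rules within a tolerance `epsilon = 0.02` per time point
(about three binomial standard errors at 3000x for mid-range VAFs); prefer,
among near-tied candidates, a parent detected no later than the child (a
clone cannot predate its ancestor — the formalization of "appeared later"
evidence); clusters with no valid parent attach to the germline root
(prevalence 1). A validator re-checks every edge and every internal node of
every emitted tree.

Trend sub-clustering (`split_by_trend()`) divides a cluster by the sign of
the VAF change over a designated window, then separates mutations whose
full trajectories correlate below `min_corr = 0` (single-linkage
components); mutations are processed in genomic-coordinate order, making
the result deterministic.

**Identifiability.** Two lineages whose prevalences stay within `epsilon`
of each other everywhere cannot be ordered by these rules — no algorithm
could order them from such data. The topology-recovery guarantee therefore
refers to identifiable instances: `simulate_planted_tree()` draws planted
trees conditional on every pair of non-nested lineages mutually crossing by
more than `2 * epsilon` (an algorithm-independent condition), and the suite
requires at least 16 of 20 such topologies recovered from reads at 3000x.
On unconstrained cohorts, low-prevalence subclones frequently violate this
condition and the builder conservatively attaches them to the root.

**Emergence and lead time.** A cluster emerges on the earliest sampled day
where its prevalence exceeds `phi_min = 0.01` (comfortably above the
binomial noise floor at 3000x) and the trajectory shows `rise_points = 2`
consecutive rising intervals ending at or after that day — one rising
interval is indistinguishable from noise. Note the rule dates a clone
already present at baseline to day 0. Lead time is the first
progressive-disease scan day minus the emergence day, reported as-is (it
may be negative), measured to the scan date. Lesion association is reported
purely as sign agreement between per-interval prevalence changes and
diameter-sum changes — a descriptive table, not a causal claim.

## Outcome statistics

The Mann-Whitney U test is implemented in-package because the response
groups are small and heavily tied: for combined n <= 20 the p-value is
exact by full enumeration of all group assignments (ties handled by the
1/2-convention in U; two-sided p as the symmetric tail
\(P(|U - n_1 n_2/2| \ge |u - n_1 n_2/2|)\)), and beyond that a
tie-corrected normal approximation without continuity correction.
Sample-level MSAF comparisons label each on-treatment sample with the
response of its nearest scan (PR versus SD/PD); baselines have no response
label and are excluded. Patient-level mean MSAF is compared by best
response. Spearman correlation (average ranks, t-approximation) associates
per-sample MSAF with the contemporaneous lesion-diameter sum.
Kaplan-Meier curves and the median-split log-rank test (ties-to-low-group
convention, config-exposed) are backed by the `survival` package behind the
package's interface; a Cox model is deliberately not fitted — the reported
analysis is the median split, and a proportional-hazards fit on 12 patients
would suggest precision that is not there.

## The simulator: what it emulates, what it does not

`simulate_cohort()` generates the full study: ~12 patients; 2-7 serial
samples at uniform 14-35-day intervals; Poisson(3000) depths; binomial alt
reads at `phi * m / c`; a 637-kb panel whose 329 gene symbols are a
synthetic stand-in list; 2-5 clones per patient on a random nested tree
with founder mutation counts (2 + Poisson(4)) and subclone counts
(1 + Poisson(2)) calibrated so the cohort-median baseline bTMB lands near
21/Mb; per-patient response archetypes (responder / stable / progressor /
relapse-after-response in proportions 3:6:1:2, mirroring a PR 5 / SD 6 /
PD 1 cohort of 12); common germline SNPs (VAF ~0.5, population AF >=
0.001), CHIP variants (plasma VAF 0.5-3%, >2 WBC reads), and private
germline variants that escape both lookups; and 10% of somatic mutations on
copy-number events (logR ~ +/-0.5).

Clinical coupling: lesion diameter sums follow
`baseline_cm * (0.3 + 0.7 * tf_lagged / tf_0)` with multiplicative noise
(sd 0.04) — tf is the founder prevalence (circulating tumor fraction), and
baseline size couples to baseline tumor fraction as
`(2.5 + 20 * tf_0) * lognormal(0.15)`. Radiology lags biology: shrinkage is
seen with a ~3-week delay, and for relapse patients the regrowth driven by
the resistance clone becomes CT-visible only at the planted progression
day, 60-120 days after the clone crosses the 1% molecular detectability
floor. That lag *is* the phenomenon the lead-time analysis measures; without
it, scans would see progression the moment ctDNA does and no lead time
could exist. Response labels are thresholded: PR at a 30% diameter decrease
from baseline, PD at a 20% increase from the nadir (PD wins when both
hold), SD otherwise; PFS is the first PD scan or censoring at the last
visit. The diameter noise is kept multiplicative at 4% because the label
thresholds (especially +20% from nadir) sit close to the on-treatment
diameter range; larger noise manufactures spurious progressions and
destroys the label structure every downstream statistic consumes.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequencing error beyond binomial sampling
(deduplication is assumed to have removed error reads), fragment-length and
methylation signal, subclonal or multi-sample copy-number change,
beta-binomial overdispersion, pseudo-progression on imaging, irregular
per-patient scan schedules decoupled from blood draws, and the full
confirmation logic of immune-response criteria (reduced to the three
thresholded labels). Real cohorts will be messier in all these directions;
the synthetic results demonstrate correctness of the machinery, not
clinical performance.

## Numerical choices and degenerate inputs

* Prevalence grid: 512 mid-points in (0,1); avoids the endpoints exactly,
  so log-likelihoods stay finite even at VAF 0 or c = 1.
* All mixture arithmetic in log space with log-sum-exp.
* Threshold conventions, as printed where a source convention existed:
  population-AF cutoff inclusive (>= 0.001 removes); WBC cutoff exclusive
  (> 2 removes); private-germline VAF strict (> 0.20); review delta strict
  (> 0.02); logR boundaries +/-0.25 map to copy number 2.
* Median-split ties go to the low group (config-exposed).
* Empty inputs: empty VCFs parse to empty tables; an empty passing set has
  MSAF 0 and bTMB 0; a single mutation forms one cluster; a single-sample
  patient passes the cascade (with a caution) but is ineligible for
  clustering; `build_tree` on zero clusters errors.
* Determinism: every stochastic entry point requires a seed
  (`dp_cluster`, `simulate_cohort`), and equal seeds give byte-identical
  simulator output.

## Known limitations

* Multiplicity is fixed at 1; amplified mutations on all copies will have
  prevalence overestimated (clipped at 1).
* The private-germline rule removes somatic variants that stay above 20%
  VAF at every sampled time point (e.g. persistent high-burden disease with
  LOH); this is the cost of the patient-combined rule and is visible in the
  simulator's sensitivity accounting.
* Tree topology is not identifiable for lineages within the builder's
  tolerance of each other; such clusters attach to the root rather than
  guess.
* The emergence rule dates baseline-present clusters to day 0, so lead
  times for founder clones are upper bounds of no clinical interest; the
  relevant calls are for clusters near 0 at baseline.
* Problem sizes in the test and acceptance suites (cohorts of 12, up to
  ~20 mutations per patient, chains of 1500-2000 sweeps, 10-20 replicates
  per property) are chosen so the whole suite re-runs quickly; all are
  config-exposed and scale up unchanged.
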