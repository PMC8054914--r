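---
title: "Models and methods behind clonecensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonecensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecensus)
```

## The problem

A bulk tumor sample is a mixture: normal cells, a dominant clone carrying
every truncal mutation, and possibly one or more subclones carrying
additional private mutations. Whole-genome sequencing observes each somatic
single-nucleotide variant (SNV) only through a pair of read counts — variant
reads out of total reads — blurred by purity, local copy number, mutation
multiplicity, and sampling noise. Subclonal reconstruction inverts this
observation process: it estimates how many subclones are present, what
fraction of tumor cells each comprises (the cancer cell fraction, CCF), and
which mutations belong to each.

Individual reconstruction methods disagree, sometimes substantially.
`clonecensus` implements the consensus machinery that turns many imperfect
reconstructions into one robust answer, together with the simulation,
bias-correction, copy-number-consensus, read-phasing, signature-dynamics and
scoring tools that such a consensus pipeline needs.

## Coordinate systems and core algebra

Three linked scales describe a mutation's abundance:

* **VAF** — variant allele frequency, `alt / total` reads;
* **CCF** — fraction of *tumor* cells carrying the mutation (1 = clonal);
* **CP** — cellular prevalence, fraction of *all* cells; `CP = purity * CCF`.

For an SNV at total tumor copy number $n_t$ (normal $n_n$, purity $\rho$),
the mutation copy number is
$$u = \frac{f}{\rho}\left[\rho n_t + (1-\rho) n_n\right],$$
with $f$ the VAF. The multiplicity is $m = 1$ when $u < 1$ and the nearest
integer (half away from zero) otherwise — `snv_ccf()` also exposes the
alternative `max(1, round(u))` convention via `rounding = "clip"` — and
`CCF = u / m`. CCF estimates above a configurable super-clonal ceiling
(default 1.5) are flagged with a warning rather than truncated, so that
downstream clustering can see purity or copy-number inconsistencies.

Sequencing power is summarized by the number of reads per tumor chromosomal
copy,
$$\mathrm{nrpcc} = \frac{\rho\,\mathrm{cov}}{\rho \psi_t + (1-\rho)\psi_n},$$
and a caller that requires $k$ variant reads can detect clones down to CCF
$k/\mathrm{nrpcc}$: at nrpcc 10 and the standard 3-read limit, clones at 30%
of tumor cells or larger.

Genomic coordinates are 0-based half-open in segment tables internally and
1-based inclusive in SNV tables, documented per column in the I/O helpers.
For XY samples, X and Y outside the pseudo-autosomal regions should be given
`normal_total_cn = 1`; the pseudo-autosomal regions are treated as diploid.

## The read-count simulator

`simulate_reads()` generates tumors with known truth. Reads per chromosome
copy for tumor and normal cells are
$$c_t = \frac{C\rho}{\rho\psi_t + 2(1-\rho)}, \qquad
  c_n = \frac{C(1-\rho)}{\rho\psi_t + 2(1-\rho)}.$$
A mutation with multiplicity $m_m$ in a cluster at CCF $f$ has expected
variant reads $E(r_m) = m_m f c_t$ and expected wild-type reads
$$E(r_w) = 2 c_n + m_w c_t + m_m (1-f)\,c_t,$$
where $m_w$ counts the tumor copies not carrying the mutation in mutated
cells (total $-$ $m_m$ for clonal mutations; total $-$ 1 inside the
subclone for subclonal ones, whose non-carrier cells are already covered by
the $(1-f)$ term). Depth is Poisson with mean $E(r_m)+E(r_w)$ and the
variant count binomial given depth. Clonal multiplicity is Poisson(1)
clamped to [1, major allele copies]; subclonal mutations sit on one copy.
Mutations with fewer than `min_count = 3` variant reads are dropped — this
detection filter is the origin of the winner's curse corrected below.

Architectures come from `draw_architecture()`: subclone CCFs uniform on
(0.1, 0.9), subclonal mutation count
$N_{sub} = N_{clonal}(1-f_{clonal})/f_{clonal}$, partitioned by
stick-breaking with U(0.1, 0.9) stick fractions and random assignment of
chunks to subclones.

The grid design (`build_grid()`) crosses 6 purity levels, 5 clonal-SNV
levels (one anchored at $10^5$ for hypermutators), 5 clonal-fraction levels
(one anchored at 0.995 for the melanoma-like corner) and 4 subclone levels
(0, 1, 2, "3+", the last drawn uniformly from 3–7), at fixed coverage
48.46621 — 600 cells. The non-anchored levels are fixed representative
values spanning the ranges seen in large WGS cohorts (purity 0.24–0.93,
2,000–100,000 clonal SNVs, clonal fractions 0.55–0.995); the original study
derived its levels by clustering cohort values that this package does not
ship. `two_pass_sample()` draws 600 cells with replacement, then 100 more
restricted to the cells still uncovered, which maximizes grid coverage
while keeping the design hard to reverse-engineer from the samples.

`calibrate_n_input()` bisects the simulated mutation count so that the mean
*emitted* count over repeated simulations lands within ±5% of a target,
compensating for the detection filter. Diploid twin simulations preserve
power exactly through $\rho_d = 2\rho/(\rho\psi_t + 2(1-\rho))$, which makes
the nrpcc of the diploid re-simulation algebraically identical to the
original; the literal ploidy-ratio alternative $(2/\psi_t)\rho$ is kept
behind a flag.

Copy-number profiles for simulations come from `synthetic_cn_profile()`, a
deliberately parametric stand-in (log-uniform segment lengths, a
configurable distribution over common allele-specific states) for profiles
sampled from a real cohort. Mutations are assigned to segments with
probability proportional to segment length — the uniform-per-base reading
of random placement.

What the generator does *not* emulate: sequencing error and mapping
artifacts, GC and replication-timing coverage waves, kataegis, indels and
structural variants, and correlated (phylogenetically nested) copy-number
states. Tests that pass on this generator therefore demonstrate correctness
of the statistical machinery under the stated observation model, not
robustness to artifact-laden real data.

## Clustering SNVs into subclones

`reference_cluster()` is the package's in-house clusterer with two engines.

The **Gaussian engine** fits 1-d Gaussian mixtures to CCF values with
`mclust` (unequal variances, BIC over 1–7 components), merges adjacent
components whose mixture density has no dip between their means (no local
minimum below 0.95 of the smaller peak), and collapses every component with
mean above 0.9 into a single clonal cluster pinned at CCF 1.0. `mclust`'s
deterministic hierarchical initialization replaces random EM restarts.

The **binomial engine** (used automatically when read counts are supplied)
models each SNV's variant count as Binomial(depth, $m_k / c_i$), where
$m_k$ is the cluster location and $c_i$ the per-SNV CCF-to-VAF factor from
`ccf_conversion_factor()`. This matters: at realistic depth (~50×), a
single SNV's CCF point estimate carries noise with a standard deviation of
0.15–0.25, so mixtures fitted to point estimates cannot separate clusters
0.2 apart no matter how many SNVs are available, while the exact
heteroscedastic likelihood can. The EM is deterministic — quantile starts
plus a split of every previous component, screened with short (25-iteration)
runs, the best start run to convergence — with BIC selection, a
resolution-limit merge of components closer than 0.06 CCF (just below the
~0.07 empirical resolution floor of single-sample bulk reconstruction), and
the same clonal collapse at 0.9.

Random baselines (`randomclone()`) bound expected performance from below:
`stick` breaks the CCF-ordered mutation list into 1 + U{0..6} random
chunks; `informed` scores 100 stick draws by the fraction of mutations in
the outermost 5% of a per-cluster beta model (overdispersion 0.01 on the
proportion scale, configurable — the original criterion's dispersion is not
published) and keeps the best; `single` and `single_clonal` place one
cluster at the mean CCF or at 1.0.

`cna_pseudo_ssm()` and `binomial_se()` implement the pseudo-SNV weighting
that lets copy-number events enter SNV-based phylogeny models: an event of
length $L$ kb contributes implied depth $d = L \cdot R \cdot D$ (7
heterozygous SNPs per 10 kb, mean depth $D$), variant reads $v = 0.5 p d$,
and merged clonal events are capped at the confidence of 3,000
average-depth SNVs; the implied standard error is
$\sqrt{p(1-p)/(d+1)}$.

## Consensus of clusterings

A clustering is summarized as ordered pairs $\{(p_k, f_k)\}$ — proportions
and locations — whose CDF is a step function. The earth mover distance
between two clusterings is the exact rectangle sum of $|F_1 - F_2|$ over
the union of their breakpoints (`emd()`).

**WeMe** (`weme_consensus()`): the *median clustering* of a set has CDF
equal to the pointwise median of the member CDFs (`median_clustering()`).
Outliers — the 20% of inputs with the largest EMD to the all-method median,
rounded down, never leaving fewer than two inliers — are removed; the
median is recomputed; K is the ceiling of the median inlier cluster count;
and the K-constrained consensus minimizes EMD to the median over proportion
vectors (a 0.05-step simplex grid for K ≤ 4, coordinate descent from an
equal split above that, plus the inlier proportion vectors themselves as
candidate starts), with each candidate's locations set to weighted medians
of the median clustering within each proportion step. Weighted-median ties
break toward the lower location, deterministically.

**CICC** (`cicc_consensus()`): each SNV's vector of per-method cluster
labels (−1 when unassigned) is reduced to unique vectors with
multiplicities; the pairwise distance counts disagreeing coordinates (a
coordinate where both labels are −1 also counts 1), scaled to
$d_{ij} = 10 \max_l N_l \cdot d(U_i, U_j) - \max(N_i, N_j)$ — implemented
as printed, including possible negative values, with an optional
`clamp_negative` flag; Ward clustering on this matrix is cut at the median
method K when that is below 3, otherwise at the K minimizing the proportion
of ambiguous clustering (PAC, consensus-index window 0.1–0.9, 100 method
bootstraps). Consensus per-SNV CCFs use the floor of the median
multiplicity across methods; the cluster CCF is the median member CCF and
CP = purity × CCF.

**CSR** (`csr_consensus()`): the mean of the methods' binary co-clustering
matrices is thresholded at 0.2 (a pair supported by 2 of 11 methods carries
no signal), factorized by non-negative matrix factorization with an L1
penalty on the code matrix (multiplicative updates; NMF replaces the
original sparse dictionary learner under the same contract
$M \approx DA$), and k-means on the code columns gives K clusters, K being
the rounded-up median of the per-method cluster counts. Post-processing
merges super-clonal clusters (CP above purity) into the nearest legal
cluster, merges clusters closer than the median of per-method shortest
inter-cluster distances (fallback 0.05), drops clusters smaller than the
median of per-method smallest cluster sizes (fallback 5% of SNVs, or 50
below 1,000 SNVs), and downsamples inputs above 30,000 SNVs to 25,000 by
taking a prefix of the pre-shuffled SNV list.

`assign_mutations()` assigns every mutation to consensus clusters by
beta-binomial likelihood (overdispersion 0.01) at each cluster's expected
VAF, weighted by cluster-size priors; mutations with unknown copy number
are assigned but flagged for exclusion from location updates.

## Winner's curse correction

Detection censors variants with fewer than 3 supporting reads, biasing a
low-CCF cluster's observed position up and its mutation count down.

`spoilsport_correct()` is the analytic route. Under its stated assumptions
— every variant single-copy at the average copy number
$\rho\psi + 2(1-\rho)$ and at the average depth, with the cluster CP a
binomial maximum-likelihood estimate — the observed per-read variant
probability is the mean of a truncated binomial. The method finds $p^*$
with $E[\mathrm{TruncBinom}(p^*, n, T)]/n$ equal to the observed
$p_v = \theta / (\rho\psi + 2(1-\rho))$ by golden-section/parabolic search
(`stats::optimize`, tolerance $10^{-8}$), reports corrected
CP = $p^*$ × average copy number, and inflates the mutation count by
$sf = 1/(1 - F_{\mathrm{Binom}}(T; p^*, n))$. The truncated distribution is
normalized by $1 - F(T)$ — the only normalization that integrates to one —
and $T$ defaults to 2 (detected iff ≥ 3 reads). When the observed $p_v$
falls below the truncation floor $(T+1)/n$, no $p$ can match and the method
returns corrected CP 0 with a diagnostic. Because the method equates the
observed CP with a pooled binomial MLE, that is also the estimator that
should be fed to it; per-SNV mean CCFs carry an extra detection-selection
bias of order +0.02 at nrpcc 10.

`phylogic_correct_bias()` is the simulation-search route: candidate true
CCFs walk down a 0.01 grid from the observed position; each candidate is
simulated under the read-count model (common random numbers across
candidates), the detection rule applied, and the detected cluster's mean
CCF compared to the observation; the best-matching candidate within 0.01
is reported together with the implied true count (observed /
detected-fraction).

`combine_corrections()` merges methods: arithmetic mean of CCF shifts,
geometric mean of corrected counts.

## Copy-number consensus

`consensus_breakpoints()` implements the six-step breakpoint merging: each
caller's inter-segment gap becomes a plausible interval padded by
δ = 50 kb, scored by the empirical-CDF rank of the gap size within that
caller; scanning from the chromosome start, the first intersection
supported by at least 3 callers of any kind or at least 2 "conservative"
callers yields one breakpoint — the in-intersection candidate locus with
the smallest gap rank, ties preferring segment ends, or the upstream edge
when no locus falls inside — after which the contributing intervals are
removed and the scan repeats. Structural-variant breakpoints within 100 kb
replace the nearest consensus breakpoint (unmatched ones are added), and
centromere/telomere anchors are enforced at 1 Mb.

`segment_agreement()` walks the agreement ladder a–i for one segment:
unanimous clonal (a), leave-one-out (b), ploidy-overruled-excluded (c),
clonal majority (d), complete/leave-one-out agreement over the
rounded-subclonal state inventory (e), rounded majority (f), best-method
call constrained to any single-allele consensus (g), next-best methods (h),
and the expert-panel-unresolved flag (i); stars are 3 for a–c, 2 for d–f,
1 for g–i. When the best method conflicts with an established single-allele
consensus the call falls through to the next method. `rank_callers()`
orders callers by the genome fraction on which they match the a–f
consensus, excluding ploidy-overruled profiles, ties broken by caller id.

`consensus_purity()` excludes ploidy-overruled callers (ploidy differing
from the reference by more than 0.25 × reference), drops purity calls
differing by more than 0.2 from every other call in their group (copy-
number-based and SNV-based filtered separately), uses only SNV-based calls
when less than 8% of the genome is altered, returns the surviving call
nearest the mode of a Gaussian kernel density (Silverman's bandwidth — not
specified in the source method) and the median absolute deviation of the
survivors as confidence.

## Phased SNV pairs and tree odds

Read pairs covering two nearby SNVs are haplotype observations.
`classify_pair()` labels a pair *collinear* when ≥ 2 read pairs carry both
mutant alleles, ≥ 2 carry exactly one of them (one direction only), the
major allele copy number is 1, and either the sample's expected
infinite-sites violations are below 1 or the segment is clonal 1+0; the
single-mutant haplotype identifies the ancestral SNV. *Branching* requires
zero double-mutant pairs, ≥ 2 pairs in each single-mutant direction, and a
clonal haploid (1+0) segment. In-cis pairs outside the informative context
are `phased_cis_uninformative`, mutually exclusive pairs in diploid regions
`trans_diploid`, three haplotypes on one copy `inconsistent`, anything
below threshold `unpowered`.

`infinite_sites_rate()` estimates expected double hits by permuting the
sample's mutations over the callable positions of their own trinucleotide
context — two allele slots per position, drawn without replacement — and
averaging over 1,000 simulations; a lower bound, since real mutation rates
are non-uniform. `branching_odds()` computes branching:linear odds over
pairs restricted to contexts where both calls are possible, with a
percentile bootstrap. `tree_odds()` samples one subclone pair per tree per
repetition and tallies siblings (same parent) against parent–child (direct
edge); cousins and deeper relations are excluded from both counts.

## Signature activity along pseudo-time

`build_timeline()` orders SNVs by average mutation copy number per cell
(VAF resampled from its Beta(alt+1, ref+1) posterior to remove
quantization, converted via purity and local copy number), descending, and
bins them 100 at a time. `fit_activities()` fits, per bin, a mixture of
multinomials with components fixed to the active signature catalog (EM on
the mixture weights); activities sum to 1 per bin. `detect_changepoints()`
finds the optimal penalized segmentation by PELT, with segment cost −2 ×
maximized mixture log-likelihood of the pooled counts and a per-segment BIC
penalty of (S − 1) × log(total mutations) — the source method states "BIC"
without its constant, so the penalty is exposed as an argument — and drops
change points whose activity change is under 5% (with 10% as the
overall-change flag, and ~30-replicate bootstrap standard errors from
`activity_bootstrap_se()` as the uncertainty reference).
`segment_exhaustive()` is the O(n²) dynamic program used to verify PELT
optimality, and `boundary_support()` compares the fraction of subclone
boundaries with a change point within 3 time points against the same
fraction under 1,000 random change-point placements.

## Scoring

`score_reconstruction()` returns three metrics, each clipped to [0, 1] with
1 best: the relative clonal fraction change $1 - |F_O - F_T|/F_T$; the
cluster-number score $\mathrm{NCD} = 1 - |e^{(C_O-C_T)/C_T} - 1|$, whose
exponent makes overestimation cost strictly more than underestimation —
the parse of the printed formula that uniquely matches that stated
preference; and the per-SNV RMSE score
$1 - \sqrt{\mathrm{mean}((\phi_O - \phi_T)^2)}/\rho$, computed in CP space
(the division by purity implies CP units). `rank_methods()` normalizes
per-sample ranks to [0, 1] with best = 1 (all-tied metrics give everyone
1); `method_similarity()` gives truth-free pairwise similarities.
`clonality_permutation_test()` compares nrpcc-weighted median subclonal
probabilities between event groups by label permutation, with
Benjamini–Hochberg adjustment across loci via `adjust_bh()`. The weighted
median interpolates ties linearly. Note that with point-mass inputs
(identical probabilities within each group) the permuted median difference
reproduces the observed one with high probability — a property of the
median statistic, not a bug — so meaningful p values require continuous
probability inputs.

## Benchmark designs used by the test suite

The closed-loop winner's-curse check simulates a CCF-0.25 subclone at
nrpcc 10 with 5,000 mutations per cluster — large enough that sampling
noise on the observed cluster position is negligible next to the 0.02
tolerance being verified, so the check measures the correction methods
rather than fixture noise.

The end-to-end recovery benchmark runs 50 simulated tumors at purity 0.9
and coverage 65 (nrpcc ≈ 29, a deep-WGS-quality sample), diploid genomes,
0–2 subclones with CCFs in [0.3, 0.75] (detectable with margin at this
power, and separated from the clonal cluster by at least 0.25), all
pairwise cluster separations at least 0.2 — comfortably above the ~0.07
empirical resolution floor — and clusters of 700–1,000 SNVs. Each tumor is
clustered once with the binomial-engine reference clusterer; five jittered
copies of that output (locations and proportions perturbed by N(0, 0.02))
emulate independent methods and are combined by WeMe. Exact recovery of K
and all locations within 0.05 CCF is required on all 50 tumors.

## Numerical choices and degenerate inputs

* All stochastic functions accept explicit seeds; the pipeline writes every
  tumor's seed into its manifest, making runs byte-reproducible.
* EMD and the median clustering are exact (rectangle sums over union
  breakpoints), not quadrature.
* The WeMe proportion grid step is 0.05; ties in candidate scores keep the
  first candidate in a fixed enumeration order.
* Golden-section tolerance for the truncated-binomial match is $10^{-8}$ on
  p; bisection for `calibrate_n_input()` stops inside ±5% of target.
* Single-clustering consensus returns the input with a warning; all-
  identical CCF input yields one cluster without error; baselines never
  fail by construction.
* CICC with every SNV unassigned, zero-coverage purity computations, and
  empty caller lists raise typed errors naming the offending input.

## Known limitations

* The binomial clustering engine assumes the copy-number context and
  multiplicity passed to it are correct; systematic copy-number errors
  translate directly into location biases.
* Sub-0.15 cluster separations are not reliably resolvable at PCAWG-like
  depth by any single-sample method, this package's included.
* The CSR implementation targets cohort-scale inputs only through prefix
  downsampling; it holds the thresholded co-clustering matrix densely in
  memory.
* Phasing consumes pre-tabulated read-pair evidence; extraction from
  alignments (with the mapping-quality, clipping and mismatch filters
  described for the evidence format) is out of scope.
* The signature module requires a user-supplied catalog; none is bundled.
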