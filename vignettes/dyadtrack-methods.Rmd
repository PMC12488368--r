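---
title: "Methods: models and design choices in dyadtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in dyadtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtrack)
```

# Scope and data model

`dyadtrack` implements the downstream statistical analysis of a
mother–infant dyad 16S amplicon study in which mothers with gestational
diabetes mellitus (GDM) and non-diabetic controls each contribute a stool
sample, and their infants contribute meconium (T1) and, usually, a 6-week
stool sample (T2). The package starts from a denoised amplicon sequence
variant (ASV) count table — the object produced by an upstream DADA2-style
pipeline — plus sample metadata linking samples to dyads. Everything
upstream of the count table (read processing, denoising, taxonomy
assignment) is out of scope.

The canonical container is `asv_table`: an integer matrix with ASVs as rows
and samples as columns. Readers accept a transposed layout behind a flag,
but writers always emit features-as-rows, so a table can never be silently
transposed between stages. Counts must be integers because the downstream
models (multinomial resampling, negative-binomial tests, the multinomial
source-tracking likelihood) are count models; a lenient mode floors
decimals with a warning for tables that passed through fractional
normalization upstream.

Missing samples are represented as absent dyad slots (`NA`), never as
all-zero columns: an unsequenced sample is not an empty community, and the
distinction matters wherever presence/absence is counted.

# The synthetic cohort generator

Because the real cohort's raw reads are not needed (or used) here, every
downstream stage is validated against a synthetic dyad cohort with known
ground truth. The generator (`simulate_cohort()`) draws, in order:

1. a baseline community over `n_asvs` gut ASVs from a symmetric
   Dirichlet(`base_concentration`), with `base_concentration = 0.3` giving
   the uneven, long-tailed abundance profile typical of stool communities;
2. a GDM group mean in which `n_markers` marker ASVs are multiplied by
   `2^marker_log2fc` and the vector renormalized. Markers are planted on
   taxa near `marker_base_abundance` (default 0.1% relative abundance):
   abundant enough to be observed at typical depths in both groups, yet
   carrying so little total mass that renormalization barely attenuates
   the planted fold change. Markers are planted in **mothers only**; any
   marker signal in infants must arise through the transmission mechanism,
   which makes marker-transfer detection a genuine end-to-end test;
3. each mother's composition from a Dirichlet centred on her group mean
   and scaled by `overdispersion` (a single concentration scalar
   controlling inter-subject variation);
4. each dyad's meconium as `tau_d * mother + (1 - tau_d) * environment`,
   where the environment is a Dirichlet draw over a disjoint pool of
   `env_pool_size` environment-only ASVs and `tau_d ~
   Beta(tau * kappa, (1 - tau) * kappa)` with `kappa = tau_concentration`;
5. the 6-week sample by independently retaining each T1 ASV's mass with
   per-dyad probability `rho_d` and re-seeding the lost mass from a
   mother/fresh-environment admixture with weight `t2_mother_weight`;
6. observed counts as one multinomial draw of `depth` reads per sample.

Defaults mirror the study design: 23 GDM and 10 control complete,
vaginally delivered dyads (99 samples), 300 gut plus 100 environmental
ASVs, depth 10^4 reads. `tau = 0.35` and `tau_concentration = 6` were
chosen so that per-dyad transmission fractions spread widely around a
moderate mean, and `overdispersion = 50` corresponds to a
Dirichlet-multinomial overdispersion (theta about 0.02) in the range
reported for human stool cohorts.

Two deliberate mismatches with real data should temper interpretation.
First, ASV identity is exact and global across samples; real cross-run ASV
matching noise is absent, so shared-ASV percentages here are cleaner than
in practice. Second, presence/absence statistics saturate: because
detection at depth 10^4 hides the abundance scale, the *realized* shared
percentage varies far less across dyads than the planted `tau_d` does, and
much less than the very wide ranges real cohorts show. Tests therefore
check ordering and calibration of these statistics, not their absolute
spread.

# Diversity, ordination and community tests

These are standard steps and are delegated to the standard tools behind a
stable package surface: Bray–Curtis via `vegan::vegdist` on raw counts,
PCoA via classical metric scaling (`stats::cmdscale`), NMDS via
`vegan::monoMDS` (Kruskal stress-1, global monotone regression) started
from the PCoA configuration so that results are deterministic, PERMANOVA
via `vegan::adonis2` under unrestricted label permutation (B = 999 by
default, the permutation p-value bounded below by 1/(B+1)), and the
Wilcoxon rank-sum via `stats::wilcox.test`.

Choices the upstream description left open, fixed here and exposed as
arguments:

* **No rarefaction** before Bray–Curtis (a `rarefy` flag exists, default
  off): the analysis being reproduced computes dissimilarities on the
  counts as given.
* **Shannon uses the natural logarithm**, the convention of the diversity
  tooling this mirrors; richness counts ASVs with any positive count.
* **Negative PCoA eigenvalues are reported but their axes dropped**; no
  Cailliez/Lingoes correction is applied.
* **The Wilcoxon exact branch** is used when the smaller group has at most
  8 observations and there are no ties; otherwise the tie-corrected normal
  approximation. The exact branch is verified against full enumeration of
  all 3-vs-3 assignments.
* **BH adjustment is per call**: `pairwise_permanova()` adjusts across the
  contrast list it was given, not study-wide, matching how pairwise
  PERMANOVA tools behave.
* The low-abundance filter keeps ASVs whose cohort-wide total is at least
  10 ("below 10" read strictly, so a total of exactly 10 is retained).

# Differential abundance and the marker rule

`nb_wald_test()` is a deliberately simplified DESeq2-style stage: counts
are normalized by median-of-ratios size factors (with a positive-counts
fallback for sparse meconium tables, where no ASV may be present in every
sample); a per-ASV negative-binomial dispersion is estimated by method of
moments on normalized counts and floored at 1e-8; the log2 fold change is
the ratio of group means (a 0.5 pseudocount replaces a zero group mean);
its standard error follows from the delta method under NB variance
$\mu + \alpha\mu^2$; and the Wald statistic is referred to the standard
normal, with BH adjustment across ASVs. There is no dispersion shrinkage,
no fold-change shrinkage and no independent filtering. The GDM marker rule
is then strict on both axes: log2 fold change > 3.5 **and** adjusted
p < 0.001 for maternal markers (the infant contrasts in the reproduced
analysis used the looser adjusted p < 0.01; both are plain arguments).

A consequence of dropping shrinkage deserves emphasis. Under the
single-scalar Dirichlet-multinomial cohort model, a taxon at relative
abundance $p$ has subject-level squared coefficient of variation close to
$1/(cp)$ for concentration $c$. With $c$ in the realistic 50–200 range and
markers at 0.1% abundance, the sampling spread of the estimated fold
change across 20-vs-20 mothers is 0.6–1.5 log2 units: a planted 16-fold
marker cannot clear a strict 3.5 cut-off reliably, no matter the test.
The marker-recovery benchmarks in the test-suite therefore run in the
low-overdispersion regime (`overdispersion = 1e4`, effectively multinomial
sampling noise only), where the stage recovers the planted fold change to
within 0.5 log2 units with sensitivity 1 and no false discoveries, and
its null type-I error sits at the nominal 5%. At realistic overdispersion
the unshrunk Wald test is both underpowered for this rule and mildly
anticonservative — which is precisely why DESeq2 shrinks dispersions; the
simplification is acceptable here because acceptance is parameter recovery
on synthetic data, not coefficient-level equality with DESeq2.

# Core microbiome and tracking

`core_microbiome()` uses strict prevalence: an ASV is core to a group when
it is detected (count > 0 by default) in *more than* 90% of the group's
samples — in a 16-mother group that means at least 15 of 16. Maternal core
sets are computed per group among vaginally delivered mothers, then
tracked in infant samples as relative abundances with explicit zero rows
(`track_set_in_samples()`), ordered for heatmaps by Ward (`ward.D2`)
clustering on Euclidean distance.

# Vertical-transmission bookkeeping

All transmission quantities are presence/absence set operations on the
low-abundance-filtered table, with presence meaning any positive count and
sharedness meaning exact ASV identity. Per dyad:

* **shared** = T1-present ASVs also present in the mother; **unique** =
  T1-present ASVs absent in the mother; `pct_shared_t1` is the shared
  count over the T1-present total;
* **transferred** = shared ASVs still present at T2; `pct_retained` is
  transferred over shared;
* `pct_contribution_t2` is transferred over the T2-present total — the
  denominator is the ASVs present in that sample, the only reading
  consistent with a per-sample "total ASVs" denominator.

Undefined ratios (empty denominators) propagate as missing values — never
as zero — and group summaries report the number of dyads they actually
cover. The identity `n_shared + n_unique = n_t1` is asserted on every run,
and the whole record set is tested for exact equality against an
independent brute-force reimplementation on 200 randomized dyads. Cohort
summaries can be restricted to complete (mother + T1 + T2) and vaginally
delivered dyads, mirroring the paired-analysis design; when a marker set
is supplied, the records additionally count markers among the shared and
transferred sets, and `marker_sharing_frequency()` reports how many dyads
share each marker.

# EM source tracking

`fit_source_proportions()` estimates how much of a sink community (a T2
stool) derives from each known source (the dyad's mother and meconium)
plus an unknown component. Sink counts are modelled as multinomial over
$\sum_k \alpha_k \gamma_k$; known-source distributions $\gamma_k$ are
plug-ins (source relative abundances with a pseudocount of 1 per ASV,
exposed as an argument), and EM updates the proportions $\alpha$. With all
component distributions fixed, the log-likelihood is concave in $\alpha$,
so the fit is deterministic and globally convergent from the uniform
start; the likelihood trace is asserted non-decreasing on every fit.

The unknown component requires care. If its distribution is refit from
responsibilities at every M-step, the model contains the empirical sink
distribution as a global optimum — the unknown alone can explain every
read — and EM demonstrably collapses to an unknown proportion of 1
regardless of the sources. The package instead estimates the unknown's
composition **once**: the mixture is first fit over the known sources
alone, and the unknown distribution is set to the positive part of the
sink's residual relative abundance that exceeds a two-standard-deviation
multinomial sampling allowance, $\max(\hat p_i - m_i - 2\sqrt{m_i/N},
0)$. Residual mass attributable to sampling noise is thus not credited to
the unknown; if nothing survives the allowance, the unknown proportion is
exactly zero. On simulated 0.5/0.3/0.2 mother/meconium/unknown mixtures at
depth 10^5 with well-separated sources this recovers proportions with mean
absolute error around 0.001, while a sink drawn purely from one source
leaves at most a few percent outside it. With `pseudocount = 0` and
sources of disjoint support, responsibilities are 0/1 and mixtures are
recovered exactly in closed form (the default pseudocount trades that
exactness for robustness to unseen ASVs).

The known sources are *not* re-estimated jointly with the sink (full
FEAST-style joint estimation); this plug-in simplification means source
sampling noise that the pseudocount cannot absorb appears as unknown mass.
On overlapping within-dyad sources at depth 10^4 the unknown therefore
runs higher than the generative truth, and cohort-level conclusions are
read qualitatively (ordering of mother vs meconium contributions), which
the tests verify under both mother-dominated and retention-dominated
regimes.

# Pipeline, seeds and determinism

`run_pipeline()` executes load/simulate → filter → diversity + ordination
→ pairwise PERMANOVA → maternal differential abundance + marker selection
→ core microbiome + tracking → transmission records → source tracking,
writing TSV outputs plus a JSON run summary that records every file,
threshold and seed. Configs are nested lists (or YAML); unknown keys are
errors, not silently ignored, so typos cannot silently revert a threshold
to its default. A single config seed is expanded into per-stage seeds by a
fixed affine rule (`seed + 97 * stage_index`, reduced mod 2^31 − 3), so a
stage rerun standalone with its recorded seed reproduces its in-pipeline
result, and a full rerun is byte-identical. A thin command-line wrapper
(`inst/scripts/dyadtrack.R`) exposes each stage and the full run as
subcommands.

# Problem sizes used in validation

The shipped tests validate: transmission against a brute-force oracle on
200 randomized dyads; PERMANOVA type-I calibration on 500 null
Dirichlet-multinomial cohorts of 16 samples at 999 permutations; Wilcoxon
exactness by full enumeration of all 3-vs-3 assignments; marker recovery
on 20 replicate 20-vs-20 cohorts at depth 2×10^4; source-tracking mixture
recovery on 20 replicate sinks at depth 10^5; and an end-to-end
deterministic pipeline run on the 33-dyad study-sized cohort. These sizes
were chosen as the smallest at which the statistical claims are
meaningfully testable (e.g. 500 replicates bound a 5% rejection rate to
about ±1 percentage point).

# Known limitations

* Transmission is presence/absence at exact ASV identity; there is no
  strain-level resolution and no abundance weighting.
* The NB Wald stage is unshrunk and should not be used as a DESeq2
  replacement on real, highly dispersed cohorts (see above).
* Source tracking fixes known-source distributions; unknown-source mass
  partly reflects source sampling noise rather than genuinely novel
  colonization.
* The generator shares one global ASV namespace and cannot emulate
  cross-run ASV mismatches, chimeras or sequencing error profiles.
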