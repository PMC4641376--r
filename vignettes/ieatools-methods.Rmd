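---
title: "Integrative enrichment analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative enrichment analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieatools)
```

## The problem

Classical pathway over-representation analysis asks whether a pathway
holds more differentially expressed genes (DEGs) than a random draw of
the same size would. In heterogeneous cohorts — cancer and metabolic
disease being the canonical examples — a second signal carries
information that mean shifts miss: genes whose expression *variance*
changes between conditions (DEVGs). A gene that is bimodal in cases but
tight in controls often marks a subtype split rather than a uniform
shift, and pathways rich in such genes are systematically under-scored
by DEG-only enrichment.

`ieatools` scores pathways on both signals at once, links dysregulated
pathways through network propagation, and screens pathways whose
variance-carrying genes define clinically visible sample subgroups.

## Feature genes: DEG and DEVG

For each gene with control values $X$ and case values $X'$ and condition
means $u, u'$:

* **DEG**: $H_0\colon E(X) = E(X')$ rejected. Tested with a two-sided t
  test; the Welch (unequal-variance) statistic is the default because
  differential-variance genes violate the pooled-variance assumption by
  construction. A pooled-variance flag is provided.
* **DEVG**: $H_0\colon E(|X - u|) = E(|X' - u'|)$ rejected *and* the
  mean test not rejected. Each condition is centred on its own mean, so
  a pure location shift changes no deviation (this invariance is tested
  to $10^{-12}$). Under normality the deviations are folded-normal, so
  a two-sided Wilcoxon rank-sum test compares them. For combined sample
  sizes up to 25 the exact null is used — the classical distribution
  when tie-free, full enumeration of group assignments of the
  average-rank statistic when ties occur (capped at 50,000
  assignments) — otherwise the normal approximation with continuity
  correction.

A gene passing both tests is a DEG by priority, so the DEG and DEVG sets
are disjoint in every run. Directions: `up`/`down` follow the sign of
$u' - u$; `relax` (case variance larger) and `tight` (smaller) follow
the variance difference. Genes with zero variance in both conditions
get p = 1 and are never selected.

Selection uses a three-tier protocol per category: (1) BH-adjusted
p ≤ 0.1; (2) if fewer than `min_genes` pass, raw p ≤ 0.05 with fold
change ≥ 1.5; (3) if still fewer, the top 1% of genes by p. For DEVGs,
which have no natural mean fold change, tier 2 uses the
larger-to-smaller variance ratio. The `min_genes` floor defaults to
200, which is calibrated to genome-scale arrays (~20,000 genes); the
synthetic evaluation studies below run at ~1,000–3,000 genes, where the
proportional floor is ~20 — those studies therefore pass
`min_genes = 20` so that tier 1 (the FDR tier) actually governs
selection, which is how the power properties are stated.

## The HT2 joint enrichment test

With $N$ background genes of which $x_1$ are DEGs and $x_2$ DEVGs, a
pathway of $y$ genes holding $k_1$ DEGs and $k_2$ DEVGs is scored by
the two-category hypergeometric tail

$$P(X_1 = k_1, X_2 = k_2) \;=\;
  \frac{\binom{x_1}{k_1}\binom{x_2}{k_2}
        \binom{N - x_1 - x_2}{\,y - k_1 - k_2\,}}{\binom{N}{y}},
  \qquad
  p \;=\; P(X_1 > k_1,\, X_2 > k_2),$$

the joint upper tail over the rectangle $(k_1, x_1] \times (k_2, x_2]$,
computed in log space. Two tail conventions are shipped:

* **strict** (`inclusive = FALSE`, the default of `ht2_pvalue`): the
  printed form above. It is exactly 0 at the maximal observation (the
  strict tail is empty), which is a real degeneracy: any observation at
  the boundary is "significant" at every level.
* **inclusive** (`inclusive = TRUE`): $P(X_1 \ge k_1, X_2 \ge k_2)$,
  the convention in which the observed outcome contributes to its own
  p-value. It dominates the strict value.

Both are verified against exhaustive enumeration of every $y$-subset of
a labeled universe for all parameter combinations with $N \le 12$, and
against Monte-Carlo draws at $N = 1000$. With $x_2 = 0$ the test
reduces exactly to the classical one-category hypergeometric (ORA)
tail, which the package also reports for every pathway as the baseline.

The background universe is all genes of the expression dataset, not the
union of pathway genes. Ranks use average ties; BH q-values are
reported alongside raw p-values.

## Pathway crosstalk by two-way restart walks

A crosstalk between pathways $u$ and $v$ is claimed only when each
pathway's dysregulated genes can "reach" the other pathway through the
interaction network:

1. Seed a random walk with restart (RWR) at $u$'s DEG ∪ DEVG genes
   present in the network, with uniform seed mass. The update is
   $P_{k+1} = (1 - \lambda)\,T^{\top} P_k + \lambda P_0$ with
   row-stochastic $T$ applied through its transpose, so probability
   mass is conserved at every iteration (checked to $10^{-12}$). The
   non-transposed, literally row-stochastic application is available
   behind `as_printed = TRUE` for comparison; it does not conserve
   mass. Iteration stops when the L1 change falls below the tolerance;
   successive changes contract at least by $(1-\lambda)$.
2. Rank non-seed nodes by steady-state probability (ties broken by gene
   id); the top 5% are "high-ranked". Their intersection with $v$'s
   genes is the partner set $S$.
3. Score $S$ with the HT2 test on the *network* universe ($N$ = network
   nodes, $x_1/x_2$ = network-wide DEG/DEVG counts, $y = |S|$). This
   gives the directional score $E_{uv}$; an edge is accepted only when
   $E_{uv}$ and $E_{vu}$ are both below α = 0.001.

Parameter choices, all configurable through `rwr_config()`:

* **λ = 0.7** — the restart probability is not dictated by the method;
  0.7 is the common choice in RWR gene prioritization and keeps the
  walk local enough that partner sets reflect direct wiring.
* **top 5% of non-seed nodes** — the "high-ranked" cutoff; a fraction
  (rather than a count) scales with network size.
* **partner set excludes the seeds** — seeds are dysregulated by
  construction, so counting them in $S$ would bias every pair towards
  significance; `include_seeds = TRUE` restores the naive variant.
* **inclusive tail for crosstalk scores** — with the strict tail a
  partner set consisting of one dysregulated gene scores exactly 0 and
  would be accepted at any α, so map building defaults to the inclusive
  convention. The strict variant remains available.
* **weighting** — `topology` (uniform over neighbors) or `correlation`
  ($w_{ij} = |r_{ij}|$ across all samples, via
  `correlation_weights()`); rows with all-zero weights fall back to
  uniform.

By default the walk runs on the **differential network**: edges of the
input network whose Pearson correlation differs between conditions by
the Fisher z test ($Z = (\operatorname{atanh} r' -
\operatorname{atanh} r)/\sqrt{1/(n'-3) + 1/(n-3)}$, two-sided p <
0.05). Correlations are clamped to $\pm(1 - 10^{-12})$ before the
transform; edges with unmeasured or constant genes are dropped and
counted. `use_diffnet = FALSE` propagates on the full network instead
— the choice is exposed because which network the walk should use is a
genuine modelling decision, not a fact.

Modules of the resulting pathway map are detected by greedy
modularity-maximizing agglomeration (fast-greedy), chosen for
determinism and zero tuning; singleton components are singleton
modules.

## Subtype-factors by supervised-like clustering (SLC)

For a pathway with at least `min_devg = 3` measured DEVGs:

1. **Binarize**: each case sample's DEVG expression becomes 1 iff it
   exceeds the control mean of that gene (ties → 0). When the
   pathway's DEVGs are majority tight-regulated the roles flip and the
   control samples are binarized against case means; ties cluster
   cases. Binarization is exactly invariant under affine rescaling
   applied to both groups.
2. **Cluster**: hierarchical clustering of the binary vectors (Hamming
   distance, average linkage, cut at two) by default — deterministic;
   k-means (k = 2, 10 restarts, fixed seed) is available. Samples with
   indistinguishable vectors cannot be split; the pathway is skipped
   with a warning.
3. **Associate**: each clinical index is tested between the two
   clusters — Wilcoxon rank-sum for continuous indices (tie-aware
   exact small-sample path, as above), Fisher's exact test for
   categorical ones. The test is not dictated by the method
   description; these were chosen for robustness at small cluster
   sizes, with a t-test flag for continuous indices. Clusters smaller
   than `min_cluster = 3` after removing missing values are skipped
   and counted.

All tested (pathway, index) pairs are reported with BH q-values;
flagging uses the raw p < 0.05, matching the screening character of the
procedure (the q-values are there for readers who want them). The
`min_devg` and `min_cluster` floors guard against degenerate clusters
and tests; 3 is the smallest size at which the exact rank-sum test can
reach p < 0.05 against a complementary cluster of reasonable size.

`pgc_baseline()` is the comparator that clusters raw expression of
*all* pathway genes (Euclidean, average linkage, same association
step).

## The synthetic data generator

`simulate_iea()` emits a mutually consistent expression matrix, gene
set collection, interaction network, clinical table and ground truth:

* **Baseline**: gene $g$ is Normal$(\mu_g, \sigma_g^2)$ with
  $\mu_g \sim U(4, 12)$, $\sigma_g \sim U(0.5, 1.5)$ — log2-microarray
  scale.
* **DEGs** shift case means by ±δ·σ (δ = 2 by default, half up, half
  down).
* **Bimodal DEVGs** (relax): case samples split into two arms at
  ±δv·σ (δv = 3), preserving the mean and inflating the variance by
  $1 + δv^2$. Bimodal genes planted in pathways share one case-subtype
  split — the structure the SLC screen looks for — while background
  bimodal genes get independent per-gene splits, since most
  variance-heterogeneous genes in a real cohort do not track any one
  clinical subtype.
* **Heteroscedastic DEVGs** (tight): case SD shrunk by $\sqrt{\rho}$
  (ρ = 4).
* **Pathways** are disjoint; planted pathways receive prescribed
  fractions of DEG/DEVG members, and *filler members are drawn from
  all remaining genes*, so null pathways carry dysregulated genes at
  the background rate rather than being artificially depleted.
* **Network**: within-pathway edges with probability 0.25, background
  edges at an expected degree of 1, and planted crosstalk pairs wired
  through shared interactor hubs — dysregulated genes outside any
  pathway, each connected to every dysregulated member of both
  pathways of its pair. Every planted pair is therefore connected
  within two steps.
* **Clinical indices**: continuous indices are Normal(50, 10²) with
  the planted effect (in SD units) added to one case arm; categorical
  indices shift the level odds by the effect on the logit scale.

The canonical evaluation configurations are exported as
`spec_null_study()`, `spec_power_study()`, `spec_distribution_study()`,
`spec_crosstalk_study()` and `spec_subtype_study()`; the test suite and
`scripts/acceptance.R` run exactly these. Problem sizes were chosen
once as the smallest at which the statistical regime is representative:
1,000 genes × 20+20 samples for null calibration, 2,000 × 50+50 for
power, 3,000 genes and 60 pathways for the ranking comparison, 800
genes and 8 pathways with two wired pairs for crosstalk recovery, and
1,000 genes with 40 case samples for the subtype screen.

**What passing these tests does not show.** The generator draws iid
Gaussian noise around single-gene effects. Real cohorts have correlated
biological noise, batch structure, non-normal marginals and overlapping
pathways. Two consequences observed while building the package are
worth stating plainly: (i) with iid noise and 3-SD bimodal separation,
the raw-expression comparator (PGC) recovers the planted subtype as
reliably as SLC does, so the tests assert SLC's own recovery and
calibration plus SLC/PGC agreement on strong signal — the *advantage*
of SLC over PGC reported on real cohorts depends on data features the
generator does not emulate and is deliberately not asserted; (ii)
recovery rates measured here are upper bounds on what to expect on
real data.

## Numerical choices

* HT2 in log space via `lchoose`, log-sum-exp for tails; out-of-range
  binomial coefficients contribute zero mass.
* Zero-variance genes: p = 1, flagged ineligible, never selected.
* Degenerate t statistics (zero pooled spread): p = 1 for equal means,
  0 for unequal.
* Rank ties: average ranks everywhere; ordering ties broken by
  pathway/gene id for byte-stable output.
* `write_table` renders floats with 6 significant digits so written
  tables round-trip.
* RWR convergence: L1 tolerance $10^{-10}$, hard iteration cap with an
  explicit error on non-convergence.
* All simulation and k-means seeds run through a local RNG scope that
  restores the caller's `.Random.seed`.

## Known limitations

* DEG∩DEVG genes carry only their DEG label; no combined label is
  emitted.
* The tiered-selection floor interacts with study size (see above);
  at genome scale the default 200 applies.
* Crosstalk scores on very small networks are coarse (the attainable
  p-value floor is $1/\binom{N}{y}$), so toy-scale demonstrations use
  a relaxed α.
* The differential network requires ≥ 4 samples per condition and
  warns below 10, where Fisher-z edge tests are unstable.
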