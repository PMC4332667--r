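---
title: "Detecting organ-specifically expressed or repressed ortholog clusters: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting organ-specifically expressed or repressed ortholog clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oserve)
```

## The problem

Comparative RNA-Seq across vertebrates makes it possible to ask which genes
an organ *relies on* — genes whose expression is specifically elevated
(expressed) or specifically suppressed (repressed) in one organ relative to
all others, consistently across species. `oserve` implements a complete
pipeline for finding such organ-specifically expressed or repressed (OSER)
orthologous gene clusters across nine vertebrates (chicken, platypus,
opossum, mouse, macaque, orangutan, gorilla, chimpanzee, human) and six
organs (brain, cerebellum, heart, kidney, liver, testis), and for
characterizing their evolution: phylostratigraphic origin, large-scale
duplication history, evolutionary rate, and the transcription factors that
bind them.

Because the pipeline spans heterogeneous inputs (expression tables,
homology exports, trees, ChIP peaks), every stage is validated end to end
on synthetic cohorts with planted ground truth rather than on a frozen
external dataset. The synthetic-data generator is itself a first-class,
tested module.

## Expression normalization

Raw measurements are RPKM values, `1e9 * C / (N * L)` for `C` reads on an
exon model of `L` bp in a library of `N` mapped reads (`compute_rpkm()`).
Replicates within one (gene, species, organ, sex) batch are averaged;
female and male batches are never merged, because they are separate
library batches in the underlying design. Values are then log2-transformed
with a pseudocount (default 1, so zero RPKM maps to 0) and Z-scored within
each (species, organ, sex) stratum with the n−1 denominator
(`zscore_normalize()`). Z-scoring is what makes expression comparable
across organs and species with very different library depths and
transcriptome compositions.

Two conventions are deliberately configurable because the underlying
design leaves them open:

* **Sex pooling.** The default normalizes each sex batch separately
  (`pool_sexes = FALSE`); the pooled alternative is available. Neither can
  be asserted as "the original" and the calls are insensitive to the
  choice in our cohorts.
* **Pseudocount.** Default 1.0: monotone, bounded, and maps "not
  expressed" to exactly 0 on the log2 scale.

Missing sample batches — orangutan testis (both sexes), orangutan male
cerebellum, human female liver — are carried as absent rows, never
zero-filled, and every downstream operation tolerates the resulting
unbalanced group sizes.

`rank_bin()` reproduces the 0–7 expression-rank scale used for annotating
trees: 0 = not expressed, then percentile bins among the organ's expressed
genes with upper-closed boundaries at 5, 15, 35, 65, 85 and 95. The
percentile uses mean ranks for ties so tied values can never straddle a
bin boundary.

## Ortholog clusters

`build_clusters()` assembles template-anchored clusters from pairwise
ortholog tables (template species: chicken, whose inparalogs arrive
pre-grouped). Low-confidence pairs are discarded first; each template gene
or inparalog group seeds one cluster; a cluster is kept only if all nine
species contribute at least one gene. Within-species paralogs are allowed.
A cluster is *one-to-one* when every species has exactly one member —
only these are used for rate estimation. A target gene claimed by two
different template seeds is an error by default (`keep_first = TRUE`
relaxes it), since the source data should not contain such conflicts and
silently resolving them would hide upstream problems.

## The two-stage OSER caller

**Stage 1 — statistical screen.** For each cluster, the per-gene,
per-species, per-sex Z-scores are grouped by organ (up to 18 observations
per organ for a one-to-one cluster) and compared with a one-way ANOVA
followed by Tukey HSD over all 15 organ pairs (`organ_screen()`). An organ
is a candidate target when all five of its pairwise comparisons are
significant at `alpha = 0.05` in one direction. The *nervous tissue* group
(brain + cerebellum) is a candidate when brain and cerebellum are
statistically indistinguishable from each other while all eight
member-versus-outside pairs separate in one direction. Candidates are
evaluated in a fixed order (six organs, then tissue groups) and all
surviving candidates are kept, so one cluster may be expressed for one
target and repressed for another (dual calls).

The statistical primitives (`anova_oneway()`, `tukey_hsd()`,
`rank_sum_test()`) are implemented self-contained from the classical
formulas (sums of squares + F distribution; studentized range with the
Tukey–Kramer form for unequal n; exact rank-sum enumeration for combined
n ≤ 12, normal approximation with continuity and tie corrections
otherwise) and are cross-checked in the test suite against
`stats::aov()`, `stats::TukeyHSD()` and `stats::wilcox.test()` on random
fixtures, plus Monte-Carlo null calibration. The screen's wording admits
two readings — 15 separate two-group ANOVAs versus one omnibus ANOVA with
Tukey post-hocs; the omnibus + Tukey path is the default because it is the
standard multiple-comparison treatment for six groups, and the pairwise
reading is available as `detection_config(pairwise_anova = TRUE)`.
No correction is applied across clusters (the procedure applies none); a
`cluster_level_correction = "bh"` annotation hook exists.

**Stage 2 — expression-ratio filter.** Candidates are confirmed on the
natural RPKM scale (`fold_filter()`): *every* member gene must average at
least 50% higher (focal/rest ≥ 1.5) or at least 50% lower (focal/rest ≤
0.5) in the target organ than in the rest. Per gene, the focal value is
the mean RPKM in the target organ (for nervous tissue, the mean of the
brain and cerebellum organ means) and the rest value is the unweighted
mean of the other organs' per-organ means — per-organ means rather than a
pooled mean so that organs with more measurements do not dominate
(`rest_mean = "pooled"` is available). "50% lower" is read literally as
≤ 0.5 × rest, not as 1/1.5; both bounds are configurable. A gene whose
rest value is zero passes an expressed candidate and fails a repressed
one, with a warning; a gene with no focal-organ measurement at all (e.g.
the orangutan gene of a testis candidate) cannot vote and is excluded
from the all-genes requirement.

## Families, origins, duplications

Gene families are connected components of the combined ortholog + paralog
graph over 14 species (the nine focal species plus anole lizard, clawed
frog, zebrafish, lamprey, sea squirt). The source families are precomputed
database groupings; component closure over the same edge lists is the
reproducible stand-in and coincides with them whenever the edge lists are
complete. The origin stratum of a family is the deepest level witnessed by
a member species — Chordata (sea squirt), Craniata (lamprey),
Gnathostomata (zebrafish), Tetrapoda (clawed frog), Amniota (lizard or any
focal amniote) — and a cluster inherits the origin of its family.

A family containing more than one orthologous cluster experienced at least
one large-scale duplication, the clusters being mutually paralogous;
`duplication_profile()` counts them. `categorize_families()` contrasts
families whose OSER clusters all point at one organ/tissue (category 1)
with families targeting two or more (category 2) via the rank-sum test on
cluster counts. Within category 1, `family_profile_concordance()` re-runs
the full caller on the pooled expression of *all* family members and asks
whether the family-level call set still contains the cluster's (target,
direction). Concordance is not defined in the source procedure; "identical
(target, direction) membership" is our interpretive criterion, chosen
because it is the strictest check that uses only the caller itself.

## Evolutionary rates

The rate proxy of a one-to-one cluster is the total branch length of its
phylogenetic tree — the sum over all edges, internal and terminal
(`total_branch_length()`). Trees built under an empirical amino-acid model
accumulate substitutions per site along every branch, so the total acts as
the cumulative evolutionary rate of the cluster's nine genes. Only
one-to-one clusters are admitted: extra paralogs add branches and would
inflate the sum. Alignment and tree inference are consumed, not
implemented — the package reads newick (via `ape`), because the
scientific computation here is the summation and the group comparison
(`group_rate_comparison()`, rank-sum tests between (target, direction)
groups), not tree building. A missing branch length counts as 0 with a
warning, tolerating newick dialects; re-rooting never changes the sum
(property-tested).

## ChIP peak assignment

`assign_peaks()` assigns each peak to the gene minimizing the distance
between the peak midpoint and the strand-aware transcription start site,
and classifies the assignment *proximal* when that distance is ≤ 2500 bp,
*distal* otherwise. The anchor is the TSS (the ENCODE-consistent reading
of "within 2.5 kb of the nearest gene"); gene-body distance is available
as `anchor = "body"`. The boundary is inclusive; equidistant ties go to
the lexicographically smaller gene id; no maximum distance bounds
"distal". Per (target, site class), `tf_target_tally()` counts distinct
bound OSER genes per TF; `shared_tf_sets()` computes the intersection
over all targets together with all exclusive Venn regions;
`cross_species_overlap()` maps another species' bound genes through a
one-to-one ortholog table and reports the overlap as a percentage of the
human count, printed as an integer (one decimal below 10%).

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` generate every input with known
truth. What is emulated — and what is not:

* **Expression**: `log2(RPKM) = baseline + cluster effect + planted shift
  + noise`, with the cluster effect N(0, `gene_sd`²) shared by all
  orthologs of a cluster (conserved expression across species) and
  independent noise N(0, `noise_sd`²) per measurement. Defaults
  `gene_sd = 0.46`, `noise_sd = 0.2` give a within-stratum SD of 0.5.
  The split matters: the noise component is what two sex batches per
  organ must average over, and at 0.2 a planted gene's per-organ fold
  estimate has ~7% sampling error, so planted effects sit clear of the
  fold boundaries; a substantially noisier split would turn the
  all-genes fold rule into a coin flip for genes at the margin.
  Organ baselines are equal on the log2 scale: Z-scoring removes organ
  location anyway, and equal baselines keep the fold-filter geometry
  exact. Not emulated: heavy-tailed expression, correlated noise between
  organs, mappability artifacts — so passing tests demonstrate the
  machinery, not robustness to every pathology of real RNA-Seq.
* **Planted effects**: an expressed cluster is shifted by
  `log2(rpkm_fold)` (default fold 2.0 = shift of 2 within-stratum SDs on
  the Z scale) in its target organ(s); a repressed cluster is shifted to
  `repressed_fold = 0.375`. The repressed fold is deliberately *not*
  `1/rpkm_fold = 0.5`: that would place planted repressed clusters
  exactly on the ≤ 0.5 decision boundary, where detection measures noise
  sign rather than the method. Instead both directions are planted at
  the same log-margin from their boundary
  (`0.375 = 0.5 × 1.5 / 2.0`). Target/direction allocation follows the
  empirical spread of organ-specific calls (testis-expressed dominant,
  liver the only organ with a repressed majority).
* **Homology**: families drawn over origin strata (witness-species
  membership planted accordingly), duplications splitting families into
  several clusters, per-species losses and low-confidence demotions,
  within-species inparalogs, chicken inparalogs pre-grouped.
* **Trees**: random nine-leaf topologies with i.i.d. exponential edge
  lengths scaled by per-group rate multipliers (testis 2.5, liver 2.2,
  heart/kidney 1.5, nervous 1.0).
* **ChIP**: genes on synthetic chromosomes with TSSs 25–60 kb apart;
  peaks placed within 2.5 kb of the intended TSS (probability
  `proximal_fraction`) or 2.5–9 kb away — always nearer to the intended
  gene than to any neighbor, so truth labels and nearest-TSS assignment
  coincide by construction. Cross-species binding is conserved with
  probability `conservation_prob` plus independent background binding.

All generators are pure functions of (config, seed): the same seed gives
byte-identical output, which the pipeline's manifest (md5 checksums)
makes checkable.

## Validation scale and numerical choices

The shipped validation runs at sizes chosen to make every stochastic
check statistically sharp while remaining quick on one CPU: 2,000
clusters for null calibration of the caller (expected false-call rate
well under the 5% bound), 10,000 Monte-Carlo replicates for the type-I
error of the ANOVA and rank-sum tests (±0.01 resolution), 1,000 clusters
with 10% planted effects for sensitivity (observed ≥ 0.90 with correct
target and direction in ≥ 95% of recovered calls), 300 trees per group
for rate-ratio recovery (2.5 ± 0.3), and ≥ 100 random instances per
brute-force oracle comparison (cluster assembly, graph components,
branch-length sums, nearest-TSS assignment, Venn regions).

Numerical edge cases are pinned down explicitly: a completely flat
cluster returns F = 0, p = 1 and no call; zero within-group variance with
unequal means returns F = ∞, p = 0; Tukey p-values are clamped to [0, 1];
the exact/approximate switch of the rank-sum test sits at combined n =
12; fold boundaries are closed (ratio exactly 1.5 or 0.5 passes); the
proximal boundary is closed at exactly 2,500 bp; rank-bin boundaries are
closed on the upper side.

## Known limitations

* The caller's observation unit (gene × species × sex Z-scores) maximizes
  n but treats species as exchangeable replicates; phylogenetic
  non-independence is not modeled.
* Connected-component families are only as good as the edge lists; noisy
  paralog edges can merge families, and a cluster spanning two families
  is treated as an input error rather than resolved.
* The generator plants clean multiplicative effects; sensitivity numbers
  do not transfer to effects near the fold boundary, by design.
* GO/KEGG enrichment, sequence alignment and tree inference are outside
  the package: it consumes trees, it does not build them.
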