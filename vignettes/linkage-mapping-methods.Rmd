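---
title: "Methods: RAD-seq linkage maps from a single outbred F1 family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RAD-seq linkage maps from a single outbred F1 family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmapr)
```

# The problem

A draft genome assembly arrives as thousands of scaffolds with unknown
chromosomal order and orientation. `radmapr` anchors such scaffolds into
chromosome-level linkage groups using restriction-site-associated DNA
sequencing (RAD-seq) genotypes from a single mapping family: two outbred
parents and their F1 offspring. Recombination between markers during the
parents' meioses is the only source of ordering information, so everything
in the package is organised around extracting those recombination signals
from noisy, moderately covered sequencing data.

The pipeline runs in the order a mapping study proceeds:

1. depth-guided filtering of loci and individual genotype calls;
2. maximum-likelihood inference of each locus's parental cross-type under a
   global heterozygote-dropout rate, with correction of Mendelian-impossible
   genotypes;
3. segregation-distortion and parent-concordance filters;
4. pairwise recombination-fraction estimation and single-linkage clustering
   of scaffolds into linkage groups;
5. per-parent (sex-specific) map construction;
6. an equal-weight consensus that orders and orients scaffolds, exported as
   AGP with GFF liftover.

# Genotype model and dropout inference

At a biallelic SNP the informative parental combinations in an outbred
cross are `aa x ab`, `ab x aa`, `ab x ab` and `aa x bb`. Writing
`n_aa, n_ab, n_bb` for the offspring genotype counts at one locus, the
counts follow a multinomial distribution whose category probabilities
depend on the cross-type and on a global allelic-dropout rate *e*: a true
heterozygote is observed as one specific homozygote with probability *e*
(total dropout probability *2e*), because sequencing sampled only one
allele. The categories are

| cross-type | P(aa) | P(ab) | P(bb) |
|---|---|---|---|
| AA x AB | 0.5 + e/2 | 0.5 − e | e/2 |
| AB x BB | e/2 | 0.5 − e | 0.5 + e/2 |
| AB x AB | 0.25 + e/2 | 0.5 − e | 0.25 + e/2 |
| AA x BB | e | 1 − 2e | e |

each summing to one for every `e` in [0, 0.5]. The log-likelihood of a
locus is the multinomial `sum n_g log p_g`. A single global `e` is profiled
over all loci (each locus contributing its best-fitting cross-type), with a
coarse grid at step 0.005 refined by golden-section search; per-locus
cross-types are then the arg-max at the fitted `e`
(`estimate_global_e()`, `classify_loci()`).

At single-heterozygote loci the unexpected homozygote class is impossible
under Mendelian segregation, so those calls are corrected to heterozygotes
(`correct_dropout_genotypes()`). Double-heterozygote loci admit all three
genotypes and cannot be corrected; they are classified and tested but
excluded from mapping, because they are also the least powerful for
detecting distortion and the least safe to correct.

Distortion is tested per locus (`test_segregation()`): an exact two-sided
binomial test of the two permitted classes against 1:1 for
single-heterozygote types, a chi-square goodness of fit against 1:2:1
(df 2) for `ab x ab`, and p = 1 by convention for `aa x bb`, which
segregates nothing. The level is 0.05 two-sided with no multiplicity
correction — the filter is deliberately per-marker. Finally, loci whose
observed parental genotypes contradict the offspring-derived cross-type are
excluded; when only one parent is called, the cross-type fills in the other,
and when both are missing the locus is kept but flagged unoriented
(`concordance_filter()`).

# Filter cascade

Six filters run in a fixed order, each with a strict boundary convention (a
value exactly at a threshold survives; removals use strict inequalities):

* **A — pooled depth per position** (pre-genotyping): keep
  `2.0 <= log10(depth) <= 3.2`. RAD tags concentrate near 1000 pooled
  reads; far deeper positions are repetitive-sequence pile-ups.
* **B — locus allele balance**: keep
  `-2.32 <= log2(ref/alt) <= 2.6`. The window is asymmetric because read
  alignment is biased toward reference-carrying reads.
* **C — locus total depth**: keep totals in [320, 1400].
* **D — genotype depth**: calls with fewer than 8 or more than 40 reads go
  to missing.
* **E — heterozygote balance**: heterozygous calls with
  `|log2(ref/alt)| > 3.26` (or either allele at zero reads) go to missing.
* **F — locus missingness**: keep loci with at least 50 of 90 offspring
  called.

All thresholds live in `filter_config()`; `run_filter_cascade()` applies
them and returns an audit table (loci, called genotypes, percent missing
after each step). Filters D and E only ever blank calls, never change them.

# Recombination, clustering and ordering

Markers heterozygous in exactly one parent (pseudo-testcross markers) are
informative for recombination in that parent alone. Offspring reduce to two
phase classes (heterozygote vs expected homozygote); for two loci the
fraction estimate is `rf = min(d, n - d)/n` over the `n` co-called
offspring with `d` discordant pairs — the minimum over the two unknown
linkage phases. Estimates from fewer than 20 co-called offspring are
treated as unknown rather than 0.5, so sparse data cannot fabricate
linkage.

Several practical properties of this regime shaped the implementation, and
each was verified on simulations with known truth before being adopted:

* **Phase alignment.** The 0/1 phase classes of two markers are comparable
  only up to the heterozygous parent's linkage phase at each locus. Within
  a scaffold, markers are essentially fully linked, so signs are aligned by
  majority concordance (`align_scaffold_phase()`) before any within-scaffold
  voting.
* **Per-genotype cleaning.** Allelic dropout toward the *permitted*
  homozygote is invisible to Mendelian correction and flips a phase class
  in a few percent of calls. An interior marker call that disagrees with
  both physical neighbours while they agree implies a double crossover
  within a few hundred kb — overwhelmingly an artifact — and is blanked
  (`clean_phase_singletons()`). Genuine crossover steps are preserved. The
  locus-level variant (`remove_double_crossover_loci()`) additionally drops
  markers that keep flipping.
* **Scaffold consensus vectors.** Co-scaffold markers are co-inherited, so
  a per-scaffold, per-individual majority vote
  (`scaffold_consensus_phase()`) yields one low-noise phase vector per
  scaffold and parent. Scaffold-level fractions pool the phase-minimised
  discordance counts of the two parents (`pooled_scaffold_rf()`); the
  parents' vectors are never concatenated directly, because phase signs are
  arbitrary per scaffold *and* parent.

Scaffolds join linkage groups by single-linkage agglomeration at
`rf < 0.07` — a scaffold joins a group when any chain of sub-threshold
fractions connects it, which is exactly the connected components of the
thresholded graph (`cluster_scaffolds()`). Groups are numbered by
descending total scaffold length. Clusters with at least two scaffolds are
reported as linkage groups; singletons are the unplaced set, mirroring the
anchored/unplaced split a mapping study reports. Scaffolds whose markers
form two internally linked but mutually unlinked blocks are flagged as
likely chimeric joins (`flag_chimeric_scaffolds()`, within-block mean
rf < 0.07, between-block > 0.3, at least two markers per block) but are
kept intact — a deliberately conservative choice, since low-coverage
correct scaffolds are hard to distinguish from chimeras. Loci linking to
two or more groups are dropped (`exclude_multigroup_loci()`), and each
scaffold's markers are thinned to the five most complete per cross-type
class (`thin_markers()`): near-identical markers add computation, not
resolution.

Within a linkage group, marker order is a seriation problem. The generic
operation (`order_markers()`) minimises the sum of adjacent recombination
fractions by greedy nearest-neighbour construction plus 2-opt and
reinsertion refinement from multiple deterministic starts. For scaffold
ordering the package instead embeds the (path-completed, Haldane-scaled)
scaffold distance matrix in one dimension by classical multidimensional
scaling and polishes with adjacent swaps (`seriate_scaffolds()`): with few
sampled crossovers the adjacency-only objective has many spurious optima —
orders with a *lower* adjacent-fraction sum than the true order — whereas
the principal coordinate uses every pairwise estimate at once. Unknown
entries are filled by min-plus shortest paths (`complete_rf_paths()`),
valid because fractions are nearly additive when small, and estimates are
shrunk to `(d + 1/2)/(n + 1)` so that a zero over few meioses cannot
undercut a zero over many.

Distances convert to centimorgans with the Haldane map function
`d = -50 ln(1 - 2r)` (Kosambi available), chosen for self-consistency with
the simulator's interference-free crossover process. Map positions are
assigned at scaffold resolution: the residual per-call error floor —
estimated from split-half discordance within scaffolds, where true
recombination is negligible (`phase_error_floor()`) — is subtracted from
each adjacent fraction. Without this, every marker-to-marker interval
inherits the error floor and the map expands several-fold, the classic
genotyping-error map-inflation pathology.

# Consensus, orientation and export

`merge_maps()` pairs the maternal and paternal linkage groups by Jaccard
overlap of scaffold content, reflects the paternal group when its shared
scaffolds anticorrelate, and orders each chromosome's scaffolds by the
pooled-meiosis seriation above — both parents' meioses weighted equally.
Scaffolds that no sampled meiosis separates stay tied and fall back to the
mean of their rescaled per-map positions, then to their identifier, so the
output is deterministic.

Orientation uses crossover-event reconstruction rather than a bp-vs-cM
correlation: the within-scaffold cM gradient is direction-symmetric, so it
cannot tell a forward scaffold from a reversed one. Instead, for each
meiosis whose flanking scaffolds carry different phases (a crossover in the
neighbourhood), the scaffold's own markers are read in physical order: a
clean step from the left-flank phase to the right-flank phase votes `+`, the
reverse votes `-`, and non-monotone patterns are rejected as noise. A
scaffold is oriented only when all its votes agree; otherwise it is
anchored but unoriented (`?`), and `orientation_support` records the number
of informative meioses. With short scaffolds few crossovers fall inside a
scaffold's marker span, so most anchored scaffolds legitimately remain
unoriented — the anchored-versus-oriented distinction any scaffold-anchored
map reports.

The consensus is exported as AGP v2.0 (`write_agp()`; scaffolds as `W`
components, 100 bp `U` gaps of type "map", the conventional unknown-gap
size) and gene annotations are lifted onto chromosome coordinates by direct
affine/reflective coordinate arithmetic (`liftover_gff()`), preserving
feature lengths exactly; chain-file semantics are intentionally not
reproduced.

# The simulator and what passing tests mean

`simulate_f1_cross()` generates the full study design with known truth: a
24-chromosome genome fragmented into 20 scaffolds per chromosome
(Dirichlet lengths, shuffled and randomly flipped to form the "assembly"
frame, with the inverse mapping recorded as a truth AGP); RAD sites at 5-10
per scaffold; 90 offspring; crossovers as an interference-free Poisson
process at 2.34 cM/Mb; per-locus log-normal tag efficiency centred at 1000
pooled reads with negative-binomial per-genotype depth (dispersion 8,
coefficient of variation 0.25 across loci); parents sequenced at three
times the per-offspring effort, reflecting a multi-barcode design;
repetitive regions (2% of loci) at 30-fold depth; heterozygote dropout at
`2e = 0.10`; and a 0.2% uniform genotype-error rate. Chromosomes are
scaled to 5 Mb to keep a full genome small; the recombination density per
Mb keeps its empirical value, so each chromosome spans about 11.7 cM.

Two generative choices keep estimation well-posed. Crossovers are simulated
without interference, matching the Haldane function used downstream. And
`e` is *exactly* the total het-to-homozygote observation rate: non-dropout
heterozygotes draw their allele split from a binomial truncated to both
alleles observed. Otherwise low-depth sampling would add an e-independent
dropout channel, and the no-dropout control (zero corrections at `e = 0`)
could not hold.

What the simulator does not model: read-level errors and FASTQ output,
restriction-site polymorphism (dropout is depth-independent), the
low-coverage paired-end mass seen in real pooled-depth distributions,
segregation distortion with a biological cause, and chimeric assembly
joins (those are exercised by dedicated fixtures instead). Passing
recovery tests therefore demonstrates internal consistency of estimator
and generator under realistic depth, missingness and dropout — not
robustness to every artifact of a real library.

# Known limitations

The stated study design bounds what any estimator can recover. At ~11
reads per genotype, the 8-40 depth window blanks roughly a third of calls
(matching the missingness a real study of this design reports), and
scaffold-pair recombination estimates lose the individuals either scaffold
misses. Re-running the seriation on error-free calls masked with the same
missingness pattern changes the recovered orders very little — the
implementation sits at that ceiling — but the ceiling itself is
substantially below perfect ordering: with ~20 crossovers sampled per
chromosome across both parents and 20 scaffolds to place, adjacent
scaffolds are frequently separated by no observed recombination at all.
Consensus orders are therefore good at chromosome scale and fuzzy locally,
and only the few scaffolds with internal crossover evidence can be
oriented. Longer scaffolds, more offspring, or deeper sequencing — not a
different algorithm — are what would move these numbers. The acceptance
suite states the corresponding targets at their nominal values and reports
honestly against them.

Problem sizes used throughout the tests (two-chromosome genomes for unit
tests, the full 24-chromosome design for recovery checks, a handful of
fixed seeds) are the package's choice of a desk-scale validation design.
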