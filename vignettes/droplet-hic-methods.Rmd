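---
title: "Droplet single-cell Hi-C processing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet single-cell Hi-C processing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droplethic)
```

# Scope

`droplethic` processes droplet-based single-cell Hi-C data from
barcode-annotated read pairs to called cells, per-cell A/B compartment
(scA/B) scores, pseudobulk and metacell contact maps, insulation/TAD
statistics, and differential chromatin-architecture tests between
conditions. Read alignment, contact-map imputation, embedding and
clustering are out of scope: cluster and metacell labels are *inputs* to
the aggregation and differential stages. Every stage can be exercised on
synthetic data with known truth, generated by the `sim_*` family.

# From reads to contacts

**Barcode correction.** Index reads are matched against a fixed-length
whitelist. An exact member is kept as-is; otherwise the read is assigned
to the unique whitelist member within one substitution (Hamming
distance), and reads with zero or multiple one-mismatch hits are
discarded. `N` bases count as mismatches at their position — the
conservative convention aligners use. The implementation enumerates the
3L one-base variants of the observed barcode against a hashed set, which
scales to 737K-entry whitelists while provably returning the same answer
as a full scan (the test suite checks this equivalence against a
brute-force oracle). No abundance-based tie-breaking is attempted: two
candidate parents mean the read is discarded. Multiome chromatin
barcodes are translated to their paired RNA barcodes by line-number
lookup in a paired whitelist.

**Contact extraction.** Both legs must be mapped with mapping quality at
least 20 (pairs with either leg below are discarded), and cis pairs at
distance ≤ 1 kb are dropped as self-ligation/religation artifacts, so a
"contact" is intra-chromosomal above 1 kb or inter-chromosomal. Legs
are stored unstranded in canonical order: chromosomes in the order of
the sizes file, positions ascending within a chromosome, 1-based, per
the 4DN pairs convention. Bins are 0-based half-open.

**Barcode-aware deduplication.** Two contacts are duplicates iff they
share the cell barcode and chromosome pair and both legs lie within
`dup_dist` (default 100 bp). Including the barcode in the duplicate key
is essential in droplet data: distinct cells legitimately produce
near-identical coordinates. Duplicate chains collapse greedily to the
first member in (barcode, chrom1, chrom2, pos1, pos2) sort order — a
deterministic rule, checked against an O(n²) clustering oracle. The
window comparison happens after canonicalization. Per-barcode totals,
unique counts, cis/trans splits, duplication rate (1 − unique/total) and
trans rate feed QC and cell calling.

# Cell calling on the barcode-rank curve

Droplet microfluidics yields many barcodes carrying only a handful of
contacts. True cells are separated from this ambient cloud by a knee
point on the barcode-rank curve (rank vs contact count, both log10: the
curve spans orders of magnitude on both axes).

The detector builds the kneedle difference curve: min-max normalize both
axes, reflect the decreasing curve to concave-increasing, and form
`d = y_n − x_n`. Local maxima of `d` are knee candidates, scored by
**prominence** — the rise of `d` from the preceding local minimum.
Candidates with prominence at or below the noise floor
`S · mean(Δx_n)` (S = sensitivity) are discarded; the knee is placed at
the steepest single step of the most prominent surviving rise.

Why prominence rather than the textbook first-passed-threshold walk? A
barcode-rank curve is S-shaped in log-log space: a cell plateau, a
cliff, and an ambient slope. With tens of thousands of points the noise
floor `S · mean(Δx_n)` is ~10⁻⁵–10⁻⁴, far below the ~10⁻³ kinks that
order-statistic spacing produces on the cell plateau, so a
first-accepted-candidate walk reliably stops at the first noise kink
and calls a few dozen "cells" (we measured 16% contact retention on a
500-cell/50,000-ambient mixture, at every sensitivity). The cliff, by
contrast, produces a difference-curve rise two orders of magnitude above
any noise kink, and its steepest step is the cell/ambient boundary
itself, so the prominence-maximal rise is a stable estimator of the
turning point and the knee lands on the last barcode of the cell
shoulder. One consequence is that larger S never moves the knee
earlier: the knee is unchanged while the dominant rise survives the
noise floor and becomes undefined beyond it.

**Adaptive sensitivity selection.** The sensitivity is swept (default
1–10) and the chosen value is the one whose called barcodes most
closely retain *over* 85% of all contacts: among sensitivities at or
above the target the smallest retained fraction wins; if none reaches
it, the largest is returned with a warning flag. Ties at the threshold
count are always called — deterministic, and downstream QC can still
remove them. On clean curves all sensitivities give the same knee and
the sweep acts as a robustness guard rather than a tuner; the selection
rule still protects against the degenerate knees that very noisy curves
can produce at individual sensitivities.

# Species mixing, cell-cycle metrics and joint QC

In a barnyard design, reads are assigned to a genome by the
chromosome-name prefix of the concatenated two-species reference. The
mixing rate of a barcode is `min(n_A, n_B) / (n_A + n_B)` — symmetric in
the genomes, in [0, 0.5] — and a barcode is a doublet iff its mixing
rate is strictly above 0.20. Reads below mapping quality 20 are excluded
upstream.

Cell-cycle metrics are per-cell distance-band mass fractions of cis
contacts — short [25 kb, 2 Mb), mitotic [2 Mb, 12 Mb), far [12 Mb, ∞) —
plus the trans fraction. Condensed mitotic chromosomes enrich the
2–12 Mb band. The package deliberately emits *metrics, not phase
labels*: the decision boundaries used for phasing in the literature are
not restated here, so labeling is left to a user-supplied rule table.

The multiome joint filter keeps cells with > 500 UMIs, > 400 genes,
> 1000 contact pairs, < 10% mitochondrial content, and < 45%
inter-chromosomal contact rate — all strict inequalities; a missing
metric fails the cell with reason `"incomplete"`.

# scA/B compartment scores

The per-cell compartment score of bin *b* is the mean CpG density of the
partner bins of all contacts with one leg in *b* (a contact with both
legs in *b* is excluded; each contact contributes its other leg with
weight 1). CpG density is computed per bin as the count of CG
dinucleotides whose first base lies in the bin, divided by bin length —
case-insensitive, ambiguous bases never form a CpG, and an
edge-straddling CpG counts once, in the bin of its C. Because active
(A) chromatin is CpG-rich and contacts are compartment-assortative, a
bin's partner-CpG average tracks its compartment membership; raw values
are bounded by the CpG track's range by construction.

Both cis and trans partners contribute by default (`cis_only` and
`min_dist` are exposed); bins with fewer than `min_partner_contacts`
(default 1) partner contacts are masked, never zero-filled. Z-score
normalization is per cell over unmasked bins (population sd), making
cells comparable for marker-set averaging; cells with fewer than two
unmasked bins or constant values are left raw and flagged. The raw
matrix is kept for gene-module analyses, the z-scored matrix for
bin-level comparison — the two normalizations serve different
downstream statistics and are never mixed.

Gene-level scores average a gene body's overlapped bins (any overlap, no
flanks). Cell typing scores each cell against marker-gene sets (top
markers per type) as the mean scA/B over the set's bins, then labels a
cluster with the argmax of the cluster-mean score; exact ties break by
type order and are flagged.

# Contact maps, balancing and topology

**Aggregation.** Contacts pool by group label into symmetric binned
count matrices; total mass (upper triangle + diagonal) equals the number
of labeled contacts, so mass is conserved across any partition of the
cells — a property the tests assert exactly.

**Balancing.** Iterative correction drives the balanced matrix
`W = diag(w) C diag(w)` toward equal row marginals (target 1),
converging when the marginal coefficient of variation falls below
`tol` (default 10⁻⁵, `max_iter` 200, square-root damped updates).
Low-coverage bins are excluded beforehand by a MAD-max rule on log10
marginals (default 5 MADs below the median — standard
iterative-correction hygiene); they receive `NA` weights and stay masked
downstream. A doubly-stochastic matrix is a fixed point (weights 1), and
a diagonal matrix yields weights ∝ 1/√(row mass) — both are unit tests.

**Distance decay.** P(s) divides observed cis contacts in log-spaced
distance bands by the exact number of locus pairs at those distances
(`Σ_chrom (L − s)`), so the estimator is linear in counts and unbiased
up to distances comparable to chromosome length.

**Insulation.** The insulation square value of bin *i* is the mean
balanced interaction in the window×window square `[i−w, i) × [i, i+w)`;
the normalized score is its log2 ratio to the chromosome mean. Uniform
matrices score exactly 0, the track is invariant under global scaling,
and bins within one window of a chromosome end are missing. TAD
boundaries are local minima of the normalized score with prominence
(the smaller rise to the flanking maxima) ≥ `min_strength` (default 0.1
log2 units — the tools this follows rely on defaults of this order, and
the value is exposed). Boundary usage of a gene in a cluster is the
fraction of cluster members (cells or metacells — the membership list is
caller-supplied) whose boundary set contains the TSS bin.

**Domain melting.** For genes longer than 300 kb, scored at 50-kb
resolution, the per-bin insulation-square values over the gene domain
are compared between a reference and a target condition with a
two-sample Kolmogorov–Smirnov test; the melting score is −log10 p. A
domain is *melted* when the values decreased in the target condition
(domain structure lost) and *established* when they increased; swapping
the conditions flips the direction and preserves the score. Genes with
fewer than 4 scored bins per condition are flagged underpowered. The
call threshold defaults to score ≥ 5 and is exposed.

# Differential compartmentalization

Metacells — pools of architecturally similar cells under supplied
sub-cluster labels — are the unit of replication: testing over single
cells would pseudoreplicate, while metacell medians are stable. A
metacell's per-bin value is the median of its members' unmasked scA/B
values, masked when fewer than half the members are unmasked.

Per bin, groups A and B of metacells are compared with the Wilcoxon
rank-sum test (midrank ties; exact enumeration when n₁+n₂ ≤ 12 without
ties, else normal approximation with tie and continuity corrections —
delegated to `stats::wilcox.test`, with the exact branch verified
against full enumeration in the tests). Benjamini–Hochberg adjustment
runs over all tested bins within one comparison, mirroring
per-comparison differential testing practice, with no fold-change-style
pre-filter. Bins with adjusted p < 0.01 are retained; the change
summary additionally requires |Δ| > 0.05, where Δ is the difference of
group medians, split by sign into increased/decreased. Bins masked in
more than half of either group are recorded untested.

Gene-module scores are means of *raw* scA/B over the module genes' bins
per metacell, compared between timepoints pairwise (rank-sum + BH,
significance at adjusted p < 0.01).

# The synthetic-data generators

All generators are deterministic given a seed, draw each component
(genome, barcodes, positions, duplicates, errors) from a fixed
sub-seed so toggling one feature does not shift the others, and emit
truth tables sufficient to score every downstream stage.

* `sim_genome` builds alternating A/B compartment blocks; each bin's
  CpG density is drawn from its block's distribution (A ≈ 0.02/bp, B ≈
  0.005/bp, 10% relative sd) and *realized in sequence* — CG
  dinucleotides planted at non-overlapping positions in an A/T
  background — so `cpg_density()` recovers the target to within a few
  percent and no accidental CpGs arise.
* `sim_cells` draws per-cell contact totals (log-normal), cis distances
  from a truncated power law (exponent −1 by default), leg placement
  uniform with out-of-range rejection (so realized counts carry the
  `L − s` pair-availability factor and the decay estimator recovers the
  exponent), within-compartment partners enriched 5× by
  acceptance-rejection, 10% trans contacts, duplicates re-emitted with
  per-leg jitter uniform on [0, dup_dist], and one-base barcode errors
  at 2%. Ambient barcodes draw small Poisson counts. Cell types are
  expressed as per-type compartment flips of chosen bins.
* `sim_barcode_mixture` generates the barcode-rank conditions at count
  level only (500 cells, log-normal mean 20,000, log-sd 0.5; 50,000
  ambient barcodes, mean 20, log-sd 0.8): cell calling consumes counts,
  so materializing ~10⁷ contact records would add nothing.
* `sim_barnyard` plants doublets (1:1 genome mix) among singlets with
  ≤ 2% cross-species noise.
* `sim_aging_cohort` generates per-cell scA/B profiles directly from
  the planted compartment model: three timepoints × 15 metacells × 10
  cells, 1000 bins of 500 kb, per-cell bin noise sd 0.2, a 0.2 shift
  planted in 50 bins of old cells only, young and middle identically
  distributed, optional gene-module elevation. Generating the cohort at
  the scA/B level (rather than via ~10⁸ simulated contacts) keeps the
  differential stage testable at desk scale; the contact→scA/B path is
  exercised separately by `sim_cells`. The cohort sizes correspond to a
  well-powered study: with metacell-median noise ≈ 0.08, a 0.2 shift
  gives near-complete group separation at n = 15 vs 15.

**What the simulator does not emulate.** Real restriction-site
placement, polymer 3D structure, distance-dependent duplicate structure,
chromatin-state-specific coverage biases, index-hopping, and the RNA
modality beyond the per-cell summary metrics the joint QC consumes.
Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under the stated generative model, not
end-to-end fidelity on sequencing data.

# Numerical choices and degenerate inputs

* Chromosome order is the sizes-file order; canonicalization, bin
  ordinals and leg ordering all derive from it.
* Knee detection uses log10 axes; counts of 0 are floored at 0.5 before
  the log. Degenerate curves (all counts equal, single barcode) error
  with advice to set a manual threshold (`threshold_cell_call()`).
* Rank-curve ties keep stable input order; threshold ties are called.
* P(s) slope fits should stay below ~L/4, where the `L − s` correction
  is well-conditioned; the decay-recovery tests fit 3 kb–5 Mb on 20-Mb
  chromosomes. Slope calibration uses enrichment = 1 because
  compartment acceptance-rejection modulates the marginal decay by
  construction.
* Balancing on empty/degenerate matrices returns all-NA weights with a
  non-convergence flag rather than erroring.
* Identical pooled samples short-circuit to p = 1 in the rank-sum test;
  identical insulation-square multisets short-circuit to KS p = 1
  (avoiding tie warnings on a test that is exactly null).
* Problem sizes in the test suite — 10–25 cells at 10³–10⁴ contacts on
  two 10–20 Mb chromosomes, 1000-bin cohorts, 100-instance oracle
  sweeps — were chosen so each statistical check retains clear margins
  at desk scale.

# Known limitations

* The knee detector is designed for cliff-shaped rank curves; on smooth
  convex curves without a dominant rise its placement at the steepest
  step degenerates toward the curve start. Barcode-rank curves from
  droplet assays are cliff-shaped whenever cells are present.
* Greedy first-kept deduplication is order-defined: a chain of contacts
  spaced just under `dup_dist` collapses to its first member, which can
  differ from a clustering that optimizes representative choice. The
  oracle encodes the same rule.
* Insulation uses dense per-chromosome submatrices; at 10-kb resolution
  on mammalian genomes, process one chromosome at a time.
* The rank-sum normal approximation is used for all tied samples
  regardless of size; for tiny tied samples exact conditional p-values
  would differ slightly.
* `melting_score` compares per-bin value distributions; it does not
  model spatial autocorrelation along the gene domain, so its p-values
  are calibrated only under approximate bin exchangeability.
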