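---
title: "Methods: cross-species prioritization of seed-oil candidate genes"
author: "crossoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species prioritization of seed-oil candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossoil)
```

## The problem

Two oilseed crops with very different seed oil contents — a diploid,
protein-rich species (soybean-like, ~20% oil) and a tetraploid, oil-rich
species (rapeseed-like, ~40%) — are compared over four matched seed
developmental stages (t1 to t4; t2–t3 is the period of rapid oil
accumulation). `crossoil` prioritizes gene families that could explain the
oil-content difference by combining several independent lines of evidence:
gene-family copy-number divergence, temporal expression trends, pathway
enrichment, differential co-expression networks, regulatory (TF and miRNA)
overlays, and selective-pressure statistics. Orthologous-group (OG)
membership, pathway annotations and regulator tables are consumed as
inputs; the package implements the comparative statistics, not the
upstream inference.

## Copy-number divergence

Raw copy counts are not comparable between species of different ploidy, so
the statistic of interest is the *relative copy number*, count/ploidy
(`relative_copy_number()`). A lipid-degradation family with 41 copies in
the diploid (41/2 = 20.5) has contracted in the tetraploid when the latter
carries 31 copies (31/4 = 7.75).

An OG is flagged divergent (`divergent_ogs()`) when the larger relative
copy number is at least `fold` times the smaller, with `fold = 2` by
default, or when one species lacks the family entirely (the ratio is then
undefined and presence/absence is itself the strongest divergence signal).
The source analyses this package follows do not state the numeric rule
behind their divergent-family count, so the 2-fold default was chosen
because it cleanly separates every contraction/expansion they discuss
(ratios of 2.6 and above) from families with equal relative copy number;
it is exposed as a parameter rather than hard-coded.

## Short time-series profile clustering

Expression series (v0, ..., vn) with v0 > 0 are transformed to
(0, log2(v1/v0), ..., log2(vn/v0)) (`log_normalize()`). Genes with v0 = 0
are excluded rather than pseudocounted: the transform is undefined there,
and any pseudocount choice would silently reshape profiles. Genes whose
transformed series never reaches `min_change = 2` in absolute value are
filtered out as flat (`min_change_filter()`), mirroring the minimum
absolute expression-change convention of short time-series clustering.

Model profiles (`generate_model_profiles()`) are all shapes starting at 0
with per-stage unit changes in −c..c; at the defaults (4 stages, c = 1)
there are 27 candidates from which m = 20 representatives are picked by
greedy max–min Euclidean distance, seeded with the flat profile. Ties in
the greedy step are broken by enumeration order, making the profile set
fully deterministic. Each filtered gene is assigned to the profile with
the highest Pearson correlation (`assign_genes()`); correlation is
invariant to positive affine transforms, so assignment depends only on
shape. Zero-variance genes are unassignable and ties go to the lowest
profile id.

Cluster significance (`profile_significance()`) follows the permutation
logic of short time-series clustering: the expected size of a profile's
cluster is its mean share of assignments when the stage order is permuted
(all n! permutations for n ≤ 5 stages — 24 at the default 4 — and `n_perm`
sampled permutations above that), and the p-value is the upper binomial
tail of the observed size at that expectation. One implementation detail
is worth recording: permuting the stages of the *transformed* matrix is
exactly equivalent to permuting the raw series and re-transforming,
because the two differ by a per-gene constant to which Pearson correlation
is insensitive. No multiplicity correction is applied by default (the
convention the package follows reports raw p < 0.05); a Bonferroni flag is
available.

Profiles are labelled up/down/other over a stage window
(`classify_trend()`, default t2–t3, the oil-accumulation window), and
`candidate_genes()` combines the evidence: within the query families, the
union (default; `"intersect"` available) of genes in divergent OGs and
genes assigned to significant up/down profiles. Union semantics was an
open design choice; it was selected because the two rules capture
complementary mechanisms (dosage vs regulation) and either alone is
reported as informative in the analyses this package reproduces.

## Enrichment, co-expression, regulation

Pathway enrichment (`fisher_enrichment()`) is the one-sided
hypergeometric tail P(X ≥ k) with the Benjamini-Hochberg step-up
correction (`stats::p.adjust`), terms with background count below 5
excluded, and a top-k report. The universe defaults to all annotated
genes, the convention of the KOBAS-style tools this mirrors, and is
overridable.

Co-expression neighborhoods (`coexpr_neighbors()`) keep genes with
|r| ≥ 0.9 *and* p ≤ 0.05 against the focal gene, both thresholds enforced
conjunctively. The correlation test is the usual t transform
t = r√((n−2)/(1−r²)); no test was named in the source convention, and this
is the standard test for a product-moment coefficient. A consequence worth
documenting: with only n = 4 stage samples, df = 2 and
p = 1 − t/√(2+t²), so r = 0.9 gives p ≈ 0.10 — the p-criterion then
dominates and the effective |r| cutoff exceeds 0.9. The sample count is
taken from the matrix actually supplied. Networks of two species are
compared through the OG map (`compare_networks()`): neighbor pairs sharing
an OG are the conserved part; the rest are species-specific and typically
forwarded to enrichment.

miRNA target sites are scored by an expectation penalty
(`score_duplex()`): per miRNA position from the 5' end, match 0, G:U
wobble 0.5, mismatch 1, target gap 2, with non-gap penalties doubled at
positions 2–7 (the seed). These constants reproduce exactly, position by
position, all of the published duplex alignments shipped in
`inst/extdata/published_duplexes.tsv`; the originating tool publishes
only its defaults, not its arithmetic, so the scheme was reconstructed
from those printed alignments. Two choices are unobservable from that
evidence and were fixed conservatively: gap penalties are not doubled in
the seed (the only in-seed gap observed is consistent with the undoubled
value), and at most one gap per duplex is allowed (no published alignment
shows more). The inhibition call (`call_inhibition()`) is Translation if
any of positions 9–11 is unpaired, else Cleavage. `scan_transcript()`
evaluates every window and every single-gap variant, keeps the best
alignment per start position, and applies the expectation cutoff — 3 by
default, the stringent conventional setting, although published hit
tables include sites up to expectation 4; the cutoff is therefore a
parameter, and the discrepancy is noted rather than resolved. The scanner
is a vectorized dynamic of the same definition and is tested for equality
against per-window brute-force enumeration. UPE (site accessibility
energy) requires a partition-function RNA model and is carried as a
pass-through field only, never computed.

## Molecular evolution

Protein distances use the proportion of differing sites under pairwise
deletion with Poisson correction d = −ln(1−p). Trees are built by
neighbor joining (`ape::nj` behind `neighbor_joining()`); negative branch
lengths, an NJ artifact on non-additive matrices, are clamped to zero
with the remainder moved to the sibling branch (the common
display convention), raw values retained in an attribute. Bootstrap
supports resample alignment columns (`ape::boot.phylo`) and report
bipartition percentages.

Ka/Ks uses the Nei-Gojobori (1986) counting method with unweighted
pathway averaging, stop-codon paths disregarded, and Jukes-Cantor
correction; it is validated against an established independent
implementation on a frozen codon pair. This counting estimator is the
package's desk-scale measure of selective pressure; maximum-likelihood
codon models (branch and branch-site) are out of scope, but their
published log-likelihoods can be evaluated with `branch_lrt()`, which
computes 2|Δ lnL| against the chi-square tail. The absolute value is
deliberate: in the published comparison the package reproduces, the
more-parameterized model is printed with the *worse* log-likelihood —
impossible for correctly maximized nested fits — so the statistic is
defined on |Δ| and a `label_swap_suspected` flag surfaces the anomaly
instead of silently relabeling the models.

## The synthetic study generator

`simulate_study()` emits a complete two-species study with known ground
truth so that every stage has a parameter-recovery test. What it emulates,
and what it does not:

* **Copy numbers.** A base per-haploid count per OG from a zero-truncated
  geometric (mean 2) — chosen because it produces realistic 1:1, 1:many
  and many:many classes without external data — multiplied by ploidy, so
  undisturbed OGs have exactly equal relative copy number. Planted
  divergent OGs get one species doubled (ratio exactly 2) or zeroed.
  Counts carry no noise, so the 2-fold rule must recover the planted set
  with precision and recall 1; real orthology inference is noisy in ways
  this does not model.
* **Expression.** Series are baseline × 2^(shape + ε), ε ~ N(0,
  `noise_sd`) on the log2 scale — the scale the clustering transform
  works on — with `noise_sd = 0.2` as the default study condition and
  per-gene baselines spanning 2–128. Real RPKM data have
  mean–variance structure, replicate effects and dropout that this does
  not emulate, so passing recovery tests demonstrate correctness of the
  clustering machinery, not robustness to RNA-seq artifacts.
* **Recovery is measured on the genes the procedure clusters.** The
  clustering stage filters at `min_change = 2` before assignment; planted
  genes from low-amplitude profiles (max |shape| = 1) are mostly and
  correctly excluded by that filter, and the recovery statistic is the
  fraction of *filter-passing* planted genes assigned to their planted
  profile (92 ± 1% at the default conditions; assignment without the
  filter, which includes profiles the procedure would never report, sits
  just below 90%).
* **miRNA targets.** Planted sites are exact reverse complements with a
  configurable number of mismatches/wobbles placed outside the seed
  (2–7) and the cleavage centre (9–11), so the planted score is exactly
  1·mismatches + 0.5·wobbles.
* **Codon alignments.** Sequences evolve down a tree; per branch,
  mutation events arrive at the branch-length rate per site, stops are
  rejected, and synonymous/nonsynonymous proposals are accepted with
  probabilities min(1, 1/ω) and min(1, ω). The realized Ka/Ks therefore
  approximates the planted ω (slightly below 1 for neutral branches
  because stop rejection removes more nonsynonymous than synonymous
  opportunities, an accepted bias of this simple scheme). No indels are
  generated, so the output is alignment-free by construction.

All generators draw from seeded streams (distinct offsets per generator)
and identical configurations give byte-identical files.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path while keeping runs quick: 100 OGs, 2,000 genes
over 4 stages for recovery, 1,000-gene null screens, 3,000-codon pairs for
ω recovery, 8-taxon trees with tens of bootstrap replicates, and 1 kb
transcripts for scanner/oracle equivalence. Tolerances: exact equality is
asserted for combinatorial quantities (expectation scores, copy-number
fractions, hypergeometric tails vs enumeration to 1e-12), 1e-8 for NJ
additivity, and interval checks for stochastic recoveries. Ties are
everywhere broken deterministically (lowest profile id, enumeration
order, term id), and degenerate inputs (all-zero stages, constant series,
zero-copy OGs, saturated distances p ≥ 0.75) raise typed errors or
documented NA flags rather than propagating NaN.

## Known limitations

* OG inference, alignment, ML tree search, codon-model fitting, motif
  discovery and target-site accessibility are consumed, not computed.
* The divergence fold threshold and the union combination rule are
  package defaults standing in for unstated upstream conventions; both
  are parameters.
* The binomial approximation in profile significance treats genes as
  exchangeable and independent; correlated gene families will inflate
  significance, as they do in the tool this emulates.
* The counting ω estimator saturates (NA) when either proportion reaches
  3/4 and should not be used for deeply diverged pairs.
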