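---
title: "Comparative plastome analysis with plastomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## The analysis

Chloroplast genomes (plastomes) of related plant taxa share a nearly
constant set of 70–80 protein-coding genes, yet individual genes
repeatedly lose function: a frameshifting indel, a premature stop codon,
or a truncating deletion turns a gene into a pseudogene in one lineage
while it stays intact in others. `plastomics` implements a comparative
pipeline over per-gene coding sequences from many taxa:

1. **Pseudogene calling.** Each taxon's copy of a gene is aligned to an
   intact reference copy and walked in the reference frame; the first of
   a persistent frameshift, an in-frame premature stop, or a terminal
   truncating deletion is recorded, together with the fraction of the
   gene preserved before it. The calls populate a gene-by-taxon status
   matrix (the classic heatmap of pseudogenization and loss).
2. **Windowed alignment tracks.** GC content, gap share, and parsimony
   substitution counts on a fixed tree topology in non-overlapping
   100-bp windows over the concatenated alignment.
3. **Per-gene evolutionary rates.** Pseudogenized rows are masked with
   gaps, genes are concatenated, reference branch lengths are estimated
   once under JC69, and each gene receives a maximum-likelihood scalar
   multiplier of those branch lengths. Rates are reported relative to
   the across-gene mean.
4. **Selection.** Gene-wide Kn/Ks by Nei–Gojobori counting; two
   independent per-site tests (a counting test on reconstructed
   ancestral codons and an empirical-Bayes rate grid); a consensus rule
   that flags only sites found by both; a per-branch Kn/Ks screen; and
   ontology-level enrichment of consensus sites by Fisher's exact test
   with Holm–Bonferroni adjustment across the pairwise family.

Every stage is exercisable end-to-end on synthetic data with known
ground truth, generated by the package's own codon-model simulator.

## The models and their assumptions

### Pseudogene scanner

The scanner aligns the query to the reference with the query global and
the reference local (free reference end gaps), so a truncated gene comes
out as a clean terminal deletion run rather than a scatter of interior
gaps. Three lesion rules apply, in reference-codon coordinates:

* **Frameshift**: the cumulative net indel length becomes non-zero
  modulo 3 and stays so for at least `frameshift_window` codons
  (default F = 10). A compensating indel inside the window restores the
  frame and no lesion is called — a compensated frameshift is treated as
  evidence of continued function, not of loss.
* **Premature stop**: an in-frame stop codon in the query at a
  reference codon before the last. Stops in the final 5% of codons are
  tolerated with a warning (default `terminal_stop_tolerance = 0.05`),
  since terminal extensions and annotation wobble are common.
* **Truncation**: a terminal deletion covering at least
  `truncation_fraction` (default T = 0.05) of the reference codons; a
  missing start region is a truncation at codon 1.

The preserved fraction `(first lesion codon − 1) / codons` drives the
status-matrix shading: `pseudo_severe` below 0.25, `pseudo_moderate` up
to 0.75, `pseudo_mild` above. These thresholds are declared package
defaults: published heatmaps of this kind shade by preserved length
without stating cut-offs, so the boundaries here are design choices,
not inferred values.

### Rates and likelihoods

Branch lengths come from coordinate-wise Brent optimization of the JC69
likelihood on the masked concatenate (passes repeat until the
log-likelihood improves by less than 1e-4); the topology is never
re-estimated. The per-gene rate is the scalar `c_g` maximizing the JC69
likelihood of that gene with all reference branch lengths multiplied by
`c_g` (1-D bounded search, tolerance 1e-6, bounds 1e-3 to 100). A gene
identical across taxa drives `c_g` to the lower bound and is flagged
`no_signal`; all-gap genes report `NA`. JC69 is deliberately simple:
the quantity of interest is a *relative* rate, and the scalar is robust
to the substitution model as long as the same model prices every gene.

### Selection tests

The counting test ("method A") reconstructs ancestral codons per site
by 61-state Fitch parsimony; ties are resolved toward the state with
minimal nonsynonymous pathway count to the parent, then
lexicographically, which makes the output deterministic. Changes along
branches are split into synonymous and nonsynonymous fractions by
pathway averaging (equal weights over stop-free orderings of the
single-base steps). With `s` synonymous and `n` nonsynonymous counts at
a site and `f = N/(N+S)` the site's nonsynonymous site fraction, the
one-sided tail `P(X ≥ n)` for `X ~ Binomial(s+n, f)` is computed via
the regularized incomplete beta function, which extends the binomial
tail continuously to the fractional counts pathway averaging produces.
A site is flagged at `p ≤ 0.05` with at least one substitution.

This null is conservative whenever transitions are more frequent than
transversions: κ > 1 raises the synonymous share of neutral changes
above what the site fractions imply, so the realized false-positive
rate sits well below the nominal threshold — and the test's power
against moderate positive selection is correspondingly modest. The
package treats method A as a specific, cheap screen whose flags are
meaningful mainly through the consensus rule below.

The empirical-Bayes grid ("method B") computes each site's likelihood
under an MG94-style codon model on a 20 × 20 grid of synonymous (α) and
nonsynonymous (β) rates over [0, 5], with branch lengths fixed from the
rate stage and a gene-level κ estimated as twice the
transition/transversion ratio of reconstructed changes. Grid weights
are fitted by EM on the summed log marginal likelihood (the objective
is checked to be non-decreasing every iteration); the reported
`posterior_prob_pos` is the posterior mass where β > α, flagged at 0.9.

A site is **consensus**-selected only when both methods flag it. The
intersection inherits the lower false-positive rate of either method,
mirroring the practice of trusting only sites confirmed by several
detection methods. The per-branch screen aggregates the reconstructed
counts per branch and reports branches with Kn/Ks > 1 carrying at least
3 substitutions; it is explicitly a descriptive screen, not a
likelihood-ratio test.

### Kn/Ks conventions

`gene_kn_ks()` averages Nei–Gojobori pairwise estimates over all
unordered pairs. Per pair, proportions are corrected with the
Jukes–Cantor formula; pairs beyond its validity range (p ≥ 3/4) are
dropped. The gene ratio is the ratio of the pair-averaged Kn to the
pair-averaged Ks — a ratio of means, chosen over a mean of ratios
because per-pair ratios are unstable when Ks is small and their mean is
upward-biased. Pairs with Ks = 0 are counted and reported
(`n_pairs_ks0`).

### Enrichment

Consensus and non-consensus site totals are accumulated per ontology
(seven functional groups: ATP synthesis, cytochrome/electron transport,
*ndh*, photosynthesis, translation, transcription, other). "Fisher's
exact test for multiple samples" is ambiguous between an r×2 exact test
and pairwise 2×2 tests; the package declares the pairwise-with-Holm
contract: all pairwise two-sided 2×2 Fisher tests with Holm step-down
adjustment over that family, plus each-vs-rest tests adjusted within
their own family.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes: a few dozen protein-coding genes across a few dozen taxa
evolved on one tree under an MG94-style codon model over the 61 sense
codons of translation table 11. Defaults encode the study conditions:
20 taxa, 40 genes of 80–300 codons, a Yule tree rescaled to total
length 2 substitutions per nucleotide site, κ = 2, uniform codon
frequencies, per-gene rate multipliers log-uniform on [0.25, 4], and
ω classes (0.1, 1, 5) in proportions (0.70, 0.25, 0.05) — purifying
selection dominating with a small positively selected minority, as in
real plastomes. Branch lengths are multiplied by 3 to convert
nucleotide-site units to codon units. Stop codons are excluded from
the state space, so intact simulated genes always translate cleanly;
stops enter only via lesion injection (premature stop substitution,
1–2 bp frameshift deletion, terminal truncation, whole-gene deletion),
recorded in `truth.json`.

Per-gene random streams are keyed by (seed, gene index), so adding
genes to a config never perturbs earlier genes; for the same reason the
default rate multipliers are drawn per gene without post-hoc
normalization to an exact mean of 1 (they are mean-1 in expectation on
the log scale, and all reported rates are normalized across genes
anyway).

What the generator does **not** emulate: indel evolution along the tree
(alignment difficulty), rate heterogeneity beyond the ω classes and
gene multipliers, codon usage bias, recombination, and annotation
error. Passing tests on synthetic data therefore demonstrate the
correctness of the implemented statistics under their own model — they
do not certify robustness to misalignment or biased codon usage in real
plastomes.

## Numerical choices

* Alignment scores: match 2, mismatch −3, gap open −5, gap extend −2
  (nucleotide); BLOSUM62 with open 10 / extend 1 at the amino-acid
  level. The multiple alignment is a star alignment anchored on the
  first cleanly translating record: every translatable record is
  aligned to the anchor at amino-acid level and merged in anchor
  coordinates, then back-translated (each residue keeps its own codon);
  untranslatable records are added by nucleotide alignment, which is
  what lets frameshift-revealing non-triplet gaps appear. A star
  alignment was chosen over progressive alignment with a guide tree
  because the generator simulates no indels, downstream rules must be
  robust to modest alignment differences by contract, and the star
  construction is deterministic with no tie-prone tree step.
  Externally aligned FASTA is accepted as drop-in input at every
  downstream stage.
* Fitch parsimony treats `-`/`N` as the universal state set; a column
  with fewer than two resolved leaves contributes zero steps.
* JC69 pruning compresses site patterns and rescales partial
  likelihoods per node to avoid underflow; likelihood is re-rooting
  invariant (checked in tests via the pulley principle).
* The EB grid includes α = β = 0 (an invariant-site point); transition
  matrices are obtained by eigendecomposition of the π-symmetrized
  generator, with rows clipped at 0 and renormalized against rounding.
* GC windows pool counts across all taxa (not a per-taxon mean), with
  `N` excluded from numerator and denominator; windows are fixed in
  alignment coordinates.
* GenBank coordinates are 1-based inclusive on disk and are kept
  1-based inclusive internally (the R `substr` convention); reports are
  1-based. Trans-spliced `rps12` is skipped (multi-locus joins are not
  supported); duplicate (inverted-repeat) features use the first in
  file order with a message; ambiguity codes other than `N` become `N`
  with a warning.

## Problem sizes used in the test-suite

The validation suite runs the analysis at reduced but representative
sizes chosen as a matter of design: 20 taxa and 300 codons for the
selection and Kn/Ks checks (200 replicate simulations per ω class for
the sampling bands), 15 planted-lesion genes of 100–200 codons for the
scanner, and 20 genes of 120 codons on 15 taxa for rate recovery. These
sizes give stable Monte-Carlo estimates for the assertions made while
keeping the suite quick to run.

## Known limitations

* The counting test's binomial null ignores κ, making it conservative;
  its recall against ω = 5 sites at the default divergences is low
  (`scripts/acceptance.R` reports it as `counting_recall_omega5`),
  which is why it is paired with the EB grid through the consensus rule
  rather than used alone.
* Parsimony reconstruction undercounts substitutions at high
  divergence; windowed substitution tracks and branch screens are
  relative descriptions, not absolute rates.
* Alignment-based scanning degrades at extreme divergence: when a
  gene's branch-length scale grows several-fold beyond the defaults,
  the pairwise alignment saturates and can fabricate frameshift calls.
  The scanner is meant for the conserved-gene regime plastomes actually
  occupy.
* The rate scaler is defined operationally against the masked
  concatenate under JC69; it is an analogue of partitioned-ML per-gene
  rates, not a reimplementation of them.
* The GenBank parser covers the LOCUS/FEATURES/ORIGIN subset needed
  for CDS extraction (including `join` and `complement`), not the full
  format specification.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(seed = 1, n_taxa = 10, n_genes = 8,
                  gene_length_codons = c(60, 120),
                  lesion_plan = tibble::tibble(
                    gene = c(1, 2), taxon = c(2, 3),
                    kind = c("premature_stop", "frameshift"),
                    position_fraction = c(0.4, 0.5)))
res <- run_all(run_config(mode = "synthetic", out_dir = "run1",
                          sim = cfg))
res$calls |> dplyr::filter(status != "intact")
plot_status_matrix(res$calls)
tidy(res$rate_fit)
```
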