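---
title: "Methods: the CRISPRable landscape and its heritability enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CRISPRable landscape and its heritability enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprable)
```

## The question and the pipeline

A Cas enzyme can only cleave where its protospacer-adjacent motif (PAM)
occurs, so each enzyme sees its own "editable" subset of the genome. This
package quantifies that subset and its genetic payload in four stages:

1. **Segment** the genome: chromosomes are concatenated end to end and cut
   into a fixed number of equal half-open segments.
2. **Count** PAM occurrences per segment on both strands and rank segments;
   the top decile forms the enzyme's *Cas-enriched regions*.
3. **Annotate** SNPs: a binary annotation marks SNPs inside those regions.
4. **Partition heritability**: stratified LD score regression estimates how
   much of a trait's SNP heritability the annotation carries, and the
   enrichment (heritability share over SNP share) is tested against 1.

Overlap statistics (Fisher exact odds ratios against functional
annotations, correlations of PAM density with GC content, off-target-site
matching) characterise *why* an annotation is or is not enriched.

## PAM patterns and GC content

PAMs are IUPAC-degenerate strings. Two conventions matter and are worth
stating precisely:

- **Reverse-strand counting.** A PAM site on the reverse strand reads as
  the reverse-complement motif on the forward strand, so counting `NGG` on
  both strands means scanning the forward sequence for `NGG` and `CCN`.
  Forward and reverse hits at the same offset are *distinct* targetable
  sites and both count; windows containing `N` never match.
- **GC content.** The GC content of a PAM is the fraction of G/C among its
  non-N positions. We exclude *every* N position (including internal ones,
  as in `NGGNG`), because that is the only rule well defined for all
  registry patterns, and we weight other degenerate codes by the G/C
  fraction of their allowed bases (`V` → 2/3, `S` → 1, `W` → 0). This
  equals the expected GC of a uniformly drawn concrete expansion and
  reproduces the conventional reference values (`NGG` 100%, `NGAG` 67%).
  Whether fractional weighting is the "right" convention for codes like
  `V` is genuinely open; the alternative (counting `V` as 1) would only
  affect Cas12a-family patterns, and the oracle-equivalence test pins the
  convention explicitly.

The shipped registry is a curation of 21 enzymes (16 Cas9, 5 Cas12a) from
the primary engineering literature. The xCas9 entry encodes a documented
subtlety: its `GAA`/`GAT` sites are a subset of its `NG` sites, so only
`NG` is used as its ranking PAM — otherwise the same window would be
counted twice before deduplication. In general a Cas's segment count is
the *union* of its ranking PAMs' match positions (same window, same strand
counted once).

## Segmentation conventions

- Segment length is `ceiling(total_length / n_segments)`; the last segment
  absorbs the remainder. For the GRCh37 autosomes (2,881,033,286 bp,
  20,000 segments) this yields 144,052 bp.
- Coordinates are 0-based half-open internally (BED-compatible); 1-based
  positions appear only at VCF/BIM-facing IO. A SNP exactly at a segment's
  end coordinate belongs to the next segment.
- Soft-masked lowercase bases are counted as their base, not as N: repeats
  carry real PAM sites, and no masking rule is part of the method.
- Segments that are entirely N (assembly gaps) are flagged and excluded
  from GC, ranking and downstream analysis; partially-N segments have GC
  (and optionally PAM counts) adjusted to their non-N length.
- Segments may span chromosome junctions (the concatenation has no
  junction rule); `segments_to_bed()` splits such segments when projecting
  back to chromosomes. PAM windows are counted only when fully inside a
  segment — a boundary loses at most `length(pam) - 1` sites, invisible at
  144-kb scale but stated here because it is a convention, not a theorem.
- Ties at the top-k boundary are broken by ascending segment index, making
  region sets deterministic.

## The stratified regression model

For SNP j with GWAS sample size N, the working model is

$$E[\chi^2_j] \;=\; 1 \;+\; N \sum_c \tau_c\, \ell(j,c),
\qquad
\ell(j,c) \;=\; \sum_{k \in c,\; |cM_j - cM_k| \le w} r^2_{adj}(j,k),$$

with a window of w = 1 cM (the convention for this class of estimator) and
the small-sample adjusted correlation
\(r^2_{adj} = r^2 - (1 - r^2)/(n - 2)\), which is unbiased under
independence so that unlinked SNPs contribute nothing in expectation. The
intercept is estimated, not fixed, absorbing confounding inflation.

Estimation is weighted least squares. The default weights are the
heteroskedasticity proxy \(1 / (2\,(1 + N \bar h^2 \ell_{base,j}/M)^2)\)
with \(\bar h^2\) taken from a preliminary unweighted fit and clipped to
[0.001, 1]; `weights = "none"` gives OLS. We deliberately do not iterate
the weights — at desk scale the one-step scheme is indistinguishable in
the recovery tests and easier to reason about.

Per-annotation heritability is \(h^2_c = \sum_j a_{jc} \sum_{c'}
\tau_{c'} a_{jc'}\); enrichment is \((h^2_c / h^2) / (M_c / M)\). Negative
\(\tau\) (hence negative \(h^2_c\)) is reported as-is rather than
truncated, so that jackknife distributions stay symmetric. Standard errors
come from a delete-one-block jackknife over 200 contiguous SNP blocks
(configurable); the delete-block fits are computed by downdating the
normal equations, which the test suite checks against brute-force refits.
Wald tests compare \(\tau\) to 0 and enrichment to 1 against a normal
reference; Benjamini–Hochberg flags are computed over whatever set of
p-values the caller pools (the default in `sldsc()` is per call; pooling
the annotation-by-trait grid globally is the caller's one-liner).

Known limitation: this is a desk-scale reimplementation for method study
and simulation, not a drop-in replacement for the released LDSC tool at
biobank scale — continuous annotations, allele harmonisation, and the full
97-annotation baseline model are out of scope. The IO layer writes
LDSC-dialect annot/ldscore/sumstats files so the released tool can take
over at full scale.

## What the synthetic data emulates — and what it does not

`generate_genome()` draws bases independently with a per-block GC
probability, plants concrete motifs, and overwrites N-runs (N wins over a
planted motif, with a warning). It reproduces the features the landscape
analysis consumes — spatial GC structure, gaps, motif density — but not
repeats, isochore fine structure, or CpG depletion; a passing landscape
test says the *counting machinery* is right, not that real genomes look
like this.

`generate_genotypes()` uses a blockwise latent-Gaussian haplotype model:
within a block, latent values share a factor with loading \(\sqrt\rho\);
alleles threshold the latent at the MAF quantile; genotypes sum two
haplotypes. This gives block-diagonal LD with tunable strength (default
blocks of 50 SNPs, \(\rho = 0.8\), MAF uniform on [0.05, 0.5]) and a
uniform genetic map (1 cM/Mb) — adequate for windowing and regression
tests, but without recombination hotspots, MAF-LD coupling, or
demography. `msprime`-style coalescent realism is deliberately not
attempted.

`simulate_sumstats()` has two modes. *Model-level* draws
\(Z_j \sim \mathcal N(0, \sqrt{1 + N\sum_c \tau_c \ell(j,c)})\) from
precomputed LD scores — seconds per replicate, used for replicate studies.
*Genotype-level* draws per-SNP effects, builds a phenotype, and computes
marginal-regression Z scores at the panel's own sample size — the full
causal chain, used to validate the model-level shortcut. A target
enrichment E for an annotation with SNP share p converts exactly to
per-SNP variances via \(\tau_{base} = h^2(1-pE)/(M(1-p))\),
\(\tau_{annot} = h^2(E-1)/(M(1-p))\) (feasible when \(pE < 1\)), so the
planted truth is analytic, not itself estimated.

Every generator is a pure function of its specification plus seed;
identical calls produce byte-identical output.

## Study sizes used by the test suite

The recovery study uses a 5-Mb genome (alternating 250-kb GC blocks at
0.35/0.55, one 50-kb gap), 100 segments, the NGG top decile as the Cas
annotation, a panel of 20,000 SNPs at 250-bp spacing with n = 200
individuals, and a GWAS sample size of 20,000. Planted enrichments of 2.0
and 3.5 are each re-estimated over 25 simulated traits and checked to fall
within ±3 jackknife SE; 100 null traits check the FDR flag rate. These
sizes were chosen so the whole chain — including a 1-cM-window LD score
computation over the full panel — exercises realistic SNP density while a
complete run stays in the minutes range on one core. Motif-scan
equivalence against an independent regex oracle uses 1,000 random
sequences up to 10 kb with planted N-runs across all 25 registry patterns.

## Numerical and degenerate-input choices

- Monomorphic SNPs are excluded from LD scores with a warning (their
  correlation is undefined).
- Rank-deficient regression designs fail loudly, naming the collinear
  (e.g. duplicated) annotation columns.
- Min-max normalisation in the GC-vs-PAM quantile comparison rejects
  constant vectors instead of dividing by zero.
- Fisher exact odds ratios are reported as the sample cross-product
  `a*d/(b*c)` (what overlap heatmaps plot), with the conditional MLE
  behind a flag; zero cells yield a flagged 0/Inf with no continuity
  correction. Two-sided p-values sum all tables with probability at most
  that observed.
- Correlation tests use the Fisher Z transform
  \(z = \operatorname{atanh}(r)\sqrt{n-3}\); correlations within 1e-12 of
  ±1 are treated as exactly ±1 and flagged as underflow (p = 0).
- An empty keep-list in SNP filtering warns and returns an empty panel;
  MAF filtering is strictly greater-than (a SNP at exactly the 5% bound is
  removed). The default exclusion interval for the MHC is
  chr6:25–34 Mb (GRCh37 convention), configurable because published
  analyses rarely state their exact coordinates.

## Open choices made here

- Whether boundary-spanning or strand-double-matching windows should count
  is not settled by convention; our choices (exclude; count per strand)
  are isolated behind the documented operations so a user can quantify
  their effect.
- The X chromosome is handled by the same operations with an explicit
  segment count or length — the autosomal ceiling rule is not forced on
  it.
- The registry's PAM set is a curation; the `unique_pams` count depends on
  how expanded-recognition variants are written (e.g. `NRN` + `NYN` vs
  `NNN`), so no specific count is asserted anywhere.
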