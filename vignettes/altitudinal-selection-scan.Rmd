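---
title: "Methods: screening altitudinal allele-frequency clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening altitudinal allele-frequency clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altiscan)
```

## The problem and the model

Highland ecotypes of outcrossing plants can evolve over a few kilometers of
mountainside despite ongoing gene flow. On such microgeographic scales the
signature of divergent selection is not genome-wide structure but a *cline*:
an allele whose frequency shifts monotonically from the lowest to the
highest deme, dragging linked neutral variation with it (hitchhiking). The
scan implemented here looks for exactly that signature in a transect of
four altitude-ordered demes (lowest, lower-middle, higher-middle, highest)
plus one or more low-altitude *reference* demes that are pooled into a
single comparison group.

Three per-SNP indices capture complementary aspects of the signature.

**Unidirectionality.** With focal-allele frequencies
$F_L, F_{M1}, F_{M2}, F_H$ (the focal allele maximizes $|F_L - F_H|$),

$$U = |F_L-F_H| + \frac{|F_L-F_H| - |F_L-F_{M1}| - |F_{M1}-F_{M2}| - |F_{M2}-F_H|}{2}.$$

The bracketed difference is zero exactly when the series is monotone
(the telescoping steps then sum to $|F_L-F_H|$) and negative otherwise, so
$U \le |F_L - F_H| \le 1$ with equality only for a full monotone cline, and
$U = -1$ at the maximal zigzag $(0, 1, 0, 0)$. `u_index()` also offers a
`"halved"` variant that divides the entire expression by two; its range is
$[-1, 0.5]$. The default is the reading whose range is $[-1, 1]$, which is
the scale all screening defaults assume.

**Differentiation.** Hedrick's standardized $G'_{ST}$ between the lowest
and highest demes: $G_{ST} = (H_T - H_S)/H_T$ with $H_S$ the mean expected
heterozygosity of the two demes and $H_T$ from their unweighted mean
frequency vector, standardized by its maximum given $H_S$
($\times (1+H_S)/(1-H_S)$ for $k = 2$). No small-sample (Nei–Chesser type)
correction is applied; with ten chromosomes per deme the observed values
therefore run well above their parametric expectations, uniformly across
loci, which is harmless for a rank-and-threshold screen but means the
absolute values should not be read as unbiased differentiation estimates.

**Derived-allele increment.** The minor allele of the pooled reference
group is taken as putatively derived ($D_R \in [0, 0.5]$ for biallelic
loci); $\Delta D' = |D_H - D_R|\,(1 - D_R)$ rewards alleles that have risen
in the highest deme, damped by the probability $1 - D_R$ that the
reference minor allele is truly derived. For tri- and tetra-allelic loci
the derived-allele frequency is one minus the major-allele frequency,
computed separately in each group; note that this multiallelic rule can
yield $D_R > 0.5$ (e.g. a reference pool at 0.4/0.3/0.3), so the pipeline
applies the formula directly there while the scalar `delta_d_prime()`
enforces the documented biallelic domain.

All three indices are averaged over a 4-kbp window (2 kbp each side,
inclusive, never crossing a scaffold, shrinking at edges) to damp
single-SNP noise, and each windowed index is thresholded at the Tukey upper
fence $Q_3 + 1.5\,\mathrm{IQR}$ of its genome-wide distribution. A SNP is
*screened* when it clears all three fences. The three criteria are
deliberately not independent — a steep monotone cline is usually also
differentiated — and the intersection is what buys specificity.

## Islands, genes, enrichment, overlap

The windowed-U values are connected by straight lines along each scaffold;
maximal sub-curves with $\bar U > 0$ are *genomic islands*, the unit at
which hitchhiking manifests. Boundaries sit at linearly interpolated
x-intercepts; the curve is additionally broken wherever consecutive SNPs
are more than 4 kbp apart, in which case the island ends at the last
observed SNP — no extrapolation into unobserved sequence. Island area (bp
× $\bar U$, by exact trapezoids of the piecewise-linear curve) ranks
islands; only islands holding at least two screened SNPs are ranked, since
a single screened SNP is too little support. Candidate genes are the union
of genes linked (exon overlap or within 5 kbp, inclusive at exactly
5 kbp) to an island's screened SNPs.

GO enrichment runs in two modes over the gene-linked SNPs only: SNP-based
(units are SNPs; a SNP carries a term if any linked gene does) and
gene-based (units are SNP-tagged genes; a gene is screened if any screened
SNP links to it). Each term gets a one-tailed Fisher p (hypergeometric
upper tail) on the disjoint 2×2 table screened/not-screened ×
term/no-term, and Benjamini–Hochberg q-values across the requested terms.
Fold enrichment divides the screened term fraction by the *background*
(all units) fraction, the genome-wide null expectation. BH was chosen over
Storey's $\pi_0$-estimated q-value because the latter is unstable for the
few dozen curated terms this scan typically tests.

Candidate-list overlap between two transects gets an empirical p-value by
literally re-running the sampling experiment: `trials` draws of two
uniform without-replacement gene lists from the SNP-tagged universe,
counting trials with at least the observed overlap. The exact
hypergeometric tail is computed alongside and serves as the test oracle;
the Monte-Carlo path is retained because it generalizes to composite
events (the jointly-tagged-counts test is the product of two tails only
because the draws are independent).

## What the simulator emulates — and what it does not

`simulate_scan_dataset()` generates the statistical structure the screen
assumes, not a demographic history:

* SNP positions with exponential spacing (default mean 484 bp);
* neutral loci as a Balding–Nichols stepping-stone chain: deme 1 drawn
  around an ancestral $p_0 \sim U(0.05, 0.95)$ with divergence `f_model`
  (default 0.05), each next deme around its neighbor with divergence
  `f_model * (1 - rho)` (default `rho` 0.8), reference demes independent
  around $p_0$;
* selected loci as exact monotone clines between configured endpoints
  (default one locus mid-scaffold per scaffold, 0 → 1), with reference
  demes tight around the low endpoint;
* hitchhiking as a frequency pull toward the cline with weight
  $w = e^{-d/\lambda}$ (default $\lambda$ = 2 kbp);
* genotypes as two binomial draws per individual (5 diploids per altitude
  deme, 4 × 4 reference), negative-binomial depths (mean 30, size 10), a
  small multiallelic fraction (1.6% tri-, 1/100 of that tetra-allelic),
  tiled exons (one 2-kbp exon per 5 kbp) and a 30-term GO annotation in
  which the first term preferentially tags genes near selected loci.

Everything is deterministic given `seed`, and a per-locus truth table
(selected flag, hitchhike weight, expected deme frequencies) rides along.

It does **not** simulate recombination, linkage disequilibrium decay from
a coalescent process, mutation-order effects, spatially varying sampling,
genotyping error, or reference-bias in calls. Passing tests on these data
therefore demonstrate that the pipeline recovers planted cline structure
under drift noise of realistic magnitude — not that it is robust to every
artifact of real resequencing data. One deliberate consequence of the
small deme sizes: multilocus $G'_{ST}$ between demes lands around
0.10–0.16 even for modest parametric divergence, the finite-sample
inflation noted above.

## Numerical choices and degenerate inputs

* Fences use type-7 (linear interpolation) quantiles; quartile conventions
  move fences, so the method is fixed and documented. The fence comparison
  is strict (`>`), configurable.
* Ties: the focal allele and the derived (minor) allele both break ties to
  the lowest allele index, with a `1e-9` tolerance so that floating-point
  asymmetry in $|F_L - F_H|$ cannot flip a tie; equal-area islands order
  by (scaffold, start).
* $H_T = 0$ (a monomorphic deme pair) returns $G'_{ST} = 0$.
* A SNP with $\bar U$ exactly 0 terminates an island as a boundary point
  and is not a member ("positive" read strictly). An isolated positive SNP
  cut off by >4-kbp gaps on both sides yields a degenerate zero-area
  island with `start == end`; it can never hold two screened SNPs, so
  ranking is unaffected.
* Windowed means with `half_width = 0` return the input; empty sliding
  windows yield `NA`, not 0.
* The per-locus depth filters run in fixed order (per-individual depth,
  total depth, minor-allele fraction) and record the first failing rule,
  so rejection reasons are deterministic and partition the dropped loci.
* Reference demes pool by chromosome counts, so unequal deme sizes weigh
  proportionally.

## Design choices that were genuinely open

* The sliding cline profile uses *absolute* frequency differences versus
  the lowest deme (configurable in principle): the scan's screening logic
  is orientation-free, and absolute differences keep profiles comparable
  across loci whose focal allele happens to be the complement.
* The enrichment 2×2 uses the disjoint screened/not-screened split (counts
  partition), while fold enrichment is reported against the all-units
  background; with screening fractions of a few percent the two
  backgrounds are numerically indistinguishable, and the pair of
  conventions keeps both the test and the effect size interpretable.
* Overlap p-values use the "at least as extreme" convention
  (P(overlap ≥ observed)); for small expected overlaps P(≥k) and P(=k)
  agree to the printed precision, so the choice is benign.
* `run_scan()` is a plain function composition with provenance-stamped TSV
  outputs rather than a workflow engine; determinism (identical inputs →
  byte-identical outputs) is part of its contract and is tested.

## Problem sizes

The test and validation suite runs at desk scale, chosen so the full suite
completes in minutes: 4 scaffolds × 250 kbp (≈ 2,000 SNPs) for
end-to-end recovery runs (20 seeds with planted selection, plus
selection-free null runs where the screened fraction stays below 5%),
2 × 50 kbp for unit-level fixtures, and $10^6$ Monte-Carlo trials for the
resampling reproductions. Genome-scale inputs (hundreds of thousands of
SNPs) pass through the same vectorized code paths; windowing and
segmentation are linear in the number of SNPs per scaffold.

## Known limitations

* The windowed mean is an unweighted average over a fixed physical
  distance; it does not adapt to local SNP density or recombination rate.
* $G'_{ST}$ and the diversity summaries carry finite-sample bias (no
  Nei–Chesser correction); they are meant for ranking and thresholding
  within one dataset, not for cross-study comparison.
* The derived-allele call trusts the pooled reference minor allele; with
  $D_R$ near 0.5 the "derived" label is close to arbitrary, which is
  precisely why $\Delta D'$ damps such loci by $1 - D_R$.
* Empirical p-values from $10^6$ trials resolve to about $10^{-3}$ with
  relative Monte-Carlo error of a few percent near that scale; the exact
  tail is always reported alongside and should be preferred when the event
  admits one.
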