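---
title: "Methods: family-based compound-heterozygous prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based compound-heterozygous prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chetscreen)
```

## The problem and the model

When two siblings develop the same rare tumor while both parents are
healthy, a recessively acting germline genotype is a natural hypothesis.
Under Knudson's two-hit model, a tumor suppressor must lose both copies;
in a family where neither parent is affected, one plausible configuration
is *compound heterozygosity*: each parent contributes a different damaged
allele of the same gene, and each child inherits both. Neither parent ever
carries two hits, so the parents are unaffected carriers.

With unphased short-read genotypes, trans configuration cannot be read off
a single sample. The family structure substitutes for phasing: an allele
carried by the mother and both affected children but absent from the
father is maternal in origin (and symmetrically for the father). Two
qualifying alleles of the same gene with *opposite* single-parent origins
are therefore guaranteed to be in trans in the children.

`chetscreen` implements this logic as a pair of per-parent filter
cascades followed by a gene-level intersection:

1. **Shared step.** A site survives a parent's branch when that parent and
   every affected child carry the alternate allele (dosage ≥ 1) and the
   other parent does not (dosage 0). "Carrier" is dosage ≥ 1 throughout:
   homozygous-alternate children remain detectable. The other-parent
   condition is what makes origin assignment unambiguous; it can be
   disabled (`require_other_parent_noncarrier = FALSE`) for sensitivity
   analysis.
2. **Allele-frequency step.** A variant is "rare" when every *available*
   frequency source among the configured `af_*` columns is below the
   threshold (default 0.01). Requiring all sources is the strict reading
   of filtering on two reference cohorts simultaneously. A variant absent
   from every source passes — a truly novel allele is by definition rare —
   and the count of such pass-throughs is logged.
3. **Consequence step.** Restrict to a whitelist, by default exonic
   non-synonymous plus the loss-of-function classes retained in this kind
   of screen (stop-gain, frameshift, start-loss).
4. **Driver step.** Restrict to a user-supplied cancer-driver gene list
   (standing in for a driver-gene database screen).

The default `"paper"` analysis mode applies the full cascade to the
maternal branch and only the shared step (no frequency limit, no
whitelist, no driver screen) to the paternal branch. This mirrors the
fallback strategy of the study this design follows: when a fully
symmetric strict screen yields no gene hit in both branches, the second
branch is relaxed so that a common missense allele opposite a rare
loss-of-function allele can still complete the two-hit pair. The fully
strict `"symmetric"` mode is available as an option.

A missing genotype in any member required by a step fails that step under
the default `"conservative"` policy; `"permissive"` treats missing as
compatible. Conservative is the default because a compound-het report
that hinges on an uncalled genotype is not actionable.

### Predictor consensus

Four pathogenicity predictors (SIFT, PolyPhen-2, MutationTaster, M-CAP)
are combined by simple majority over the available (non-missing) calls:
`damaging` on a strict majority, `benign` on a strict minority,
`uncertain` on an exact tie or no information. No published combination
rule exists for the screen this package models, so the most transparent
one was chosen; the verdict is reported as an evidence flag, never used
as a hard filter.

### Protein-domain mapping

Stop-gain candidates are mapped onto a domain table
(`brca2_domains()` by default): a stop at residue *r* fully retains
domains ending before *r* and partially overlaps domains straddling it;
missense candidates are located by simple interval containment
(inclusive boundaries). Of the six BRCA2 domains in the default table,
only the P/CAF-binding interval (residues 290–453) has an exact span that
this package's checks depend on; the other five use canonical literature
coordinates and are documented as such.

## The expression side

The expression comparisons are deliberately simple, dependency-free
stand-ins for the heavier machinery used in production RNA-seq work:

* **Differential expression** (`select_de_genes`): total-count
  normalization to the mean library size, group means compared with a
  pseudocount of 1 (`log2((mean_a + 1) / (mean_b + 1))`), Wilcoxon
  rank-sum p-values, Benjamini–Hochberg FDR. Selection requires
  |fold change| > 2 **and** FDR < 0.05. The negative-binomial model fit
  of dedicated DE packages is intentionally *not* reproduced: the
  contribution being modeled is the thresholded selection and the
  downstream comparisons, and a rank-based test keeps the stage exact,
  deterministic and assumption-light. Absolute power differs from an NB
  fit; threshold semantics do not.
* **Quartile grouping** (`quartile_groups`): high/low groups are the top
  and bottom `floor(q·n)` samples (default q = 0.25) by normalized
  expression of one marker gene, or the intersections of two genes'
  top/bottom sets for the joint rule. `floor` and stable column-order tie
  breaking were chosen for reproducibility; the percentile convention in
  the source design is not specified, and for the cohort size that
  motivated it (n = 498) `floor(0.25·498) = 124` per group either way.
  Empty joint intersections are reported, not fatal — they are a finding.
* **Over-representation** (`hypergeometric_enrichment`): upper-tail
  hypergeometric probability P(X ≥ k) with BH adjustment across the
  tested sets, sorted by adjusted p then set name. The universe defaults
  to all genes in the count matrix (expressed-genes background), which is
  the conservative choice relative to a genome-wide universe.
* **`bh_adjust`** is the package's own step-up implementation (tested
  against the reference implementation), because both the DE and the
  enrichment stage state their thresholds in FDR terms and the procedure
  must be identical and inspectable in both.

## The synthetic world

`simulate_bundle()` writes a complete, reader-compatible input bundle
(PED, multi-sample VCF, annotation TSV, driver list, GMT, count matrix,
group labels, planted-truth TSV) from one seed. Its defaults are a stated
world, fixed once:

* **Allele-frequency spectrum**: 85% of sites rare
  (AF ~ U(0.0005, 0.01)), 15% common (AF ~ U(0.01, 0.5)). The split
  guarantees both the rare branch and the no-limit branch are exercised;
  the real spectrum of a WGS callset is neither uniform nor independent
  across sites, and no claim is made that it is.
* **Genotypes**: parents Hardy–Weinberg (Binomial(2, AF)), children by
  uniform Mendelian transmission of one allele per parent.
* **De novo flips**: 1e-5 per site per child by default. Real germline
  SNV rates (~1e-8/bp) would essentially never fire at desk scale
  (10³–10⁵ sites), which would leave the de novo code path dead; the
  default is small enough not to disturb recovery statistics yet large
  enough to be observable at 10⁵ sites. Set 0 for exact Mendelian checks.
* **Gene model**: contiguous bins of 10 sites per synthetic gene; the
  first bin carries the planted gene symbol. No real gene models are
  needed for the logic under test.
* **Planted causal gene**: one maternal stop-gain allele (true AF 0.005,
  forced < 0.01 in every annotation source) and one common paternal
  missense allele (AF 0.28), both heterozygous in both children, with the
  canonical dosage patterns (0,1,1,1) and (1,0,1,1).
* **Annotations**: consequences multinomial (25% exonic non-synonymous,
  2% stop-gain, 2% frameshift, 1% start-loss, 30% synonymous, 35%
  noncoding, 5% other); observed AF = true AF × U(0.8, 1.25) clipped to
  [0,1], 5% missing per source; predictor damaging probability 0.9 for
  stop-gain/planted sites, 0.2 otherwise, 10% missing — both directions
  of the consensus logic stay testable.
* **Expression**: log-normal baseline means (median 100), common NB
  dispersion 0.1, a 4-fold multiplicative case-group effect on the
  planted pathway's genes, 40 samples split 20/20 by default.

One RNG stream per bundle, seeded once at the top of
`simulate_bundle()` / `simulate_inputs()`; identical config and seed
produce byte-identical files. The lower-level `simulate_*` operations
draw from the session RNG stream, so direct callers seed explicitly.

**What a green test establishes** — that the cascade, intersection,
statistics and report logic are correct on data with the assumed
structure. It does not establish performance on real callsets: the
simulator has no linkage disequilibrium, no sequencing or calling error
model beyond missingness, no indel realignment issues, no sex
chromosomes, no population stratification, and its headline survivor
counts are orders of magnitude below a real 4.4-million-variant callset.

## Numerical and degenerate-input choices

* VCF positions stay 1-based end to end; multiallelic records are
  decomposed per alternate allele, but indel left-alignment is assumed
  done upstream.
* The elder-affected-child genotype in the motivating family came from
  tumor tissue used as a germline proxy; the pipeline treats all samples
  as germline and `run_report()` prints the caveat whenever
  `tumor_proxy_samples` is set.
* Candidate ordering: loss-of-function-bearing genes first, then
  lexicographic by symbol — deterministic reports.
* Empty matrices, empty survivor sets, header-only annotation files and
  empty joint intersections all flow through; empty gene sets, duplicate
  annotation keys, negative counts and frequency values outside [0,1] are
  fatal at parse time.
* Exit codes of the CLI: 0 success, 2 config error, 3 input-format
  error, 4 stage failure.

## Known limitations

* No statistical phasing: a gene whose two hits both come from the same
  parent, or whose origin is ambiguous (both parents carriers), is out of
  reach by design.
* Survivor *counts* of the cascade are structural output only; matching
  any specific study's counts would require its callset and annotation
  database versions.
* The rank-based DE stand-in is less powerful than an NB fit at small n;
  with fewer than ~4 samples per group the Wilcoxon p-values are too
  coarse to clear an FDR threshold at all.
* Cross-sample comparison of raw counts (as opposed to within-cohort
  normalized comparison) is out of scope.
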