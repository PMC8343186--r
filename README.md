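# chetscreen

Family-based prioritization of germline **compound-heterozygous** candidate
genes, plus the quartile-stratified gene-set enrichment used to interpret
them.

## The problem

Two siblings with the same rare tumor and two healthy parents point to a
recessively acting germline genotype. Under Knudson's two-hit model a tumor
suppressor needs both copies knocked out; with healthy parents, a natural
configuration is compound heterozygosity — each parent contributes a
different damaged allele of the same gene and each affected child inherits
both. Unphased genotypes cannot show trans configuration directly, but the
pedigree can: an allele carried by one parent and all affected children but
absent from the other parent has a unique parental origin, and two such
alleles of one gene with *opposite* origins are necessarily in trans.

`chetscreen` is for analysts who have a multi-sample VCF for a quad family
(father, mother, ≥ 2 affected children), a per-variant annotation table
(gene, consequence, population allele frequencies, pathogenicity predictor
calls), and a cancer-driver gene list. It implements:

* **Segregation**: per-parent filter cascades — shared-with-children /
  other-parent-non-carrier, MAF < 0.01 across all available frequency
  sources, consequence whitelist, driver-gene screen — and the two-hit
  gene intersection `detect_compound_het()`, with majority-vote predictor
  consensus and protein-domain mapping of truncating alleles
  (`truncation_retained_domains()`, `locate_in_domain()`).
* **Enrichment**: threshold DE selection (|fold change| > 2 and
  FDR < 0.05 over a rank-sum test on library-size-normalized counts),
  single- and joint-gene top/bottom-quartile sample grouping, and
  upper-tail hypergeometric over-representation with Benjamini–Hochberg
  adjustment (`bh_adjust()` is the package's own step-up implementation).
* **Synthetic data**: `simulate_bundle()` writes a complete seeded input
  bundle (PED, VCF, annotation TSV, driver list, GMT, counts) with
  Hardy–Weinberg parents, Mendelian children and a planted causal gene —
  one rare maternal stop-gain plus one common paternal missense — so the
  whole pipeline is testable offline.

The core statistic of the enrichment stage is the hypergeometric upper
tail: for a query of n genes from a universe of N containing a set of K,
the enrichment p-value is P(X ≥ k) with X ~ Hypergeom(N, K, n), adjusted
across sets by BH.

## Worked example

```r
library(chetscreen)

cfg <- simulation_config(n_sites = 500, seed = 7)
simulate_bundle(cfg, "bundle7")
res <- run_report(run_config("bundle7", out_dir = "bundle7/results",
                             tumor_proxy_samples = "C1"))
cat(res$report, sep = "\n")
```

prints (abridged header):

```
maternal branch survivors: shared=9, maf=1, consequence=1, driver=1
paternal branch survivors: shared=6, maf=6, consequence=6, driver=6

candidate compound-heterozygous genes: 1
  BRCA2 (maternal: chr1:1000:T:G | paternal: chr1:2000:G:T) [LoF] [consensus-damaging] [driver]
    stop-gain at residue 871: retained domains = PALB2 binding, P/CAF binding
    missense at residue 372: domain = P/CAF binding

differential expression: 30 / 1000 genes selected
enriched sets (adjusted p < 0.05): DNA_REPAIR
```

Reading it: of 500 simulated sites, 9 were shared by mother and both
children with the father non-carrier; one survived the MAF + consequence +
driver cascade. The paternal branch (no MAF limit in `"paper"` mode) kept
6 shared sites. Exactly one gene — the planted one — has alleles from both
branches. Its stop-gain truncates the protein at residue 871, retaining
only the two N-terminal domains of the default BRCA2 domain table, and its
missense partner lies in the P/CAF-binding interval (residues 290–453).
On the expression side the planted pathway is the only set enriched among
the selected DE genes. The caveat line (not shown) records that sample C1's
"germline" DNA is a tumor-tissue proxy.

A command-line front end wraps the same stages:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "chetscreen.R", package = "chetscreen"))') \
    simulate --out bundle --seed 7
... report --bundle bundle --out bundle/results
```

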