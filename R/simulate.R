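#' Simulation configuration
#'
#' Collects every tunable of the synthetic-bundle generator with defaults
#' that exercise both branches of the filter cascade: a two-component
#' allele-frequency spectrum (85% rare, AF ~ U(0.0005, 0.01); 15% common,
#' AF ~ U(0.01, 0.5)), contiguous site-to-gene bins, a planted causal gene
#' carrying one rare maternal stop-gain allele and one common (AF 0.28)
#' paternal missense allele, and negative-binomial expression counts with a
#' multiplicative group effect planted into named pathways.
#'
#' @param n_sites Number of autosomal biallelic sites to simulate.
#' @param sites_per_gene Contiguous sites binned per synthetic gene.
#' @param rare_fraction Fraction of sites drawn from the rare AF component.
#' @param rare_range,common_range AF ranges (uniform) of the two components.
#' @param consequence_proportions Named probabilities over the consequence
#'   vocabulary; must sum to 1.
#' @param de_novo_rate Per-site, per-child probability of a transmission
#'   flip.
#' @param planted_gene Symbol of the planted compound-het gene.
#' @param planted_maternal_af True population AF of the planted maternal
#'   stop-gain allele (must be < 0.01).
#' @param planted_paternal_af True population AF of the planted paternal
#'   missense allele (unrestricted; default 0.28).
#' @param n_driver_genes Number of genes (including the planted one) put on
#'   the synthetic cancer-driver list.
#' @param n_expression_genes,n_expression_samples Dimensions of the
#'   simulated count matrix (samples split evenly into case/control).
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion);
#'   must be > 0.
#' @param planted_pathways Names of gene sets receiving the expression
#'   effect in the case group.
#' @param planted_effect Multiplicative case-group mean shift for genes in
#'   the planted pathways.
#' @param damaging_prob_lof,damaging_prob_other Per-predictor damaging-call
#'   probability for stop-gain/planted vs other sites.
#' @param seed Integer seed; required — every generator draw flows from one
#'   RNG stream seeded here.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 2000L,
                              sites_per_gene = 10L,
                              rare_fraction = 0.85,
                              rare_range = c(0.0005, 0.01),
                              common_range = c(0.01, 0.5),
                              consequence_proportions = c(
                                exonic_nonsynonymous = 0.25, stopgain = 0.02,
                                frameshift = 0.02, startloss = 0.01,
                                synonymous = 0.30, noncoding = 0.35,
                                other = 0.05),
                              de_novo_rate = 1e-5,
                              planted_gene = "BRCA2",
                              planted_maternal_af = 0.005,
                              planted_paternal_af = 0.28,
                              n_driver_genes = 5L,
                              n_expression_genes = 1000L,
                              n_expression_samples = 40L,
                              nb_dispersion = 0.1,
                              planted_pathways = "DNA_REPAIR",
                              planted_effect = 4,
                              damaging_prob_lof = 0.9,
                              damaging_prob_other = 0.2,
                              seed = NULL) {
  if (is.null(seed)) stop("seed is required (no silent nondeterminism)")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (de_novo_rate < 0 || de_novo_rate > 1) stop("de_novo_rate must be in [0,1]")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  stopifnot(setequal(names(consequence_proportions), CONSEQUENCE_LEVELS))
  if (abs(sum(consequence_proportions) - 1) > 1e-8)
    stop("consequence_proportions must sum to 1")
  if (planted_maternal_af >= 0.01)
    stop("planted maternal allele must be rare (AF < 0.01)")
  structure(as.list(environment()), class = "simulation_config")
}

#' Quad pedigree used by the simulator
#'
#' Father `F1`, mother `M1`, affected daughter `C1`, affected son `C2`.
#' @param family_id Family identifier.
#' @return A `pedigree`.
#' @export
quad_pedigree <- function(family_id = "FAM1") {
  new_pedigree(data.frame(
    family_id = family_id,
    individual_id = c("F1", "M1", "C1", "C2"),
    father_id = c("0", "0", "F1", "F1"),
    mother_id = c("0", "0", "M1", "M1"),
    sex = c("male", "female", "female", "male"),
    affected = c("unaffected", "unaffected", "affected", "affected"),
    stringsAsFactors = FALSE
  ))
}

#' Simulate quad-family genotypes under Hardy-Weinberg and Mendel
#'
#' Draws a true allele frequency per site from the configured two-component
#' spectrum, parental dosages as Binomial(2, AF) (Hardy-Weinberg), and each
#' child's genotype by sampling one allele uniformly from each parent's
#' two; with probability `de_novo_rate` per site per child one transmitted
#' allele is flipped. Sites are assigned to contiguous gene bins; the first
#' bin carries the planted gene symbol.
#'
#' Uses the session RNG stream: callers seed once per bundle (as
#' [simulate_bundle()] does) so the whole bundle is reproducible.
#'
#' @param config A [simulation_config()].
#' @param pedigree A quad `pedigree` (default [quad_pedigree()]).
#' @return List: `matrix` (a `genotype_matrix` whose `sites` carry a `gene`
#'   column) and `af` (data.frame of true per-site allele frequencies).
#' @export
simulate_family_genotypes <- function(config, pedigree = quad_pedigree()) {
  stopifnot(inherits(config, "simulation_config"), inherits(pedigree, "pedigree"))
  n <- as.integer(config$n_sites)
  roles <- pedigree$roles
  if (length(roles$affected_children) < 1L) stop("pedigree must be a quad")

  rare <- runif(n) < config$rare_fraction
  af <- numeric(n)
  af[rare] <- runif(sum(rare), config$rare_range[1L], config$rare_range[2L])
  af[!rare] <- runif(sum(!rare), config$common_range[1L], config$common_range[2L])

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  gene_bin <- ceiling(seq_len(n) / config$sites_per_gene)
  gene <- sprintf("G%04d", gene_bin)
  gene[gene_bin == 1L] <- config$planted_gene
  sites <- data.frame(chrom = "chr1", pos = 1000L * seq_len(n), ref = ref,
                      alt = alt, gene = gene, stringsAsFactors = FALSE)

  samples <- pedigree$members$individual_id
  dosage <- matrix(NA_integer_, nrow = n, ncol = length(samples),
                   dimnames = list(NULL, samples))
  dosage[, roles$father] <- rbinom(n, 2L, af)
  dosage[, roles$mother] <- rbinom(n, 2L, af)
  for (child in roles$affected_children) {
    from_f <- rbinom(n, 1L, dosage[, roles$father] / 2)
    from_m <- rbinom(n, 1L, dosage[, roles$mother] / 2)
    kid <- from_f + from_m
    flip <- runif(n) < config$de_novo_rate
    if (any(flip)) {
      delta <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
      kid[flip] <- pmin(2L, pmax(0L, kid[flip] + delta))
    }
    dosage[, child] <- kid
  }
  gm <- new_genotype_matrix(sites, samples, dosage)
  list(matrix = gm,
       af = data.frame(key = gm$sites$key, af = af, stringsAsFactors = FALSE))
}

#' Plant the causal compound-heterozygous genotype pattern
#'
#' Overwrites two sites of the planted gene with the canonical two-hit
#' pattern: at the maternal site the mother is heterozygous, the father
#' homozygous-reference and both affected children heterozygous
#' (dosages father 0, mother 1, children 1); at the paternal site the
#' pattern is mirrored (father 1, mother 0, children 1). The operation is
#' idempotent: re-planting the same truth leaves the matrix unchanged.
#'
#' @param gm A `genotype_matrix` whose `sites` carry a `gene` column.
#' @param config A [simulation_config()].
#' @param pedigree The quad `pedigree` matching `gm`'s samples.
#' @return List: `matrix` (modified genotype matrix) and `truth` (data.frame
#'   with one row per planted allele: `role`, `key`, `gene`, `consequence`,
#'   `af`, `protein_pos`).
#' @export
plant_compound_het <- function(gm, config, pedigree = quad_pedigree()) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(gm$sites$gene))
  idx <- which(gm$sites$gene == config$planted_gene)
  if (length(idx) < 2L)
    stop("planted gene ", config$planted_gene,
         " needs >= 2 sites in the matrix")
  roles <- pedigree$roles
  maternal_site <- idx[1L]
  paternal_site <- idx[2L]
  gm$dosage[maternal_site, roles$father] <- 0L
  gm$dosage[maternal_site, roles$mother] <- 1L
  gm$dosage[maternal_site, roles$affected_children] <- 1L
  gm$dosage[paternal_site, roles$father] <- 1L
  gm$dosage[paternal_site, roles$mother] <- 0L
  gm$dosage[paternal_site, roles$affected_children] <- 1L
  truth <- data.frame(
    role = c("maternal", "paternal"),
    key = gm$sites$key[c(maternal_site, paternal_site)],
    gene = config$planted_gene,
    consequence = c("stopgain", "exonic_nonsynonymous"),
    af = c(config$planted_maternal_af, config$planted_paternal_af),
    protein_pos = c(871L, 372L),
    stringsAsFactors = FALSE
  )
  list(matrix = gm, truth = truth)
}

#' Simulate the annotation sidecar for a genotype matrix
#'
#' Assigns each site its bin gene, a consequence drawn from the configured
#' proportions, two allele-frequency sources (`af_1kg_asian`, `af_exac`)
#' equal to the true AF perturbed by bounded multiplicative noise (with a
#' small missingness rate), and four predictor calls whose damaging
#' probability is elevated for stop-gain and planted sites. Planted sites
#' are forced to their true consequence and exact AF in every source (so
#' the maternal allele is always rare in all sources), with damaging-leaning
#' predictors and their protein residue recorded.
#'
#' @param gm A `genotype_matrix` with a `gene` site column.
#' @param config A [simulation_config()].
#' @param af data.frame of true allele frequencies from
#'   [simulate_family_genotypes()].
#' @param truth Planted-truth data.frame from [plant_compound_het()] (NULL
#'   for an unplanted matrix).
#' @return An `annotation_tbl`.
#' @export
simulate_annotations <- function(gm, config, af, truth = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$sites)
  true_af <- af$af[match(gm$sites$key, af$key)]
  props <- config$consequence_proportions[CONSEQUENCE_LEVELS]
  consequence <- sample(CONSEQUENCE_LEVELS, n, replace = TRUE, prob = props)

  perturb <- function() {
    obs <- pmin(1, pmax(0, true_af * runif(n, 0.8, 1.25)))
    obs[runif(n) < 0.05] <- NA_real_
    obs
  }
  af1 <- perturb(); af2 <- perturb()

  planted_idx <- integer()
  if (!is.null(truth)) {
    planted_idx <- match(truth$key, gm$sites$key)
    consequence[planted_idx] <- truth$consequence
    af1[planted_idx] <- truth$af
    af2[planted_idx] <- truth$af
  }
  p_dmg <- ifelse(consequence == "stopgain", config$damaging_prob_lof,
                  config$damaging_prob_other)
  p_dmg[planted_idx] <- config$damaging_prob_lof
  call_one <- function() {
    call <- ifelse(runif(n) < p_dmg, "damaging", "benign")
    call[runif(n) < 0.1] <- NA_character_
    call
  }
  protein_pos <- rep(NA_integer_, n)
  if (!is.null(truth)) protein_pos[planted_idx] <- truth$protein_pos

  tbl <- data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos, ref = gm$sites$ref,
    alt = gm$sites$alt, gene = gm$sites$gene, consequence = consequence,
    protein_pos = protein_pos,
    af_1kg_asian = af1, af_exac = af2,
    sift = call_one(), polyphen2 = call_one(),
    mutationtaster = call_one(), mcap = call_one(),
    stringsAsFactors = FALSE
  )
  if (length(planted_idx)) {
    # planted predictor calls are never missing, keeping the consensus
    # informative for the causal alleles
    for (col in unname(PREDICTOR_COLUMNS)) {
      miss <- is.na(tbl[[col]][planted_idx])
      tbl[[col]][planted_idx][miss] <- "damaging"
    }
  }
  new_annotation_tbl(tbl)
}

#' Simulate negative-binomial expression counts with planted pathway effects
#'
#' Gene baseline means are log-normal (median 100, log-sd 1); counts are
#' negative-binomial with common dispersion. Samples split evenly into
#' `case` and `control`; genes belonging to any planted pathway get their
#' case-group mean multiplied by `planted_effect`.
#'
#' @param config A [simulation_config()].
#' @param gene_sets A `gene_set_collection`; its member genes are included
#'   in the matrix, padded with background genes `BG0001...` up to
#'   `n_expression_genes`.
#' @return List: `counts` (an `expression_matrix`), `groups` (data.frame
#'   `sample`, `group`), and `planted_genes` (symbols that received the
#'   effect).
#' @export
simulate_expression <- function(config, gene_sets) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(gene_sets, "gene_set_collection"))
  set_genes <- unique(unlist(gene_sets$sets, use.names = FALSE))
  n_bg <- max(0L, config$n_expression_genes - length(set_genes))
  genes <- c(set_genes, sprintf("BG%04d", seq_len(n_bg)))
  n_genes <- length(genes)
  n_samp <- as.integer(config$n_expression_samples)
  if (n_samp < 4L) stop("need at least 2 samples per group")
  n_case <- n_samp %/% 2L
  group <- c(rep("case", n_case), rep("control", n_samp - n_case))
  samples <- sprintf("S%03d", seq_len(n_samp))

  base_mu <- rlnorm(n_genes, meanlog = log(100), sdlog = 1)
  planted_genes <- unique(unlist(gene_sets$sets[
    intersect(config$planted_pathways, names(gene_sets$sets))],
    use.names = FALSE))
  effect <- ifelse(genes %in% planted_genes, config$planted_effect, 1)
  mu <- outer(base_mu, rep(1, n_samp))
  mu[, group == "case"] <- mu[, group == "case"] * effect
  size <- 1 / config$nb_dispersion
  counts <- matrix(rnbinom(n_genes * n_samp, mu = mu, size = size),
                   nrow = n_genes, dimnames = list(genes, samples))
  list(counts = new_expression_matrix(counts),
       groups = data.frame(sample = samples, group = group,
                           stringsAsFactors = FALSE),
       planted_genes = planted_genes)
}

#' Default synthetic gene-set collection
#'
#' One planted pathway (named after `config$planted_pathways[1]`) of
#' `set_size` genes plus `n_null_sets` null sets, mutually disjoint.
#'
#' @param config A [simulation_config()].
#' @param set_size Genes per set.
#' @param n_null_sets Number of unaffected sets.
#' @return A `gene_set_collection`.
#' @export
default_gene_sets <- function(config, set_size = 30L, n_null_sets = 9L) {
  n_total <- set_size * (n_null_sets + 1L)
  genes <- sprintf("PWY%04d", seq_len(n_total))
  sets <- split(genes, rep(seq_len(n_null_sets + 1L), each = set_size))
  names(sets) <- c(config$planted_pathways[1L],
                   sprintf("NULL_SET_%02d", seq_len(n_null_sets)))
  structure(list(sets = sets, universe = NULL), class = "gene_set_collection")
}

#' Generate and write a complete synthetic fixture bundle
#'
#' Seeds the RNG once from `config$seed`, then simulates pedigree,
#' genotypes (with the planted compound-het gene), annotations, a driver
#' list containing the planted gene, a gene-set collection, and expression
#' counts, and writes everything to `dir`: `family.ped`, `variants.vcf`,
#' `annotations.tsv`, `drivers.txt`, `sets.gmt`, `counts.tsv`,
#' `groups.tsv`, `truth.tsv`. Identical config (including seed) yields a
#' byte-identical bundle.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory objects and the file paths.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_inputs(config)
  paths <- list(
    ped = file.path(dir, "family.ped"),
    vcf = file.path(dir, "variants.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    drivers = file.path(dir, "drivers.txt"),
    gmt = file.path(dir, "sets.gmt"),
    counts = file.path(dir, "counts.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_pedigree(sim$pedigree, paths$ped)
  write_variants(sim$matrix, paths$vcf)
  write_annotations(sim$annotations, paths$annotations)
  write_gene_list(sim$drivers, paths$drivers)
  write_gene_sets(sim$gene_sets, paths$gmt)
  write_counts(sim$expression$counts, paths$counts)
  utils::write.table(sim$expression$groups, paths$groups, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sim$paths <- paths
  invisible(sim)
}

#' Simulate a full input bundle in memory
#'
#' The generation core of [simulate_bundle()] without file output: seeds the
#' RNG once from `config$seed` and produces pedigree, planted genotype
#' matrix, annotations, driver list, gene sets and expression counts.
#'
#' @param config A [simulation_config()].
#' @param expression Logical; set FALSE to skip the (comparatively costly)
#'   count-matrix stage when only the variant side is needed.
#' @return List with elements `config`, `pedigree`, `matrix`, `truth`,
#'   `annotations`, `drivers`, `gene_sets`, `expression`.
#' @export
simulate_inputs <- function(config, expression = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pedigree <- quad_pedigree()
  sim <- simulate_family_genotypes(config, pedigree)
  planted <- plant_compound_het(sim$matrix, config, pedigree)
  annotations <- simulate_annotations(planted$matrix, config, sim$af,
                                      planted$truth)
  other_genes <- setdiff(unique(planted$matrix$sites$gene), config$planted_gene)
  drivers <- c(config$planted_gene,
               sample(other_genes, min(config$n_driver_genes - 1L,
                                       length(other_genes))))
  gene_sets <- default_gene_sets(config)
  expr <- if (expression) simulate_expression(config, gene_sets) else NULL
  list(config = config, pedigree = pedigree, matrix = planted$matrix,
       truth = planted$truth, annotations = annotations, drivers = drivers,
       gene_sets = gene_sets, expression = expr)
}

#' Count Mendelian-inheritance violations in a genotype matrix
#'
#' A child genotype violates Mendelian transmission when its alternate
#' dosage falls outside the range implied by the parents: minimum = number
#' of homozygous-alternate parents, maximum = number of carrier parents.
#' Missing dosages are not counted.
#'
#' @param gm A `genotype_matrix`.
#' @param pedigree The matching `pedigree`.
#' @return Integer count over all (site, affected child) pairs.
#' @export
count_mendelian_violations <- function(gm, pedigree) {
  roles <- pedigree$roles
  f <- gm$dosage[, roles$father]
  m <- gm$dosage[, roles$mother]
  lo <- (f == 2L) + (m == 2L)
  hi <- (f >= 1L) + (m >= 1L)
  total <- 0L
  for (child in roles$affected_children) {
    k <- gm$dosage[, child]
    bad <- !is.na(k) & !is.na(lo) & (k < lo | k > hi)
    total <- total + sum(bad)
  }
  total
}
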