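#' Run configuration for the end-to-end pipeline
#'
#' Defaults are the study-style thresholds: MAF < 0.01 on the rare branch,
#' fold change > 2 and FDR < 0.05 for differential expression, adjusted
#' p < 0.05 for enrichment, quartile fraction 0.25. Every parameter is
#' echoed verbatim into the run log and report header.
#'
#' @param bundle_dir Directory containing the input bundle
#'   (`family.ped`, `variants.vcf`, `annotations.tsv`, `drivers.txt`, and
#'   optionally `sets.gmt`, `counts.tsv`, `groups.tsv`).
#' @param out_dir Output directory for the report and TSVs.
#' @param maf_threshold Rare-branch MAF cutoff.
#' @param mode `"paper"` (maternal branch strict: MAF + consequence +
#'   driver screen; paternal branch unrestricted) or `"symmetric"` (both
#'   branches strict).
#' @param fc_threshold,fdr_threshold DE selection thresholds.
#' @param adjusted_p_cutoff Enrichment significance cutoff.
#' @param quartile Quartile fraction for expression grouping.
#' @param seed Integer seed echoed into the report (the analysis itself is
#'   deterministic; the seed matters when the bundle is simulated).
#' @param tumor_proxy_samples Sample ids whose "germline" DNA is actually a
#'   tumor-tissue proxy; when non-empty a caveat is printed in the report.
#' @return List of class `run_config`.
#' @export
run_config <- function(bundle_dir, out_dir = file.path(bundle_dir, "results"),
                       maf_threshold = 0.01, mode = c("paper", "symmetric"),
                       fc_threshold = 2, fdr_threshold = 0.05,
                       adjusted_p_cutoff = 0.05, quartile = 0.25,
                       seed = 1L, tumor_proxy_samples = character()) {
  mode <- match.arg(mode)
  stopifnot(maf_threshold > 0, maf_threshold <= 1, fc_threshold > 0,
            fdr_threshold > 0, fdr_threshold <= 1, quartile > 0, quartile < 1)
  structure(list(bundle_dir = bundle_dir, out_dir = out_dir,
                 maf_threshold = maf_threshold, mode = mode,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 adjusted_p_cutoff = adjusted_p_cutoff, quartile = quartile,
                 seed = as.integer(seed),
                 tumor_proxy_samples = tumor_proxy_samples),
            class = "run_config")
}

#' Run both parental branches and intersect into candidate genes
#'
#' `"paper"` mode applies the strict cascade (MAF threshold, consequence
#' whitelist, driver screen) to the maternal branch and leaves the paternal
#' branch unrestricted beyond the shared step (no MAF limit) before
#' gene-level intersection — the fallback used when a fully symmetric
#' strict strategy yields no shared gene. `"symmetric"` applies the strict
#' cascade to both branches.
#'
#' @param gm A `genotype_matrix`.
#' @param annotations An `annotation_tbl`.
#' @param pedigree A `pedigree`.
#' @param driver_genes Character vector of driver symbols.
#' @param maf_threshold Rare-branch MAF cutoff.
#' @param mode `"paper"` or `"symmetric"`.
#' @return List: `maternal`, `paternal` (`branch_result`s) and `candidates`
#'   (a `candidate_genes` data.frame).
#' @export
prioritize_compound_het <- function(gm, annotations, pedigree, driver_genes,
                                    maf_threshold = 0.01,
                                    mode = c("paper", "symmetric")) {
  mode <- match.arg(mode)
  strict <- function(parent) branch_criteria(
    parent = parent, maf_threshold = maf_threshold,
    consequence_whitelist = default_consequence_whitelist(),
    driver_screen = TRUE)
  open <- function(parent) branch_criteria(
    parent = parent, maf_threshold = NULL, consequence_whitelist = NULL,
    driver_screen = FALSE)
  maternal <- branch_filter(gm, annotations, pedigree, strict("mother"),
                            driver_genes)
  paternal_criteria <- if (mode == "paper") open("father") else strict("father")
  paternal <- branch_filter(gm, annotations, pedigree, paternal_criteria,
                            driver_genes)
  candidates <- detect_compound_het(maternal, paternal, annotations,
                                    driver_genes)
  list(maternal = maternal, paternal = paternal, candidates = candidates)
}

bundle_paths <- function(dir) {
  list(ped = file.path(dir, "family.ped"),
       vcf = file.path(dir, "variants.vcf"),
       annotations = file.path(dir, "annotations.tsv"),
       drivers = file.path(dir, "drivers.txt"),
       gmt = file.path(dir, "sets.gmt"),
       counts = file.path(dir, "counts.tsv"),
       groups = file.path(dir, "groups.tsv"))
}

#' Run the full pipeline on a bundle and write a human-readable report
#'
#' Reads a bundle directory, runs both segregation branches and the
#' compound-het intersection, maps coding candidate alleles onto the
#' default BRCA2 domain table when a `protein_pos` is annotated, and — when
#' expression inputs (`counts.tsv`, `groups.tsv`, `sets.gmt`) are present —
#' runs DE selection between the labelled groups followed by
#' over-representation of the selected genes. Writes
#' `branch_maternal.tsv`, `branch_paternal.tsv`, `candidates.tsv`,
#' optionally `de_genes.tsv` and `enrichment.tsv`, and `report.txt` into
#' `config$out_dir`. Outputs are byte-identical across re-runs on the same
#' bundle.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 success, 2 config error,
#'   3 input-format error, 4 stage failure), the stage results, and the
#'   report lines. On error the partial list carries `error` instead of
#'   results.
#' @export
run_report <- function(config) {
  if (!inherits(config, "run_config"))
    return(invisible(list(status = 2L, error = "config error: not a run_config")))
  fail <- function(status, stage, e)
    invisible(list(status = status,
                   error = paste0(stage, ": ", conditionMessage(e))))

  paths <- bundle_paths(config$bundle_dir)
  inputs <- tryCatch({
    for (p in c(paths$ped, paths$vcf, paths$annotations, paths$drivers))
      if (!file.exists(p)) stop("required input missing: ", p)
    ped <- read_pedigree(paths$ped)
    list(pedigree = ped,
         gm = read_variants(paths$vcf, ped),
         annotations = read_annotations(paths$annotations),
         drivers = read_gene_list(paths$drivers))
  }, error = function(e) e)
  if (inherits(inputs, "error")) return(fail(3L, "input", inputs))
  if (!length(inputs$drivers))
    return(fail(2L, "config",
                simpleError("driver screen on but driver list is empty")))

  seg <- tryCatch(
    prioritize_compound_het(inputs$gm, inputs$annotations, inputs$pedigree,
                            inputs$drivers, config$maf_threshold, config$mode),
    error = function(e) e)
  if (inherits(seg, "error")) return(fail(4L, "segregation", seg))

  expr_results <- NULL
  if (file.exists(paths$counts) && file.exists(paths$groups) &&
      file.exists(paths$gmt)) {
    expr_results <- tryCatch({
      counts <- read_counts(paths$counts)
      groups <- utils::read.table(paths$groups, header = TRUE,
                                  stringsAsFactors = FALSE)
      sets <- read_gene_sets(paths$gmt)
      de <- select_de_genes(counts,
                            groups$sample[groups$group == "case"],
                            groups$sample[groups$group == "control"],
                            config$fc_threshold, config$fdr_threshold)
      enr <- hypergeometric_enrichment(de$gene[de$selected], sets,
                                       universe = rownames(counts))
      list(de = de, enrichment = enr)
    }, error = function(e) e)
    if (inherits(expr_results, "error"))
      return(fail(4L, "enrichment", expr_results))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  branch_tbl <- function(br) data.frame(
    step = names(br$counts), applied = br$applied,
    survivors = unname(br$counts))
  tsv(branch_tbl(seg$maternal), "branch_maternal.tsv")
  tsv(branch_tbl(seg$paternal), "branch_paternal.tsv")
  tsv(seg$candidates, "candidates.tsv")
  if (!is.null(expr_results)) {
    tsv(expr_results$de, "de_genes.tsv")
    tsv(expr_results$enrichment, "enrichment.tsv")
  }

  lines <- c(
    "compound-heterozygous prioritization report",
    "===========================================",
    "",
    "parameters:",
    sprintf("  bundle_dir        = %s", config$bundle_dir),
    sprintf("  mode              = %s", config$mode),
    sprintf("  maf_threshold     = %g", config$maf_threshold),
    sprintf("  fc_threshold      = %g", config$fc_threshold),
    sprintf("  fdr_threshold     = %g", config$fdr_threshold),
    sprintf("  adjusted_p_cutoff = %g", config$adjusted_p_cutoff),
    sprintf("  quartile          = %g", config$quartile),
    sprintf("  seed              = %d", config$seed),
    ""
  )
  if (length(config$tumor_proxy_samples))
    lines <- c(lines,
               sprintf(paste0("CAVEAT: sample(s) %s use tumor-tissue DNA as a ",
                              "germline proxy; all samples are treated as ",
                              "germline."),
                       paste(config$tumor_proxy_samples, collapse = ", ")),
               "")
  fmt_counts <- function(br) paste(sprintf("%s=%d", names(br$counts),
                                           br$counts), collapse = ", ")
  lines <- c(lines,
             paste0("maternal branch survivors: ", fmt_counts(seg$maternal)),
             paste0("paternal branch survivors: ", fmt_counts(seg$paternal)),
             "",
             sprintf("candidate compound-heterozygous genes: %d",
                     nrow(seg$candidates)))
  ann <- inputs$annotations
  for (i in seq_len(nrow(seg$candidates))) {
    cand <- seg$candidates[i, ]
    lines <- c(lines, sprintf(
      "  %s (maternal: %s | paternal: %s)%s%s%s", cand$gene,
      cand$maternal_keys, cand$paternal_keys,
      if (cand$has_lof) " [LoF]" else "",
      if (cand$consensus_damaging) " [consensus-damaging]" else "",
      if (cand$driver_gene) " [driver]" else ""))
    keys <- unlist(strsplit(c(cand$maternal_keys, cand$paternal_keys), ","))
    rows <- ann[match(keys, ann$key), , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      pp <- if ("protein_pos" %in% names(rows)) rows$protein_pos[j] else NA
      if (is.na(pp)) next
      if (rows$consequence[j] == "stopgain") {
        ret <- truncation_retained_domains(pp)
        lines <- c(lines, sprintf(
          "    stop-gain at residue %d: retained domains = %s%s", pp,
          if (length(ret$retained)) paste(ret$retained, collapse = ", ")
          else "(none)",
          if (length(ret$partial))
            paste0(" | partial: ", paste(ret$partial, collapse = ", "))
          else ""))
      } else {
        dom <- locate_in_domain(pp)
        lines <- c(lines, sprintf(
          "    missense at residue %d: domain = %s", pp,
          if (length(dom)) paste(dom, collapse = ", ") else "(none)"))
      }
    }
  }
  if (!is.null(expr_results)) {
    sig <- expr_results$enrichment[
      expr_results$enrichment$adjusted_p < config$adjusted_p_cutoff, ]
    lines <- c(lines, "",
               sprintf("differential expression: %d / %d genes selected",
                       sum(expr_results$de$selected), nrow(expr_results$de)),
               sprintf("enriched sets (adjusted p < %g): %s",
                       config$adjusted_p_cutoff,
                       if (nrow(sig)) paste(sig$set_name, collapse = ", ")
                       else "(none)"))
  }
  writeLines(lines, file.path(config$out_dir, "report.txt"))
  invisible(list(status = 0L, segregation = seg, expression = expr_results,
                 report = lines, out_dir = config$out_dir))
}
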