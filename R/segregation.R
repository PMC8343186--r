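#' Label the parental origin of a child's allele from unphased dosages
#'
#' With unphased genotypes, the origin of a child's alternate allele at a
#' biallelic site is inferred from which parents carry it: exactly one
#' carrier parent pins the origin; both parents carrying is ambiguous; a
#' carried allele absent from both parents is de novo. "Carrier" means
#' dosage >= 1, so homozygous-alternate children are labelled by the same
#' rule. All arguments are vectorized.
#'
#' @param child,mother,father Allele dosages in `{0, 1, 2, NA}`.
#' @return Character vector of labels: `maternal`, `paternal`,
#'   `biparental_ambiguous`, `de_novo`, `untransmitted` (child dosage 0) or
#'   `unresolvable_missing` (any required dosage NA).
#' @examples
#' label_inheritance(1, 1, 0)  # maternal
#' label_inheritance(1, 0, 0)  # de_novo
#' @export
label_inheritance <- function(child, mother, father) {
  n <- max(length(child), length(mother), length(father))
  child <- rep_len(child, n); mother <- rep_len(mother, n)
  father <- rep_len(father, n)
  out <- rep(NA_character_, n)
  miss <- is.na(child) | is.na(mother) | is.na(father)
  out[miss] <- "unresolvable_missing"
  idx <- !miss
  out[idx & child == 0L] <- "untransmitted"
  carrier_m <- mother >= 1L
  carrier_f <- father >= 1L
  hit <- idx & child >= 1L
  out[hit & carrier_m & !carrier_f] <- "maternal"
  out[hit & !carrier_m & carrier_f] <- "paternal"
  out[hit & carrier_m & carrier_f] <- "biparental_ambiguous"
  out[hit & !carrier_m & !carrier_f] <- "de_novo"
  out
}

#' Branch filter criteria
#'
#' Bundles the parameters of one parental branch of the filter cascade.
#' `maf_threshold = NULL` is the "no MAF limitation" mode; a variant passes
#' the MAF step iff every *available* configured frequency source is below
#' the threshold, and a variant with all sources missing passes (novel
#' alleles are by definition rare) with a log message.
#'
#' @param parent `"mother"` or `"father"`: the branch parent whose allele
#'   must be shared with all affected children.
#' @param maf_threshold Numeric in (0, 1], or NULL to disable the step.
#' @param maf_sources Character vector of `af_*` annotation columns to
#'   consult; NULL = all frequency columns present.
#' @param consequence_whitelist Character vector of admissible consequence
#'   classes, or NULL to disable the step.
#' @param driver_screen Logical; restrict to genes on the supplied driver
#'   list.
#' @param require_other_parent_noncarrier Logical; enforce single-parent
#'   origin inside the shared step (the branch definition used here), off
#'   for sensitivity analysis.
#' @param missing_policy `"conservative"` (a missing dosage in any required
#'   member fails the shared step) or `"permissive"` (missing treated as
#'   compatible).
#' @return An object of class `branch_criteria`.
#' @export
branch_criteria <- function(parent = c("mother", "father"),
                            maf_threshold = 0.01,
                            maf_sources = NULL,
                            consequence_whitelist = NULL,
                            driver_screen = FALSE,
                            require_other_parent_noncarrier = TRUE,
                            missing_policy = c("conservative", "permissive")) {
  parent <- match.arg(parent)
  missing_policy <- match.arg(missing_policy)
  if (!is.null(maf_threshold))
    stopifnot(is.numeric(maf_threshold), maf_threshold > 0, maf_threshold <= 1)
  if (!is.null(consequence_whitelist))
    stopifnot(all(consequence_whitelist %in% CONSEQUENCE_LEVELS))
  structure(list(parent = parent, maf_threshold = maf_threshold,
                 maf_sources = maf_sources,
                 consequence_whitelist = consequence_whitelist,
                 driver_screen = isTRUE(driver_screen),
                 require_other_parent_noncarrier =
                   isTRUE(require_other_parent_noncarrier),
                 missing_policy = missing_policy),
            class = "branch_criteria")
}

#' Paper-default consequence whitelist for the rare branch
#'
#' Exonic non-synonymous variants plus the retained loss-of-function
#' classes (stop-gain, frameshift, start-loss).
#' @return Character vector of consequence classes.
#' @export
default_consequence_whitelist <- function() {
  c("exonic_nonsynonymous", LOF_CONSEQUENCES)
}

#' Run one parental branch of the rare-variant filter cascade
#'
#' The ordered cascade is: (1) *shared* — the branch parent and every
#' affected child carry the alternate allele, and (optionally) the other
#' parent does not; (2) *MAF* — every available configured frequency source
#' below the threshold, if one is set; (3) *consequence* — class in the
#' whitelist, if set; (4) *driver* — gene on the driver list, if enabled.
#' Survivor counts are reported after each step (disabled steps repeat the
#' previous count).
#'
#' @param gm A `genotype_matrix` covering all pedigree members.
#' @param annotations An `annotation_tbl` (keyed join on `chrom:pos:ref:alt`).
#' @param pedigree A `pedigree`.
#' @param criteria A [branch_criteria()] object.
#' @param driver_genes Character vector of driver gene symbols (required,
#'   non-empty, when `criteria$driver_screen` is on).
#' @return List of class `branch_result`: `survivors` (character site keys,
#'   in matrix order), `counts` (named integer vector, one entry per step),
#'   `applied` (logical per step) and the echoed `criteria`.
#' @export
branch_filter <- function(gm, annotations, pedigree, criteria,
                          driver_genes = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(pedigree, "pedigree"),
            inherits(criteria, "branch_criteria"))
  if (criteria$driver_screen && !length(driver_genes))
    stop("driver screen enabled but driver gene list is empty")
  roles <- pedigree$roles
  branch_parent <- if (criteria$parent == "mother") roles$mother else roles$father
  other_parent <- if (criteria$parent == "mother") roles$father else roles$mother
  dp <- gm$dosage[, branch_parent, drop = TRUE]
  do <- gm$dosage[, other_parent, drop = TRUE]
  kid_dose <- gm$dosage[, roles$affected_children, drop = FALSE]

  permissive <- criteria$missing_policy == "permissive"
  ge1 <- function(x) if (permissive) (is.na(x) | x >= 1L) else (!is.na(x) & x >= 1L)
  eq0 <- function(x) if (permissive) (is.na(x) | x == 0L) else (!is.na(x) & x == 0L)

  shared <- ge1(dp)
  if (ncol(kid_dose))
    shared <- shared & apply(ge1(kid_dose), 1L, all)
  if (criteria$require_other_parent_noncarrier)
    shared <- shared & eq0(do)
  keys <- gm$sites$key
  alive <- shared
  counts <- c(shared = sum(alive))
  applied <- c(shared = TRUE)

  ann <- annotations[match(keys, annotations$key), , drop = FALSE]
  af_cols <- attr(annotations, "af_cols")
  if (is.null(af_cols)) af_cols <- grep("^af_", names(annotations), value = TRUE)

  if (!is.null(criteria$maf_threshold)) {
    sources <- if (is.null(criteria$maf_sources)) af_cols else criteria$maf_sources
    missing_src <- setdiff(sources, names(ann))
    if (length(missing_src))
      stop("configured MAF source(s) absent from annotations: ",
           paste(missing_src, collapse = ", "))
    af <- as.matrix(ann[, sources, drop = FALSE])
    under <- af < criteria$maf_threshold
    all_avail_under <- apply(under, 1L, function(x) all(x, na.rm = TRUE))
    none_avail <- apply(af, 1L, function(x) all(is.na(x)))
    n_novel <- sum(alive & none_avail, na.rm = TRUE)
    if (n_novel)
      message(n_novel, " surviving site(s) have no allele frequency in any ",
              "configured source; treated as rare (pass)")
    alive <- alive & (all_avail_under | none_avail)
    applied <- c(applied, maf = TRUE)
  } else {
    applied <- c(applied, maf = FALSE)
  }
  counts <- c(counts, maf = sum(alive))

  if (!is.null(criteria$consequence_whitelist)) {
    alive <- alive & !is.na(ann$consequence) &
      ann$consequence %in% criteria$consequence_whitelist
    applied <- c(applied, consequence = TRUE)
  } else {
    applied <- c(applied, consequence = FALSE)
  }
  counts <- c(counts, consequence = sum(alive))

  if (criteria$driver_screen) {
    alive <- alive & !is.na(ann$gene) & ann$gene %in% driver_genes
    applied <- c(applied, driver = TRUE)
  } else {
    applied <- c(applied, driver = FALSE)
  }
  counts <- c(counts, driver = sum(alive))

  structure(list(survivors = keys[alive], counts = counts, applied = applied,
                 criteria = criteria),
            class = "branch_result")
}

#' Intersect maternal and paternal branch survivors into candidate genes
#'
#' A candidate gene carries at least one surviving allele from each parental
#' branch at distinct sites; because each branch requires single-parent
#' origin, the two alleles are guaranteed to be in trans (the germline
#' two-hit configuration). A site key appearing in both survivor sets cannot
#' be single-parent-origin in both and is excluded from both with a warning.
#'
#' @param maternal_survivors,paternal_survivors Character site-key vectors
#'   (or `branch_result` objects) from opposite-parent branches.
#' @param annotations An `annotation_tbl` mapping site keys to genes,
#'   consequences and predictor calls.
#' @param driver_genes Optional driver list used only to set the
#'   `driver_gene` evidence flag.
#' @return A data.frame of class `candidate_genes`, sorted by
#'   (`has_lof` descending, gene symbol), with per-gene comma-separated
#'   allele keys and evidence flags `has_lof`, `consensus_damaging`,
#'   `driver_gene`.
#' @export
detect_compound_het <- function(maternal_survivors, paternal_survivors,
                                annotations, driver_genes = NULL) {
  if (inherits(maternal_survivors, "branch_result"))
    maternal_survivors <- maternal_survivors$survivors
  if (inherits(paternal_survivors, "branch_result"))
    paternal_survivors <- paternal_survivors$survivors
  overlap <- intersect(maternal_survivors, paternal_survivors)
  if (length(overlap)) {
    warning(length(overlap), " site(s) present in both branches excluded ",
            "(cannot be single-parent-origin in both)")
    maternal_survivors <- setdiff(maternal_survivors, overlap)
    paternal_survivors <- setdiff(paternal_survivors, overlap)
  }
  gene_of <- function(keys) {
    idx <- match(keys, annotations$key)
    if (anyNA(idx))
      stop("survivor site(s) missing from annotations: ",
           paste(keys[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
    annotations$gene[idx]
  }
  mg <- gene_of(maternal_survivors)
  pg <- gene_of(paternal_survivors)
  genes <- sort(intersect(unique(mg), unique(pg)))
  rows <- lapply(genes, function(g) {
    mk <- maternal_survivors[mg == g]
    pk <- paternal_survivors[pg == g]
    allk <- c(mk, pk)
    ann <- annotations[match(allk, annotations$key), , drop = FALSE]
    verdicts <- vapply(seq_len(nrow(ann)), function(i)
      predictor_consensus(ann[i, , drop = FALSE])$verdict, character(1L))
    data.frame(
      gene = g,
      n_maternal = length(mk), n_paternal = length(pk),
      maternal_keys = paste(mk, collapse = ","),
      paternal_keys = paste(pk, collapse = ","),
      has_lof = any(ann$consequence %in% LOF_CONSEQUENCES),
      consensus_damaging = any(verdicts == "damaging"),
      driver_gene = !is.null(driver_genes) && g %in% driver_genes,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), n_maternal = integer(),
               n_paternal = integer(), maternal_keys = character(),
               paternal_keys = character(), has_lof = logical(),
               consensus_damaging = logical(), driver_gene = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$has_lof, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", "data.frame")
  out
}

#' Majority-vote consensus over the four pathogenicity predictors
#'
#' Counts damaging vs benign calls among the available (non-missing)
#' predictors; the verdict is `damaging` when damaging calls are a strict
#' majority of available calls, `benign` when a strict minority, and
#' `uncertain` on an exact tie or when no call is available.
#'
#' @param record One `annotation_tbl` row, or a named character vector /
#'   list of calls for `SIFT`, `PolyPhen2`, `MutationTaster`, `M-CAP` with
#'   values `"damaging"`, `"benign"` or `NA`.
#' @return List of class `consensus_call`: `calls`, `n_damaging`,
#'   `n_available`, `verdict`.
#' @export
predictor_consensus <- function(record) {
  if (is.data.frame(record)) {
    calls <- vapply(PREDICTOR_COLUMNS, function(col)
      as.character(record[[col]][1L]), character(1L))
  } else {
    record <- unlist(record)
    missing <- setdiff(PREDICTOR_NAMES, names(record))
    if (length(missing))
      stop("missing predictor call(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(names(record), PREDICTOR_NAMES)
    if (length(extra))
      stop("exactly the four named predictors accepted; got: ",
           paste(extra, collapse = ", "))
    calls <- as.character(record[PREDICTOR_NAMES])
  }
  names(calls) <- PREDICTOR_NAMES
  bad <- !is.na(calls) & !(calls %in% c("damaging", "benign"))
  if (any(bad)) stop("invalid predictor call: ", calls[bad][1L])
  n_damaging <- sum(calls == "damaging", na.rm = TRUE)
  n_available <- sum(!is.na(calls))
  verdict <- if (n_available == 0L || n_damaging * 2L == n_available)
    "uncertain"
  else if (n_damaging * 2L > n_available) "damaging" else "benign"
  structure(list(calls = calls, n_damaging = n_damaging,
                 n_available = n_available, verdict = verdict),
            class = "consensus_call")
}
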