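#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the BH procedure directly: with order statistics
#' `p_(1) <= ... <= p_(m)`, the adjusted value for rank `i` is
#' `min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (fatal otherwise).
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adjusted <- pmin(1, cummin(p[o] * m / seq(m, 1L)))
  adjusted[order(o)]
}

#' Threshold-based differential-expression selection
#'
#' A deliberately dependency-free stand-in for a negative-binomial DE fit:
#' samples are total-count normalized (scaled to the mean library size),
#' group means are compared as `log2((mean_a + 1) / (mean_b + 1))`
#' (pseudocount 1), per-gene p-values come from the Wilcoxon rank-sum test
#' on normalized values, and the FDR is Benjamini-Hochberg. A gene is
#' selected iff its fold change exceeds `fc_threshold` in either direction
#' (|log2FC| > log2(fc_threshold)) and its FDR is below `fdr_threshold`.
#'
#' @param counts An `expression_matrix` (genes x samples).
#' @param group_a_ids,group_b_ids Sample-id character vectors (>= 2 each,
#'   disjoint).
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return data.frame with columns `gene`, `log2_fc`, `p_value`, `fdr`,
#'   `selected`, in input gene order.
#' @export
select_de_genes <- function(counts, group_a_ids, group_b_ids,
                            fc_threshold = 2, fdr_threshold = 0.05) {
  stopifnot(is.matrix(counts))
  missing <- setdiff(c(group_a_ids, group_b_ids), colnames(counts))
  if (length(missing))
    stop("sample(s) absent from count matrix: ", paste(missing, collapse = ", "))
  if (length(group_a_ids) < 2L || length(group_b_ids) < 2L)
    stop("each group needs >= 2 samples")
  if (length(intersect(group_a_ids, group_b_ids)))
    stop("groups must be disjoint")
  sub <- unclass(counts)[, c(group_a_ids, group_b_ids), drop = FALSE]
  lib <- colSums(sub)
  if (any(lib == 0)) stop("zero-total-count sample: ",
                          colnames(sub)[lib == 0][1L])
  norm <- t(t(sub) / lib) * mean(lib)
  a <- norm[, group_a_ids, drop = FALSE]
  b <- norm[, group_b_ids, drop = FALSE]
  log2_fc <- log2((rowMeans(a) + 1) / (rowMeans(b) + 1))
  p <- vapply(seq_len(nrow(norm)), function(i) {
    suppressWarnings(stats::wilcox.test(a[i, ], b[i, ])$p.value)
  }, numeric(1L))
  p[is.na(p)] <- 1
  fdr <- bh_adjust(p)
  data.frame(gene = rownames(counts), log2_fc = log2_fc, p_value = p,
             fdr = fdr,
             selected = abs(log2_fc) > log2(fc_threshold) & fdr < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quartile-stratified sample grouping on one or two marker genes
#'
#' Single-gene rule: the `floor(q * n)` samples with the highest (resp.
#' lowest) normalized expression of the gene form the high (resp. low)
#' group. Joint rule (two genes): the high group is the intersection of the
#' two genes' top-`q` sample sets, the low group the intersection of their
#' bottom-`q` sets; an empty intersection is reported with a message, not
#' an error. Ties at the quartile boundary are resolved by stable sample
#' order (column order of the matrix).
#'
#' @param counts An `expression_matrix`.
#' @param genes One (single rule) or two (joint rule) gene symbols; absent
#'   genes are fatal.
#' @param rule `"single"` or `"joint"`.
#' @param q Quantile fraction (default 0.25).
#' @param normalize Total-count normalize before ranking (default TRUE).
#' @return List of class `group_assignment` with `high` and `low` (sample-id
#'   vectors), `rule`, `genes`, `k` (per-gene group size).
#' @export
quartile_groups <- function(counts, genes, rule = c("single", "joint"),
                            q = 0.25, normalize = TRUE) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(counts), q > 0, q < 1)
  absent <- setdiff(genes, rownames(counts))
  if (length(absent))
    stop("gene(s) absent from count matrix: ", paste(absent, collapse = ", "))
  if (rule == "single" && length(genes) != 1L)
    stop("single-gene rule takes exactly one gene")
  if (rule == "joint" && length(genes) != 2L)
    stop("joint rule takes exactly two genes")
  mat <- unclass(counts)
  if (normalize) {
    lib <- colSums(mat)
    if (any(lib == 0)) stop("zero-total-count sample")
    mat <- t(t(mat) / lib) * mean(lib)
  }
  n <- ncol(mat)
  k <- floor(q * n)
  if (k < 1L) stop("q * n_samples < 1: no samples selected")
  tops <- lapply(genes, function(g) {
    expr <- mat[g, ]
    list(top = colnames(mat)[order(expr, decreasing = TRUE)][seq_len(k)],
         bottom = colnames(mat)[order(expr)][seq_len(k)])
  })
  if (rule == "single") {
    high <- tops[[1L]]$top
    low <- tops[[1L]]$bottom
  } else {
    high <- intersect(tops[[1L]]$top, tops[[2L]]$top)
    low <- intersect(tops[[1L]]$bottom, tops[[2L]]$bottom)
    if (!length(high)) message("joint rule: empty high-group intersection")
    if (!length(low)) message("joint rule: empty low-group intersection")
  }
  structure(list(high = high, low = low, rule = rule, genes = genes, k = k),
            class = "group_assignment")
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, with universe size `N`, set size in universe `K`, query
#' size `n` and overlap `k`, the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution; adjusted p-values are
#' Benjamini-Hochberg across all tested sets. Query genes outside the
#' universe are dropped with a warning; set membership is intersected with
#' the universe.
#'
#' @param query_genes Character vector of query symbols.
#' @param sets A `gene_set_collection` (or named list of character vectors).
#' @param universe Character vector of background symbols; defaults to the
#'   collection's `universe` (fatal if neither is available or empty).
#' @return data.frame of class `enrichment_result` with columns `set_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `adjusted_p`, `significant`
#'   (adjusted_p < 0.05), sorted by `adjusted_p` then set name.
#' @export
hypergeometric_enrichment <- function(query_genes, sets, universe = NULL) {
  if (inherits(sets, "gene_set_collection")) {
    if (is.null(universe)) universe <- sets$universe
    sets <- sets$sets
  }
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < 0.05
  out <- out[order(out$adjusted_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
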