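#' Read a per-variant annotation table
#'
#' The annotation sidecar is a tab-separated file with one row per
#' (site, alternate allele) and a documented header:
#' `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, at least one
#' allele-frequency column prefixed `af_` (e.g. `af_1kg_asian`, `af_exac`),
#' and the four predictor columns `sift`, `polyphen2`, `mutationtaster`,
#' `mcap` with values `damaging`, `benign` or blank (missing). An optional
#' `protein_pos` column carries the 1-based affected amino-acid residue for
#' coding variants (used for domain mapping in reports).
#'
#' Unknown consequence strings are mapped to `"other"` with a warning; blank
#' allele frequencies become `NA`. The join key to genotype data is
#' `chrom:pos:REF:ALT` with uppercased alleles.
#'
#' @param path Path to the TSV.
#' @return A data.frame of class `annotation_tbl`, one row per allele, with
#'   column `key` prepended. Duplicate keys are fatal (ambiguous annotation).
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  tbl <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = list(character = "chrom"),
                                         na.strings = c("", "NA")))
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("annotation header lacks column(s): ", paste(missing, collapse = ", "))
  af_cols <- grep("^af_", names(tbl), value = TRUE)
  if (!length(af_cols)) stop("annotation header has no af_* frequency column")
  pred_missing <- setdiff(unname(PREDICTOR_COLUMNS), names(tbl))
  if (length(pred_missing))
    stop("annotation header lacks predictor column(s): ",
         paste(pred_missing, collapse = ", "))
  new_annotation_tbl(tbl, af_cols)
}

new_annotation_tbl <- function(tbl, af_cols = grep("^af_", names(tbl),
                                                   value = TRUE)) {
  tbl$ref <- toupper(tbl$ref)
  tbl$alt <- toupper(tbl$alt)
  key <- site_key(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
  if (anyDuplicated(key))
    stop("duplicate annotation for site key ", key[duplicated(key)][1L])
  unknown <- !is.na(tbl$consequence) & !(tbl$consequence %in% CONSEQUENCE_LEVELS)
  if (any(unknown)) {
    warning("mapping ", sum(unknown), " unknown consequence string(s) to 'other'")
    tbl$consequence[unknown] <- "other"
  }
  tbl$consequence[is.na(tbl$consequence)] <- "other"
  for (col in af_cols) {
    tbl[[col]] <- as.numeric(tbl[[col]])
    if (any(tbl[[col]] < 0 | tbl[[col]] > 1, na.rm = TRUE))
      stop("allele frequency outside [0,1] in column ", col)
  }
  for (col in unname(PREDICTOR_COLUMNS)) {
    bad <- !is.na(tbl[[col]]) & !(tbl[[col]] %in% c("damaging", "benign"))
    if (any(bad))
      stop("predictor call must be damaging/benign/blank, got '",
           tbl[[col]][bad][1L], "' in column ", col)
  }
  out <- cbind(data.frame(key = key, stringsAsFactors = FALSE), tbl)
  attr(out, "af_cols") <- af_cols
  class(out) <- c("annotation_tbl", "data.frame")
  out
}

#' Write an annotation table
#'
#' @param annotations An `annotation_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_tbl"))
  out <- annotations[, setdiff(names(annotations), "key"), drop = FALSE]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a plain gene list (one symbol per line)
#'
#' Blank lines and `#` comments are skipped; duplicates are dropped.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname read_gene_list
#' @param genes Character vector of symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols. Empty sets are fatal; duplicate members within a set
#' are collapsed.
#'
#' @param path Path to the GMT file.
#' @return An object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `universe` (NULL unless set later).
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(f) < 3L || !length(members))
      stop("empty gene set '", f[1L], "' in GMT")
    members
  })
  names(sets) <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set name in GMT")
  structure(list(sets = sets, universe = NULL),
            class = "gene_set_collection")
}

#' @rdname read_gene_sets
#' @param collection A `gene_set_collection`.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene-by-sample raw count matrix
#'
#' TSV with gene symbols in the first column (`gene`) and one column per
#' sample. Negative counts and duplicated gene symbols are fatal.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix (genes x samples) of class `expression_matrix`.
#' @export
read_counts <- function(path) {
  stopifnot(file.exists(path))
  tbl <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  genes <- as.character(tbl[[1L]])
  counts <- as.matrix(tbl[, -1L, drop = FALSE])
  rownames(counts) <- genes
  new_expression_matrix(counts)
}

new_expression_matrix <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene symbols")
  if (any(counts < 0, na.rm = TRUE)) stop("negative count")
  class(counts) <- c("expression_matrix", class(counts))
  counts
}

#' @rdname read_counts
#' @param counts An `expression_matrix` (or plain matrix with dimnames).
#' @export
write_counts <- function(counts, path) {
  out <- data.table::data.table(gene = rownames(counts))
  out <- cbind(out, data.table::as.data.table(unclass(counts)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
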