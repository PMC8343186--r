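#' Read a multi-sample VCF into a genotype dosage matrix
#'
#' Loads per-sample GT genotypes for all pedigree members, decomposes
#' multiallelic records into biallelic sites (one row per alternate allele),
#' and encodes each genotype as the count of that alternate allele
#' (0, 1, 2, or NA for missing). Positions are kept 1-based as in the VCF;
#' indel left-alignment is not performed — inputs are assumed normalized.
#'
#' @param path Path to an uncompressed or bgzipped VCF with GT fields.
#' @param pedigree A [read_pedigree()] object; all members must be present in
#'   the VCF sample header (fatal otherwise). Sample columns are returned in
#'   pedigree member order.
#' @return An object of class `genotype_matrix`: list with `sites` (data.frame
#'   `chrom`, `pos`, `ref`, `alt`, `key`, position-sorted within chromosome),
#'   `samples` (character) and `dosage` (integer matrix sites x samples,
#'   NA = missing). Records with malformed GT strings are skipped with a
#'   warning.
#' @export
read_variants <- function(path, pedigree) {
  stopifnot(file.exists(path), inherits(pedigree, "pedigree"))
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  samples <- pedigree$members$individual_id
  have <- colnames(vcf)
  if (!all(samples %in% have))
    stop("pedigree sample(s) absent from VCF header: ",
         paste(setdiff(samples, have), collapse = ", "))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  gt <- gt[, samples, drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- toupper(as.character(rr$REF))
  alt_flat <- toupper(as.character(BiocGenerics::unlist(rr$ALT)))
  alts <- split(alt_flat, rep(seq_along(pos), S4Vectors::elementNROWS(rr$ALT)))

  out_sites <- vector("list", length(pos))
  out_dose <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    toks <- strsplit(gt[i, ], "[/|]")
    ok <- vapply(toks, function(t)
      length(t) > 0L && all(grepl("^([0-9]+|\\.)$", t)), logical(1L))
    if (!all(ok)) {
      warning("skipping record ", chrom[i], ":", pos[i], ": malformed GT '",
              gt[i, !ok][1L], "'")
      next
    }
    n_alt <- length(alts[[i]])
    dose <- matrix(NA_integer_, nrow = n_alt, ncol = length(samples))
    for (a in seq_len(n_alt)) {
      dose[a, ] <- vapply(toks, function(t) {
        if (any(t == ".")) NA_integer_ else sum(t == as.character(a))
      }, integer(1L))
    }
    out_sites[[i]] <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                                 alt = alts[[i]], stringsAsFactors = FALSE)
    out_dose[[i]] <- dose
  }
  sites <- do.call(rbind, out_sites)
  if (is.null(sites))
    return(new_genotype_matrix(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE),
      samples,
      matrix(integer(), nrow = 0L, ncol = length(samples))))
  dosage <- do.call(rbind, out_dose)
  ord <- order(factor(sites$chrom, levels = unique(sites$chrom)),
               sites$pos, sites$ref, sites$alt)
  new_genotype_matrix(sites[ord, , drop = FALSE],
                      samples, dosage[ord, , drop = FALSE])
}

# Constructor/validator; `sites` may carry extra columns (e.g. the
# simulator's gene assignment).
new_genotype_matrix <- function(sites, samples, dosage) {
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(dosage),
            length(samples) == ncol(dosage))
  if (nrow(sites) && any(sites$ref == sites$alt))
    stop("ref allele equals alt allele")
  sites$key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(sites$key))
    stop("duplicate site key after normalization: ",
         sites$key[duplicated(sites$key)][1L])
  rownames(sites) <- NULL
  dosage <- matrix(as.integer(dosage), nrow = nrow(sites),
                   ncol = length(samples),
                   dimnames = list(sites$key, samples))
  if (any(dosage < 0L | dosage > 2L, na.rm = TRUE))
    stop("dosage outside {0,1,2,NA}")
  structure(list(sites = sites, samples = samples, dosage = dosage),
            class = "genotype_matrix")
}

#' Write a genotype matrix as a minimal multi-sample VCF
#'
#' Emits a VCFv4.2 file carrying only GT per sample; [read_variants()] on the
#' result reproduces the matrix (sites are written in matrix order, which is
#' already position-sorted). Dosage 1 is written as the unphased heterozygote
#' `0/1`.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_variants <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(gm$sites), ncol = length(gm$samples))
  known <- !is.na(gm$dosage)
  gt[known] <- gt_code[as.character(gm$dosage[known])]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##contig=<ID=", unique(gm$sites$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(gm$sites) == 0L) body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$sites), "biallelic sites x",
      length(x$samples), "samples\n")
  invisible(x)
}
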