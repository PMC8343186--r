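# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except through the package's own readers.

quad_ped_lines <- c(
  "FAM1\tF1\t0\t0\t1\t1",
  "FAM1\tM1\t0\t0\t2\t1",
  "FAM1\tC1\tF1\tM1\t2\t2",
  "FAM1\tC2\tF1\tM1\t1\t2"
)

quad_ped_file <- function(lines = quad_ped_lines) {
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

quad_ped <- function() read_pedigree(quad_ped_file())

# Minimal VCF writer for hand-built records; `records` are body lines
# (already tab-separated), samples default to the quad.
vcf_file <- function(records, samples = c("F1", "M1", "C1", "C2")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=chr1>",
    "##contig=<ID=chr13>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Annotation row builder with all mandatory columns defaulted.
ann_row <- function(chrom = "chr1", pos = 1L, ref = "A", alt = "C",
                    gene = "G1", consequence = "exonic_nonsynonymous",
                    af_1kg_asian = NA_real_, af_exac = NA_real_,
                    sift = NA_character_, polyphen2 = NA_character_,
                    mutationtaster = NA_character_, mcap = NA_character_,
                    protein_pos = NA_integer_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, protein_pos = protein_pos,
             af_1kg_asian = af_1kg_asian, af_exac = af_exac,
             sift = sift, polyphen2 = polyphen2,
             mutationtaster = mutationtaster, mcap = mcap,
             stringsAsFactors = FALSE)
}

ann_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "")
  path
}

ann_tbl <- function(df) read_annotations(ann_file(df))

# Genotype matrix straight from a dosage matrix (rows = sites).
make_gm <- function(dosage, genes = NULL, samples = c("F1", "M1", "C1", "C2")) {
  n <- nrow(dosage)
  sites <- data.frame(chrom = rep("chr1", n), pos = 100L * seq_len(n),
                      ref = rep("A", n), alt = rep("C", n),
                      stringsAsFactors = FALSE)
  if (!is.null(genes)) sites$gene <- genes
  chetscreen:::new_genotype_matrix(sites, samples, dosage)
}

# Independent brute-force oracle for compound-het detection: enumerate all
# (gene, maternal site, paternal site) triples at distinct sites, after
# excluding sites claimed by both branches.
brute_force_chet <- function(maternal, paternal, gene_of) {
  shared <- intersect(maternal, paternal)
  maternal <- setdiff(maternal, shared)
  paternal <- setdiff(paternal, shared)
  hits <- character()
  for (g in unique(unname(gene_of))) {
    for (sm in maternal) {
      for (sp in paternal) {
        if (sm != sp && gene_of[[sm]] == g && gene_of[[sp]] == g)
          hits <- union(hits, g)
      }
    }
  }
  sort(hits)
}

# Exhaustive hypergeometric upper tail: fraction of all n-subsets of a
# universe of size N whose overlap with a fixed K-set is >= k.
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  in_set <- subsets <= K  # WLOG the K-set is {1..K}
  mean(colSums(in_set) >= k)
}
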