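# Independent scalar oracle for inheritance labels, written straight from
# the rule definition (used to cross-check the vectorized implementation
# over the whole domain).
label_oracle <- function(child, mother, father) {
  if (anyNA(c(child, mother, father))) return("unresolvable_missing")
  if (child == 0) return("untransmitted")
  cm <- mother >= 1; cf <- father >= 1
  if (cm && cf) return("biparental_ambiguous")
  if (cm) return("maternal")
  if (cf) return("paternal")
  "de_novo"
}

test_that("label_inheritance matches the rule oracle over the full domain", {
  vals <- c(0L, 1L, 2L, NA)
  grid <- expand.grid(child = vals, mother = vals, father = vals)
  expected <- mapply(label_oracle, grid$child, grid$mother, grid$father)
  got <- label_inheritance(grid$child, grid$mother, grid$father)
  expect_equal(got, unname(expected))
  # the three spec'd spot cases
  expect_equal(label_inheritance(1, 1, 0), "maternal")
  expect_equal(label_inheritance(1, 0, 0), "de_novo")
  expect_equal(label_inheritance(1, 1, 1), "biparental_ambiguous")
})

# Toy 6-site fixture: two qualifying maternal driver-gene sites, one
# shared-but-common site, one synonymous non-shared site, one father-only
# site, one de novo site.
toy_cascade <- function() {
  dosage <- rbind(
    c(0L, 1L, 1L, 1L),  # s1 shared maternal, rare, nonsyn, driver
    c(0L, 1L, 1L, 1L),  # s2 shared maternal, rare, nonsyn, driver
    c(0L, 1L, 1L, 1L),  # s3 shared maternal but common
    c(0L, 1L, 1L, 0L),  # s4 synonymous, not shared (C2 non-carrier)
    c(1L, 0L, 1L, 1L),  # s5 father-only
    c(0L, 0L, 1L, 0L)   # s6 de novo in C1
  )
  gm <- make_gm(dosage)
  ann <- ann_tbl(rbind(
    ann_row(pos = 100L, gene = "DRV1", af_1kg_asian = 0.001, af_exac = 0.002),
    ann_row(pos = 200L, gene = "DRV1", af_1kg_asian = 0.005),
    ann_row(pos = 300L, gene = "DRV1", af_1kg_asian = 0.2, af_exac = 0.3),
    ann_row(pos = 400L, gene = "G2", consequence = "synonymous",
            af_1kg_asian = 0.001),
    ann_row(pos = 500L, gene = "G2", af_1kg_asian = 0.001),
    ann_row(pos = 600L, gene = "G3", af_1kg_asian = 0.001)
  ))
  list(gm = gm, ann = ann)
}

test_that("branch_filter reproduces the hand-applied cascade", {
  fix <- toy_cascade()
  criteria <- branch_criteria("mother", maf_threshold = 0.01,
                              consequence_whitelist =
                                default_consequence_whitelist(),
                              driver_screen = TRUE)
  res <- branch_filter(fix$gm, fix$ann, quad_ped(), criteria,
                       driver_genes = "DRV1")
  expect_equal(unname(res$counts), c(3L, 2L, 2L, 2L))
  expect_setequal(res$survivors, c("chr1:100:A:C", "chr1:200:A:C"))
})

test_that("disabled filters are identity after the shared step", {
  fix <- toy_cascade()
  res <- branch_filter(fix$gm, fix$ann, quad_ped(),
                       branch_criteria("mother", maf_threshold = NULL))
  expect_equal(unname(res$counts), rep(3L, 4))
  expect_equal(unname(res$applied), c(TRUE, FALSE, FALSE, FALSE))
  expect_setequal(res$survivors,
                  c("chr1:100:A:C", "chr1:200:A:C", "chr1:300:A:C"))
})

test_that("empty matrix yields empty survivors with zero counts", {
  gm <- make_gm(matrix(integer(), nrow = 0, ncol = 4))
  res <- branch_filter(gm, ann_tbl(ann_row()[0, ]), quad_ped(),
                       branch_criteria("mother"))
  expect_equal(res$survivors, character())
  expect_equal(unname(res$counts), rep(0L, 4))
})

test_that("all-missing MAF passes (novel allele) and is logged", {
  gm <- make_gm(rbind(c(0L, 1L, 1L, 1L)))
  ann <- ann_tbl(ann_row(pos = 100L))  # both AF sources blank
  expect_message(
    res <- branch_filter(gm, ann, quad_ped(),
                         branch_criteria("mother", maf_threshold = 0.01)),
    "treated as rare")
  expect_equal(res$survivors, "chr1:100:A:C")
})

test_that("conservative missing policy fails sites permissive keeps", {
  gm <- make_gm(rbind(c(0L, 1L, NA, 1L)))
  ann <- ann_tbl(ann_row(pos = 100L, af_1kg_asian = 0.001))
  ped <- quad_ped()
  strict <- branch_filter(gm, ann, ped,
                          branch_criteria("mother", maf_threshold = NULL))
  loose <- branch_filter(gm, ann, ped,
                         branch_criteria("mother", maf_threshold = NULL,
                                         missing_policy = "permissive"))
  expect_equal(strict$survivors, character())
  expect_equal(loose$survivors, "chr1:100:A:C")
})

test_that("driver screen with empty driver list is fatal", {
  fix <- toy_cascade()
  expect_error(
    branch_filter(fix$gm, fix$ann, quad_ped(),
                  branch_criteria("mother", driver_screen = TRUE)),
    "driver")
})

test_that("tightening thresholds never enlarges the survivor set", {
  for (seed in 1:5) {
    cfg <- simulation_config(n_sites = 400L, seed = seed)
    sim <- suppressMessages(simulate_inputs(cfg, expression = FALSE))
    prev <- NULL
    for (thr in c(0.05, 0.01, 0.001)) {
      res <- suppressMessages(branch_filter(
        sim$matrix, sim$annotations, sim$pedigree,
        branch_criteria("mother", maf_threshold = thr)))
      if (!is.null(prev)) expect_true(all(res$survivors %in% prev))
      prev <- res$survivors
    }
    # shrinking the whitelist is also monotone
    full <- suppressMessages(branch_filter(
      sim$matrix, sim$annotations, sim$pedigree,
      branch_criteria("mother", consequence_whitelist =
                        default_consequence_whitelist())))
    lof <- suppressMessages(branch_filter(
      sim$matrix, sim$annotations, sim$pedigree,
      branch_criteria("mother", consequence_whitelist = "stopgain")))
    expect_true(all(lof$survivors %in% full$survivors))
  }
})

test_that("detect_compound_het handles the contract examples", {
  ann <- ann_tbl(rbind(
    ann_row(pos = 1L, gene = "g1", consequence = "stopgain"),
    ann_row(pos = 2L, gene = "g2"),
    ann_row(pos = 3L, gene = "g1"),
    ann_row(pos = 4L, gene = "g3")
  ))
  k <- ann$key
  out <- detect_compound_het(k[1:2], k[3], ann)
  expect_equal(out$gene, "g1")
  expect_equal(out$maternal_keys, k[1])
  expect_equal(out$paternal_keys, k[3])
  expect_true(out$has_lof)

  # disjoint gene sets -> empty
  expect_equal(nrow(detect_compound_het(k[2], k[4], ann)), 0L)

  # overlapping site excluded from both branches with a warning
  expect_warning(out2 <- detect_compound_het(k[c(1, 3)], k[3], ann),
                 "both branches")
  expect_equal(nrow(out2), 0L)
})

test_that("detect_compound_het equals brute-force enumeration on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n_sites <- sample(10:50, 1)
    n_genes <- sample(2:8, 1)
    genes <- sprintf("g%d", sample.int(n_genes, n_sites, replace = TRUE))
    df <- do.call(rbind, lapply(seq_len(n_sites), function(i)
      ann_row(pos = i, gene = genes[i])))
    ann <- ann_tbl(df)
    gene_of <- setNames(as.list(ann$gene), ann$key)
    maternal <- sample(ann$key, sample.int(n_sites, 1))
    paternal <- sample(ann$key, sample.int(n_sites, 1))
    expected <- brute_force_chet(maternal, paternal, gene_of)
    got <- suppressWarnings(detect_compound_het(maternal, paternal, ann))
    expect_equal(sort(got$gene), expected)
  }
})

test_that("swapping parental roles swaps branch assignments exactly", {
  cfg <- simulation_config(n_sites = 300L, seed = 11)
  sim <- suppressMessages(simulate_inputs(cfg, expression = FALSE))
  swapped <- chetscreen:::new_pedigree(within(sim$pedigree$members, {
    tmp <- father_id; father_id <- mother_id; mother_id <- tmp
    rm(tmp)
    sex <- rev(c("male", "female", "female", "male"))
  }))
  for (thr in list(NULL, 0.01)) {
    orig <- suppressMessages(branch_filter(
      sim$matrix, sim$annotations, sim$pedigree,
      branch_criteria("mother", maf_threshold = thr)))
    swap <- suppressMessages(branch_filter(
      sim$matrix, sim$annotations, swapped,
      branch_criteria("father", maf_threshold = thr)))
    expect_identical(orig$survivors, swap$survivors)
  }
})

test_that("predictor consensus is majority vote over available calls", {
  call <- function(...) predictor_consensus(
    setNames(c(...), c("SIFT", "PolyPhen2", "MutationTaster", "M-CAP")))
  # all four benign (the benign-missense pattern)
  expect_equal(call("benign", "benign", "benign", "benign")$verdict, "benign")
  # 2 damaging of 3 available
  res <- call("damaging", "damaging", "benign", NA)
  expect_equal(res$verdict, "damaging")
  expect_equal(res$n_damaging, 2L)
  expect_equal(res$n_available, 3L)
  # exact tie and no-information cases
  expect_equal(call("damaging", "benign", NA, NA)$verdict, "uncertain")
  expect_equal(call(NA, NA, NA, NA)$verdict, "uncertain")
  # annotation-row interface
  row <- ann_tbl(ann_row(sift = "damaging", polyphen2 = "damaging",
                         mutationtaster = "benign"))
  expect_equal(predictor_consensus(row[1, ])$verdict, "damaging")
  # contract: exactly the four named predictors
  expect_error(predictor_consensus(c(SIFT = "benign", Other = "benign")),
               "predictor")
})

test_that("domain truncation and residue mapping match the BRCA2 table", {
  ret <- truncation_retained_domains(871)
  expect_setequal(ret$retained, c("PALB2 binding", "P/CAF binding"))
  expect_equal(ret$partial, character())
  expect_equal(truncation_retained_domains(1)$retained, character())
  # stop beyond the protein end retains everything
  expect_equal(truncation_retained_domains(4000)$retained,
               brca2_domains()$domain)
  # a stop inside a domain reports it as partial
  mid <- truncation_retained_domains(400)
  expect_equal(mid$retained, "PALB2 binding")
  expect_equal(mid$partial, "P/CAF binding")

  expect_equal(locate_in_domain(372), "P/CAF binding")
  expect_equal(locate_in_domain(289), character())  # exclusive below start
  expect_equal(locate_in_domain(290), "P/CAF binding")  # inclusive boundary
  expect_equal(locate_in_domain(453), "P/CAF binding")
  expect_equal(
    truncation_retained_domains(5, data.frame(domain = character(),
                                              start = integer(),
                                              end = integer())),
    list(retained = character(), partial = character()))
})
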