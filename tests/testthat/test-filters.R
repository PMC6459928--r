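test_that("SNV filter enforces the tumor/normal support thresholds", {
  df <- data.frame(t_alt = c(4, 3, 4, 4, 4),
                   t_cov = c(14, 14, 13, 14, 14),
                   n_alt = c(2, 2, 2, 3, 2),
                   n_cov = c(10, 10, 10, 10, 9))
  res <- filterSomaticSnvs(df)
  expect_equal(nrow(res$passed), 1)     # exact boundary passes
  expect_equal(res$rejected$reason,
               c("tumor_support", "tumor_coverage", "normal_support",
                 "normal_coverage"))
  expect_error(filterSomaticSnvs(transform(df, n_alt = NA)), "normal")
})

test_that("indel filter enforces support, coverage and VAF jointly", {
  df <- data.frame(alt = c(6, 6, 6, 5, 0),
                   cov = c(20, 61, 20, 60, 0))
  # VAFs: .30 pass, .098 fail, .30 pass, .083 fail, no coverage
  res <- filterSomaticIndels(df)
  expect_equal(nrow(res$passed), 2)
  expect_true("vaf" %in% unlist(strsplit(res$rejected$reason, ";")))
  expect_true("no_coverage" %in% res$rejected$reason)
})

test_that("filters agree with a brute-force row oracle and partition input", {
  set.seed(101)
  n <- 10000
  snv <- data.frame(t_alt = rpois(n, 4), t_cov = rpois(n, 15),
                    n_alt = rpois(n, 1), n_cov = rpois(n, 11))
  snv$t_cov <- pmax(snv$t_cov, snv$t_alt)
  res <- filterSomaticSnvs(snv)
  oracle <- logical(n)
  for (i in seq_len(n)) {                       # independent re-evaluation
    oracle[i] <- snv$t_alt[i] >= 4 && snv$t_cov[i] >= 14 &&
      snv$n_alt[i] <= 2 && snv$n_cov[i] >= 10
  }
  expect_equal(nrow(res$passed), sum(oracle))
  expect_equal(nrow(res$passed) + nrow(res$rejected), n)
  got <- rep(FALSE, n); got[as.integer(rownames(res$passed))] <- TRUE
  expect_identical(got, oracle)

  ind <- data.frame(alt = rpois(n, 5), cov = rpois(n, 22))
  ind$cov <- pmax(ind$cov, ind$alt)
  resI <- filterSomaticIndels(ind)
  oracleI <- vapply(seq_len(n), function(i) {
    ind$cov[i] > 0 && ind$alt[i] >= 6 && ind$cov[i] >= 20 &&
      ind$alt[i] / ind$cov[i] >= 0.1
  }, TRUE)
  expect_equal(sort(as.integer(rownames(resI$passed))), which(oracleI))
})

test_that("hypermutator flag uses 10x the cohort median, inclusive", {
  burden <- c(ESCC012 = 3028, A = 150, B = 189, C = 200, D = 189, E = 170,
              F = 210)
  expect_identical(flagHypermutators(burden), "ESCC012")
  expect_equal(median(burden[-1]), 189)

  exact <- c(A = 100, B = 100, C = 1000)
  expect_identical(flagHypermutators(exact), "C")   # exactly 10x: flagged
  expect_length(flagHypermutators(c(A = 5, B = 5, C = 5)), 0)
  expect_error(flagHypermutators(numeric(0)), "empty")
})

test_that("germline HR filter keeps truncating or ClinVar-pathogenic rare variants", {
  df <- data.frame(
    gene = c("BRCA2", "BRCA1", "BRCA1", "TP53", "BRCA2"),
    consequence = c("frameshift", "missense", "missense", "frameshift",
                    "frameshift"),
    clinvar_pathogenic = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    coverage = c(50, 60, 60, 60, 50),
    vaf = c(0.48, 0.5, 0.5, 0.5, 0.48),
    population_maf = c(0, 0, 0, 0, 0.02))
  res <- filterGermlineHr(df)
  expect_equal(res$passed$gene, c("BRCA2", "BRCA1"))
  expect_true(any(grepl("not_deleterious", res$rejected$reason)))
  expect_true(any(grepl("gene_panel", res$rejected$reason)))
  expect_true(any(grepl("common_variant", res$rejected$reason)))
  # VAF bound is strict: exactly 8% fails
  df8 <- data.frame(gene = "BRCA1", consequence = "nonsense",
                    clinvar_pathogenic = FALSE, coverage = 40, vaf = 0.08)
  expect_equal(nrow(filterGermlineHr(df8)$passed), 0)
})

test_that("driver annotation applies the recorded-match and recessive rules", {
  cfg <- list(driver_genes = c("NOTCH1", "TP53"),
              cosmic_index = list(
                TP53 = data.frame(pos = c(100, 105, 110, 500),
                                  count = c(1, 1, 1, 2))),
              recessive_genes = "NOTCH1")
  df <- data.frame(
    gene = c("NOTCH1", "TP53", "TP53", "TP53", "NOTCH1"),
    pos = c(1, 100, 107, 400, 2),
    consequence = c("nonsense", "missense", "missense", "missense",
                    "nonsense"),
    sift = c(0.01, NA, 0.4, 0.4, NA),
    polyphen = c(NA, NA, NA, NA, NA))
  res <- annotateDrivers(df, cfg)
  expect_equal(res$driver, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # row 3: three recorded mutations within 15 bp of pos 107
  expect_equal(res$driver_reason[3], "cosmic")
  # row 5: recessive + deleterious but no qualifying score
  expect_false(res$driver[5])
})

test_that("neoantigen filter keeps affinities strictly below 500 nM", {
  df <- data.frame(affinity_nM = c(499.9, 500, 0.1))
  expect_equal(filterNeoantigens(df)$affinity_nM, c(499.9, 0.1))
  expect_equal(nrow(filterNeoantigens(df[0, , drop = FALSE])), 0)
  expect_error(filterNeoantigens(data.frame(affinity_nM = -1)), "negative")
})
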