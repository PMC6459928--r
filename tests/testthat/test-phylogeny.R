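test_that("presence matrix applies the VAF and alt-read thresholds", {
  df <- data.frame(
    patient_id = "P", mutation_id = rep(c("m1", "m2"), each = 2),
    sample_id = rep(c("T1", "T2"), 2),
    alt_reads = c(3L, 0L, 1L, 8L), ref_reads = c(147L, 150L, 19L, 92L))
  pm <- buildPresenceMatrix(df)
  expect_equal(pm["m1", "T1"], 1)      # VAF exactly 0.02, alt 3: present
  expect_equal(pm["m2", "T1"], 0)      # VAF 0.05 but alt 1: min_alt guard
  expect_equal(pm["m2", "T2"], 1)

  one <- df[df$sample_id == "T1", ]
  expect_error(buildPresenceMatrix(one), "2 tumor samples")

  zero <- transform(df, alt_reads = 0L)
  expect_warning(pm0 <- buildPresenceMatrix(zero), "dropped")
  expect_equal(nrow(pm0), 0)
})

test_that("presence matrix matches brute-force thresholding on random counts", {
  set.seed(41)
  n <- 400
  df <- data.frame(
    patient_id = "P",
    mutation_id = rep(sprintf("m%03d", 1:(n / 4)), each = 4),
    sample_id = rep(c("T1", "T2", "T3", "T4"), n / 4),
    alt_reads = rpois(n, 3), ref_reads = rpois(n, 120))
  pm <- suppressWarnings(buildPresenceMatrix(df))
  for (i in sample(nrow(pm), 50)) {
    for (s in colnames(pm)) {
      row <- df[df$mutation_id == rownames(pm)[i] & df$sample_id == s, ]
      v <- row$alt_reads / (row$alt_reads + row$ref_reads)
      expect_equal(pm[i, s],
                   as.integer(v >= 0.02 && row$alt_reads >= 2))
    }
  }
})

test_that("parsimony tree resolves the canonical 3-sample case", {
  P <- matrix(c(1, 1, 1,  1, 1, 0,  0, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("T1", "T2", "T3")))
  tr <- inferParsimonyTree(P)
  expect_identical(trunkMutations(tr), "m1")
  expect_equal(parsimonyScore(tr), 3)
  expect_length(tr@coOptimal, 1)
  expect_true("T1,T2|T3" %in% leafSplits(asPhylo(tr)) ||
                identical(leafSplits(asPhylo(tr)), character(0)))
  # the (T1,T2) clade must carry m2
  keys <- mrith:::.phyloEdgeKeys(asPhylo(tr))
  expect_identical(tr@edgeMutations[[which(keys == "T1|T2")]], "m2")
})

test_that("zero-homoplasy input gives score = mutation count and exact recovery", {
  for (s in c(7, 8, 9)) {
    sim <- simulatePatient(n_regions = 5, muts_per_clone = 8,
                           noiseless = TRUE, seed = s)
    pm <- buildPresenceMatrix(sim$mutations, sim$samples)
    tr <- inferParsimonyTree(pm, "P1")
    expect_equal(parsimonyScore(tr), nrow(pm))
    # planted topology recovered exactly
    planted <- ape::read.tree(text = sim$truth$topologyNewick)
    expect_setequal(leafSplits(asPhylo(tr)), leafSplits(planted))
    # trunk/shared/private labels recovered exactly
    tim <- classifyTiming(tr)
    expect_identical(tim$labels[names(sim$truth$timing)],
                     sim$truth$timing)
  }
})

test_that("ubiquitous-only input collapses to a star with all-trunk timing", {
  P <- matrix(1L, nrow = 12, ncol = 4,
              dimnames = list(sprintf("m%02d", 1:12), paste0("T", 1:4)))
  tr <- inferParsimonyTree(P)
  expect_equal(length(trunkMutations(tr)), 12)
  star <- asPhylo(tr, collapse = TRUE)
  expect_equal(star$Nnode, 1)          # single multifurcation
  expect_equal(classifyTiming(tr)$summary$prop_trunk, 1)
})

test_that("parsimony scoring agrees with exhaustive state enumeration", {
  set.seed(53)
  labels <- paste0("T", 1:5)
  for (rep in 1:30) {
    tree <- mrith:::.randomBinaryTree(labels)
    pat <- matrix(sample(0:1, 5 * 6, replace = TRUE), ncol = 5,
                  dimnames = list(NULL, labels))
    pat <- pat[rowSums(pat) > 0, , drop = FALSE]
    got <- mrith:::.scoreTopology(tree, pat, rep(1, nrow(pat)),
                                  labels)$perPattern
    for (i in seq_len(nrow(pat))) {
      expect_equal(got[i],
                   bruteParsimonyScore(tree, setNames(pat[i, ], labels)))
    }
  }
})

test_that("timing classification and trunk proportion ignore column order", {
  sim <- simulatePatient(n_regions = 4, muts_per_clone = 10,
                         noiseless = TRUE, seed = 13)
  pm <- buildPresenceMatrix(sim$mutations, sim$samples)
  t1 <- classifyTiming(pm)
  t2 <- classifyTiming(pm[, rev(colnames(pm))])
  expect_equal(t1$summary$prop_trunk, t2$summary$prop_trunk)
  expect_identical(t1$labels, t2$labels[names(t1$labels)])
  # definitional checks
  expect_true(all(t1$labels[rowSums(pm) == ncol(pm)] == "trunk"))
  expect_true(all(t1$labels[rowSums(pm) == 1] == "private"))
})

test_that("intermixed clones are flagged by foreign-branch CCF", {
  sim <- simulatePatient(n_regions = 5, muts_per_clone = 15,
                         depth = 400, seed = 17,
                         intermix = list(sample = "P1_T1", ccf = 0.25))
  pm <- buildPresenceMatrix(sim$mutations, sim$samples)
  tr <- inferParsimonyTree(pm, "P1")
  cc <- ccfTable(sim$mutations, sim$samples)
  hits <- detectIntermixing(tr, cc, ccf_min = 0.1)
  expect_true("P1_T1" %in% hits$sample_id)

  clean <- simulatePatient(n_regions = 5, muts_per_clone = 15,
                           depth = 400, seed = 17)
  pmC <- buildPresenceMatrix(clean$mutations, clean$samples)
  trC <- inferParsimonyTree(pmC, "P1")
  ccC <- ccfTable(clean$mutations, clean$samples)
  expect_equal(nrow(detectIntermixing(trC, ccC, ccf_min = 0.1)), 0)
  # an impossible threshold never flags
  expect_equal(nrow(detectIntermixing(tr, cc, ccf_min = 1.1)), 0)
})

test_that("seeding patterns are recovered from planted topologies", {
  for (pat in c("monoclonal", "linear", "explosive")) {
    sim <- simulatePatient(n_regions = 4, n_mets = 3, seeding = pat,
                           muts_per_clone = 10, noiseless = TRUE,
                           seed = 23)
    pm <- buildPresenceMatrix(sim$mutations, sim$samples)
    tr <- inferParsimonyTree(pm, "P1")
    expected <- switch(pat, monoclonal = "monoclonal_precursor",
                       linear = "linear", explosive = "explosive")
    expect_identical(classifySeeding(tr, sim$samples), expected)
  }
  noMet <- simulatePatient(n_regions = 3, noiseless = TRUE, seed = 23)
  pm <- buildPresenceMatrix(noMet$mutations, noMet$samples)
  tr <- inferParsimonyTree(pm, "P1")
  expect_error(classifySeeding(tr, noMet$samples), "no_metastasis")
})

test_that("exhaustive search refuses more than 9 samples", {
  P <- matrix(1L, nrow = 2, ncol = 10,
              dimnames = list(c("m1", "m2"), paste0("T", 1:10)))
  expect_error(inferParsimonyTree(P), "heuristic")
})
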