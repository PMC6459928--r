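test_that("channel normalization reverse-complements purine references", {
  expect_identical(channelOf("G", "T", "AGC"), "G[C>A]T")
  expect_identical(channelOf("C", "A", "GCT"), "G[C>A]T")
  expect_true(is.na(channelOf("C", "A", "GAT")))   # middle base mismatch
  expect_true(is.na(channelOf("CC", "A", "GCT")))

  snvs <- data.frame(ref = "G", alt = "T", tri_context = "AGC")
  spec <- buildSpectrum(snvs)
  expect_equal(unname(spec["G[C>A]T"]), 1)
  expect_equal(sum(spec), 1)
  expect_equal(sum(buildSpectrum(snvs[0, ])), 0)
})

test_that("spectrum channel frequencies follow the generating mixture", {
  sim <- simulatePatient(n_regions = 2, muts_per_clone = 400,
                         n_clones = 1, seed = 61)
  uniq <- sim$mutations[!duplicated(sim$mutations$mutation_id), ]
  spec <- buildSpectrum(uniq)
  n <- sum(spec)
  p <- as.vector(signatureCatalog() %*% sim$truth$signatureMix)
  sdv <- sqrt(n * p * (1 - p))
  expect_gt(mean(abs(spec - n * p) <= 3 * sdv + 1e-9), 0.95)
})

test_that("exposure fitting is exact on catalog columns and mixtures", {
  K <- signatureCatalog()
  e1 <- fitExposures(1000 * K[, 1], K)
  pr <- exposureProportions(e1)
  expect_equal(unname(pr["Signature.1"]), 1, tolerance = 1e-6)
  expect_lt(max(pr[-1]), 1e-6)
  expect_identical(dominantSignature(e1), "Signature.1")
  expect_lt(e1@reconstructionError, 1e-8)

  eMix <- fitExposures(500 * (K[, 2] + K[, 13]), K)
  prM <- exposureProportions(eMix)
  expect_equal(unname(prM["Signature.2"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(prM["Signature.13"]), 0.5, tolerance = 1e-6)

  # scale equivariance
  spec <- 200 * K[, 5] + 300 * K[, 7]
  a <- fitExposures(spec, K)@contributions
  b <- fitExposures(3 * spec, K)@contributions
  expect_equal(b, 3 * a, tolerance = 1e-6)

  z <- fitExposures(setNames(numeric(96), rownames(K)), K)
  expect_true(is.na(dominantSignature(z)))
  expect_equal(sum(z@contributions), 0)
})

test_that("planted mixtures are recovered within 0.05 at 5000 SNVs", {
  K <- signatureCatalog()
  set.seed(71)
  for (idx in list(c(1, 3, 13), c(3, 6, 22))) {
    mix <- numeric(30); mix[idx] <- c(0.3, 0.4, 0.3)
    counts <- as.vector(rmultinom(1, 5000, K %*% mix))
    names(counts) <- rownames(K)
    pr <- exposureProportions(fitExposures(counts, K))
    expect_lt(max(abs(pr - setNames(mix, colnames(K)))), 0.05)
  }
})

test_that("trunk/branch phase exposures expose a planted late signature", {
  K <- signatureCatalog()
  ch <- substitutionChannels()
  makeCohort <- function(seed, branchShift) {
    set.seed(seed)
    rows <- list(); timing <- character(0)
    for (p in paste0("P", 1:6)) {
      mixT <- numeric(30); mixT[c(1, 2)] <- c(0.6, 0.4)
      mixB <- mixT
      if (branchShift > 0) {
        mixB <- (1 - branchShift) * mixB
        mixB[3] <- mixB[3] + branchShift
      }
      for (phase in c("trunk", "branch")) {
        mix <- if (phase == "trunk") mixT else mixB
        chs <- sample(ch, 150, replace = TRUE,
                      prob = as.vector(K %*% mix))
        ids <- paste(p, phase, seq_along(chs), sep = "_")
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p, mutation_id = ids,
          ref = substr(chs, 3, 3), alt = substr(chs, 5, 5),
          tri_context = paste0(substr(chs, 1, 1), substr(chs, 3, 3),
                               substr(chs, 7, 7)),
          stringsAsFactors = FALSE)
        timing <- c(timing, setNames(
          rep(if (phase == "trunk") "trunk" else "shared", length(ids)),
          ids))
      }
    }
    list(mutations = do.call(rbind, rows), timing = timing)
  }
  hits <- vapply(1:10, function(s) {
    co <- makeCohort(s, branchShift = 0.35)
    res <- phaseExposures(co$mutations, co$timing)
    tab <- res$table
    b <- tab$proportion[tab$phase == "branch"]
    t <- tab$proportion[tab$phase == "trunk"]
    mean(b > t)
  }, 0)
  expect_gte(mean(hits >= 0.9), 0.9)   # branch sig3 above trunk's

  # a patient with no branch mutations is excluded from the paired test
  co <- makeCohort(1, 0.35)
  co$timing[grepl("^P1_branch", names(co$timing))] <- NA
  co$mutations <- co$mutations[!is.na(co$timing[co$mutations$mutation_id]), ]
  co$timing <- co$timing[!is.na(co$timing)]
  res <- phaseExposures(co$mutations, co$timing)
  expect_true(is.na(res$table$proportion[res$table$patient_id == "P1" &
                                           res$table$phase == "branch"]))
  expect_false(is.null(res$test))
})

test_that("AUC equals the Mann-Whitney statistic with half-weighted ties", {
  expect_equal(aucSignature3(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(aucSignature3(rep(1, 6), c(1, 1, 0, 0, 0, 0))$auc, 0.5)
  expect_error(aucSignature3(1:3, c(1, 1, 1)), "negative")

  set.seed(81)
  for (i in 1:20) {
    x <- sample(0:5, 30, replace = TRUE)       # force ties
    y <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.4, .6))
    if (sum(y) == 0 || sum(!y) == 0) next
    w <- suppressWarnings(
      stats::wilcox.test(x[y], x[!y])$statistic / (sum(y) * sum(!y)))
    expect_equal(aucSignature3(x, y)$auc, unname(w), tolerance = 1e-12)
  }
})
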