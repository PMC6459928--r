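test_that("preprocessing drops low-frequency clones and normalizes", {
  rec <- data.frame(
    sample_id = "S", chain = "TRB",
    cdr3_aa = c("CASA", "CASB", "CASC", "CASD"),
    v_gene = "TRBV1", j_gene = "TRBJ1",
    count = c(999995L - 2L - 3L, 2L, 3L, 1L),
    productive = c(TRUE, TRUE, TRUE, FALSE))
  # productive total is 999998: CASB sits at 2.000004 per million (kept,
  # the rule drops clones at or below 2 per million exactly)
  rep1 <- preprocessRepertoire(rec, "S", "TRB")
  expect_false("CASD|TRBV1|TRBJ1" %in% rep1@clones$clone_id)  # unproductive

  rec2 <- rec[rec$productive, ]
  rec2$count <- c(1e6 - 5, 2, 3)
  rep2 <- preprocessRepertoire(rec2, "S", "TRB")
  ids <- rep2@clones$cdr3_aa
  expect_false("CASB" %in% ids)        # exactly 2 per million: removed
  expect_true("CASC" %in% ids)         # 3 per million: kept
  expect_equal(sum(rep2@clones$freq), 1, tolerance = 1e-9)

  # below one million reads: no downsampling
  small <- data.frame(sample_id = "S", chain = "TRB",
                      cdr3_aa = c("CASA", "CASB"), v_gene = "V",
                      j_gene = "J", count = c(600L, 400L),
                      productive = TRUE)
  rs <- preprocessRepertoire(small, "S", "TRB")
  expect_equal(rs@totalReads, 1000)
  expect_equal(rs@clones$freq, c(0.6, 0.4))

  # downsampling is seed-deterministic
  big <- data.frame(sample_id = "S", chain = "TRB",
                    cdr3_aa = sprintf("C%03d", 1:50), v_gene = "V",
                    j_gene = "J", count = rep(50000L, 50),
                    productive = TRUE)
  d1 <- preprocessRepertoire(big, "S", "TRB", seed = 9)
  d2 <- preprocessRepertoire(big, "S", "TRB", seed = 9)
  expect_identical(d1@clones, d2@clones)
  expect_equal(d1@totalReads, 1e6)

  expect_error(preprocessRepertoire(rec[rec$cdr3_aa == "CASD", ], "S",
                                    "TRB"), "productive")
})

test_that("diversity metrics evaluate the evenness and CR4 formulas", {
  u8 <- makeRepertoire(setNames(rep(100, 8), paste0("c", 1:8)))
  d <- repertoireDiversity(u8)
  expect_equal(d$shannon, 3)
  expect_equal(d$evenness, 1)
  expect_equal(d$clonality, 0)
  expect_equal(d$cr4, 0.5)

  d2 <- repertoireDiversity(makeRepertoire(c(a = 75, b = 25)))
  expect_equal(d2$shannon, 0.8113, tolerance = 1e-4)
  expect_equal(d2$evenness, 0.8113, tolerance = 1e-4)

  d3 <- repertoireDiversity(
    makeRepertoire(c(a = 40, b = 30, c = 20, d = 5, e = 5)))
  expect_equal(d3$cr4, 0.95)

  d1c <- repertoireDiversity(makeRepertoire(c(only = 10)))
  expect_equal(d1c$evenness, 0)
  expect_equal(d1c$clonality, 1)
})

test_that("diversity agrees with a one-line recomputation on random repertoires", {
  set.seed(121)
  for (i in 1:300) {
    k <- sample(2:40, 1)
    counts <- setNames(sample(1:500, k, replace = TRUE),
                       paste0("c", 1:k))
    rep <- makeRepertoire(counts)
    d <- repertoireDiversity(rep)
    p <- counts / sum(counts)
    expect_equal(d$shannon, -sum(p * log2(p)), tolerance = 1e-9)
    expect_equal(d$evenness, -sum(p * log2(p)) / log2(k),
                 tolerance = 1e-9)
    expect_equal(d$cr4, sum(sort(p, decreasing = TRUE)[1:min(4, k)]),
                 tolerance = 1e-9)
  }
})

test_that("pairwise distances evaluate the Jaccard and count-overlap formulas", {
  A <- list(TRA = makeRepertoire(c(x = 10, y = 10), "A", "TRA"),
            TRB = makeRepertoire(c(c1 = 5, c2 = 5, c3 = 5), "A", "TRB"))
  # identical repertoires: zero distance
  self <- repertoireDistance(A, A)
  expect_equal(self$distance_jaccard, 0)
  expect_equal(self$distance_overlap, 0)

  # {c1,c2,c3} vs {c2,c3,c4}: Jaccard 0.5 per chain -> Eq 4 distance 1
  B <- list(TRA = makeRepertoire(c(x = 10, z = 10), "B", "TRA"),
            TRB = makeRepertoire(c(c2 = 5, c3 = 5, c4 = 5), "B", "TRB"))
  d <- repertoireDistance(A, B)
  expect_equal(unname(d$jaccard_trb), 0.5)
  expect_equal(unname(d$jaccard_tra), 1 / 3)
  expect_equal(d$distance_jaccard, 0.5 * (1 / 0.5 - 1) + 0.5 * (3 - 1))

  # count overlap worked example: a=(10,5), sumA=30; b=(20,5), sumB=50
  A2 <- list(TRB = makeRepertoire(c(s1 = 10, s2 = 5, p1 = 15), "A"),
             TRA = makeRepertoire(c(s1 = 10, s2 = 5, p1 = 15), "A", "TRA"))
  B2 <- list(TRB = makeRepertoire(c(s1 = 20, s2 = 5, q1 = 25), "B"),
             TRA = makeRepertoire(c(s1 = 20, s2 = 5, q1 = 25), "B", "TRA"))
  d2 <- repertoireDistance(A2, B2)
  expect_equal(unname(d2$overlap_trb), 0.5)
  expect_equal(d2$distance_overlap, 1.0)   # both chains at overlap 0.5

  # missing chain: remaining chain takes full weight
  d3 <- repertoireDistance(A2["TRB"], B2["TRB"])
  expect_equal(d3$distance_overlap, 1 / 0.5 - 1)
  expect_identical(d3$chains_used, "TRB")

  # disjoint clone sets: capped distance with flag
  C <- list(TRB = makeRepertoire(c(zz = 5), "C"))
  d4 <- repertoireDistance(A2["TRB"], C)
  expect_true(d4$capped)
  expect_equal(d4$distance_jaccard, 1e6)
})

test_that("distance formulas agree with direct recomputation on random designs", {
  set.seed(131)
  for (i in 1:200) {
    nA <- sample(3:20, 1); nB <- sample(3:20, 1)
    pool <- paste0("c", 1:25)
    a <- setNames(sample(1:100, nA), sample(pool, nA))
    b <- setNames(sample(1:100, nB), sample(pool, nB))
    A <- list(TRB = makeRepertoire(a, "A"))
    B <- list(TRB = makeRepertoire(b, "B"))
    d <- repertoireDistance(A, B)
    sh <- intersect(names(a), names(b))
    jac <- length(sh) / length(union(names(a), names(b)))
    ovl <- (sum(a[sh]) + sum(b[sh])) / (sum(a) + sum(b))
    expect_equal(unname(d$jaccard_trb), jac, tolerance = 1e-12)
    expect_equal(unname(d$overlap_trb), ovl, tolerance = 1e-12)
    if (jac > 0) {
      expect_equal(d$distance_jaccard, 1 / jac - 1, tolerance = 1e-12)
      expect_equal(d$distance_overlap, 1 / ovl - 1, tolerance = 1e-12)
    } else {
      expect_true(d$capped)
    }
  }
})

test_that("neighbor joining recovers additive trees and validates input", {
  D <- additiveMatrix4()
  ph <- buildNjTree(D)
  expect_true("A,B|C,D" %in% leafSplits(ph))
  # additive matrix: path lengths reproduced exactly
  expect_equal(ape::cophenetic.phylo(ph)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  eq <- matrix(1, 4, 4, dimnames = dimnames(D)); diag(eq) <- 0
  ph2 <- buildNjTree(eq)
  expect_true(all(ph2$edge.length >= 0))

  expect_error(buildNjTree(D[1:2, 1:2]), "3 samples")
  asym <- D; asym[1, 2] <- 99
  expect_error(buildNjTree(asym), "symmetric")
})

test_that("tree concordance scores genetic clades against TCR distances", {
  g <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  res <- treeConcordance(g, t1)
  expect_equal(res$score, 1)

  expect_error(treeConcordance(g, ape::keep.tip(t1, c("A", "B", "C"))),
               "4 shared")

  # planted concordant TCR distances: genetic cophenetic + small noise
  # (clades separated by unit-length internal edges, so the planted
  # signal dominates the noise)
  set.seed(141)
  g2 <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  Dg <- ape::cophenetic.phylo(g2)
  scores <- vapply(1:10, function(i) {
    noise <- matrix(runif(36, 0, 0.05), 6, 6)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    Dt <- Dg + noise
    ph <- buildNjTree(Dt)
    treeConcordance(g2, ph)$score
  }, 0)
  expect_gte(mean(scores), 0.8)
})
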