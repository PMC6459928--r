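test_that("patient simulator is seed-deterministic and honors clone count", {
  a <- simulatePatient(n_regions = 3, muts_per_clone = 5, seed = 3)
  b <- simulatePatient(n_regions = 3, muts_per_clone = 5, seed = 3)
  expect_identical(a$mutations, b$mutations)

  # single clone: every mutation present in every region (pure trunk)
  one <- simulatePatient(n_regions = 3, n_clones = 1, muts_per_clone = 10,
                         noiseless = TRUE, seed = 5)
  expect_true(all(one$truth$timing == "trunk"))
  pm <- buildPresenceMatrix(one$mutations, one$samples)
  expect_true(all(pm == 1))

  expect_error(simulatePatient(n_regions = 1), "n_regions")
  expect_error(simulatePatient(n_clones = 0), "n_clones")
})

test_that("simulated VAFs track the planted clone fractions", {
  sim <- simulatePatient(n_regions = 3, n_clones = 4, muts_per_clone = 40,
                         depth = 300, seed = 11)
  tum <- sim$mutations[sim$mutations$sample_id %in%
                         colnames(sim$truth$expectedVaf), ]
  exp_v <- sim$truth$expectedVaf[cbind(tum$mutation_id, tum$sample_id)]
  tot <- tum$alt_reads + tum$ref_reads
  obs <- tum$alt_reads / tot
  sdv <- sqrt(pmax(exp_v * (1 - exp_v), 1e-12) / tot)
  frac3sd <- mean(abs(obs - exp_v) <= 3 * sdv + 1e-12)
  expect_gt(frac3sd, 0.99)

  # clone-fraction invariants: fractions in [0,1], nested along lineages
  expect_true(all(sim$truth$ccfClone >= 0 & sim$truth$ccfClone <= 1))
})

test_that("neutral VAF generator matches its theoretical law", {
  expect_error(simulateNeutralVafs(n_mut = NULL, mu_eff = -1), "mu_eff")
  empty <- simulateNeutralVafs(n_mut = 0, seed = 1)
  expect_equal(nrow(empty), 0)

  # true frequencies follow the stated CDF (KS check, two seeds)
  cdf <- function(v, fmin = 0.05, fmax = 0.25) {
    mass <- 1 / fmin - fmin / fmax
    ((1 / fmin - 1 / v) + (v - fmin) / fmax) / mass
  }
  for (s in c(21, 22)) {
    tr <- attr(simulateNeutralVafs(n_mut = 3000, seed = s), "truth")
    ks <- suppressWarnings(stats::ks.test(cdf(tr$vaf), "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("BAF segment simulator plants (or not) the haplotype mirror", {
  st <- list(S1 = c(2, 1), S2 = c(2, 1))
  mir <- simulateBafSegments(300, purity = 1, states = st,
                             mirrored = TRUE, seed = 7)$snps
  m1 <- with(mir[mir$sample_id == "S1" & mir$phase_id == "hap1", ],
             mean(b_reads / (a_reads + b_reads)))
  m2 <- with(mir[mir$sample_id == "S2" & mir$phase_id == "hap1", ],
             mean(b_reads / (a_reads + b_reads)))
  expect_true((m1 - 0.5) * (m2 - 0.5) < 0)   # opposite sides of 0.5

  same <- simulateBafSegments(300, purity = 1, states = st,
                              mirrored = FALSE, seed = 7)$snps
  s1 <- with(same[same$sample_id == "S1" & same$phase_id == "hap1", ],
             mean(b_reads / (a_reads + b_reads)))
  s2 <- with(same[same$sample_id == "S2" & same$phase_id == "hap1", ],
             mean(b_reads / (a_reads + b_reads)))
  expect_true((s1 - 0.5) * (s2 - 0.5) > 0)

  bal <- simulateBafSegments(500, purity = 0.8,
                             states = list(S1 = c(1, 1), S2 = c(1, 1)),
                             seed = 7)$snps
  expect_equal(mean(bal$baf), 0.5, tolerance = 0.02)
  expect_error(simulateBafSegments(10, purity = 1.5, states = st), "purity")
})

test_that("TCR cohort simulator realizes planted sharing exactly", {
  full <- tcrSharingDesign(c("A", "B"), n_shared = 30, n_private = 0)
  rec <- simulateTcrCohort(full, seed = 1)
  a <- unique(rec$clone_id[rec$sample_id == "A" & rec$chain == "TRB"])
  b <- unique(rec$clone_id[rec$sample_id == "B" & rec$chain == "TRB"])
  expect_equal(length(intersect(a, b)) / length(union(a, b)), 1)

  disj <- tcrSharingDesign(c("A", "B"), n_shared = 0, n_private = 30)
  rec2 <- simulateTcrCohort(disj, seed = 1)
  a2 <- unique(rec2$clone_id[rec2$sample_id == "A" & rec2$chain == "TRB"])
  b2 <- unique(rec2$clone_id[rec2$sample_id == "B" & rec2$chain == "TRB"])
  expect_equal(length(intersect(a2, b2)), 0)

  half <- tcrSharingDesign(c("A", "B"), n_shared = 40, n_private = 40)
  rec3 <- simulateTcrCohort(half, seed = 1)
  a3 <- unique(rec3$clone_id[rec3$sample_id == "A" & rec3$chain == "TRB"])
  b3 <- unique(rec3$clone_id[rec3$sample_id == "B" & rec3$chain == "TRB"])
  expect_equal(length(intersect(a3, b3)) / length(union(a3, b3)), 1 / 3)

  expect_error(simulateTcrCohort(list(TRB = list(membership = list(),
                                                 total = 1, alpha = 1))),
               "empty")
})

test_that("BRCA cohort simulator hits its closed-form AUC limits", {
  null <- simulateBrcaCohort(400, 400, sep = 0, seed = 2)
  expect_equal(aucSignature3(null$sig3, null$brca)$auc, 0.5,
               tolerance = 0.06)
  far <- simulateBrcaCohort(200, 200, sep = 8, seed = 2)
  expect_gt(aucSignature3(far$sig3, far$brca)$auc, 0.99)
  expect_error(simulateBrcaCohort(0, 5, 1), "n_pos")
})
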