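#' @include tree-utils.R channels.R
NULL

# parse a channel label "A[C>A]G" into ref/alt/context
.parseChannel <- function(channel) {
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  ctx <- paste0(substr(channel, 1, 1), ref, substr(channel, 7, 7))
  data.frame(ref = ref, alt = alt, tri_context = ctx,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-region tumor patient with known clone tree
#'
#' Generates one patient: a rooted sample topology over `n_regions` primary
#' regions (plus optional lymph-node metastases), one clone per topology
#' edge with `muts_per_clone` mutations, and per-sample read counts drawn as
#' alt ~ Binomial(coverage, purity x CCF / 2) with coverage ~ Poisson(depth)
#' — the expected VAF of a heterozygous mutation in a diploid genome. Clone
#' CCFs decay geometrically along each root-to-leaf path (`retention` per
#' step), so trunk mutations are clonal and deeper clones are subclonal.
#' Trinucleotide contexts are drawn from `signature_mix` applied to the
#' packaged catalog.
#'
#' Metastatic seeding patterns:
#' * `"monoclonal"` — all mets form one clade, sister to all primaries
#'   (metastasis-to-metastasis spread from one precursor);
#' * `"linear"` — mets attach in a chain along the lineage of one primary
#'   region;
#' * `"explosive"` — each met attaches independently at the trunk node
#'   (the connecting edges carry no mutations);
#' * `"none"` — primary regions only (`n_mets` ignored).
#'
#' @param n_regions Number of primary tumor regions (>= 2). Default 5,
#'   the five spatially isolated specimens sampled per patient.
#' @param n_mets Number of lymph-node metastasis samples.
#' @param n_clones Number of mutation-bearing clones; `NULL` = one per
#'   topology edge (fully resolvable tree). Clones fill edges trunk-first.
#' @param muts_per_clone Mutations carried by each clone.
#' @param depth Mean tumor sequencing depth (default 290).
#' @param normal_depth Mean matched-normal depth (default 187).
#' @param purity Tumor purity shared by all tumor samples, in (0, 1].
#' @param signature_mix Non-negative 30-vector summing to 1 (signature
#'   mixing proportions); default mixes aging, APOBEC and HRD-like
#'   processes (signatures 1, 2, 13, 3).
#' @param seeding Seeding pattern for the metastases (see above).
#' @param retention Per-step CCF retention along a lineage, in (0, 1].
#' @param intermix `NULL`, or `list(sample=, ccf=)` planting clone
#'   intermixing: the sample additionally carries the mutations of a shared
#'   branch from a foreign clade at the given CCF.
#' @param noiseless Deterministic counts (coverage = depth exactly,
#'   alt = round(coverage x VAF)); used for exact-recovery checks.
#' @param patient_id Patient label.
#' @param seed Integer seed; all randomness is derived from it.
#' @return `list(mutations, samples, truth)`: a long mutation data.frame
#'   (one row per mutation x sample, including the matched normal), a
#'   sample metadata data.frame, and a ground-truth list with the planted
#'   topology (`topologyNewick`), clone table, per-mutation clone and
#'   timing labels, and the true CCF matrix.
#' @export
simulatePatient <- function(n_regions = 5, n_mets = 0, n_clones = NULL,
                            muts_per_clone = 20, depth = 290,
                            normal_depth = 187, purity = 0.8,
                            signature_mix = NULL,
                            seeding = c("none", "monoclonal", "linear",
                                        "explosive"),
                            retention = 0.75, intermix = NULL,
                            noiseless = FALSE, patient_id = "P1", seed = 1) {
  seeding <- match.arg(seeding)
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (!is.null(n_clones) && n_clones < 1) stop("n_clones must be >= 1")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (n_mets < 1) seeding <- "none"
  if (seeding == "none") n_mets <- 0
  set.seed(seed)

  regions <- paste0(patient_id, "_T", seq_len(n_regions))
  mets <- if (n_mets > 0) paste0(patient_id, "_L", seq_len(n_mets)) else character(0)
  normal <- paste0(patient_id, "_N")

  prim <- .randomBinaryTree(regions)
  tree <- switch(seeding,
    none = prim,
    monoclonal = list(prim, if (n_mets == 1) mets else .randomBinaryTree(mets)),
    linear = {
      target <- regions[1]
      chain <- target
      for (m in rev(mets)) chain <- list(m, chain)
      .replaceLeaf(prim, target, chain)
    },
    explosive = {
      t <- prim
      for (m in mets) t <- list(m, t)
      t
    })

  tumorSamples <- .treeLeaves(tree)
  edges <- .treeEdges(tree)                  # preorder; [[1]] is the trunk
  keys <- vapply(edges, .edgeKey, "")
  sizes <- vapply(edges, length, 0L)

  eligible <- rep(TRUE, length(edges))
  if (seeding == "explosive") {
    # the caterpillar spine (mixed met+primary subsets below the trunk)
    # carries no mutations, so the mets attach at the trunk node
    mixed <- vapply(edges, function(lv) {
      any(lv %in% mets) && any(lv %in% regions)
    }, TRUE)
    eligible <- !(mixed & seq_along(edges) > 1L)
  }
  # clone-bearing edges, trunk first then by decreasing subtree size
  ord <- order(-sizes, keys)
  ord <- c(1L, setdiff(ord, 1L))
  ord <- ord[eligible[ord]]
  if (is.null(n_clones)) n_clones <- length(ord)
  if (n_clones > length(ord)) {
    warning("n_clones exceeds the number of topology edges; capped")
    n_clones <- length(ord)
  }
  cloneEdges <- ord[seq_len(n_clones)]

  cloneIds <- paste0("clone", seq_len(n_clones))
  cloneLeafSets <- edges[cloneEdges]
  names(cloneLeafSets) <- cloneIds

  # per-sample clone CCFs: geometric decay along the root-to-leaf path
  ccfClone <- matrix(0, nrow = n_clones, ncol = length(tumorSamples),
                     dimnames = list(cloneIds, tumorSamples))
  for (s in tumorSamples) {
    onPath <- which(vapply(cloneLeafSets, function(lv) s %in% lv, TRUE))
    onPath <- onPath[order(-vapply(cloneLeafSets[onPath], length, 0L))]
    ccfClone[onPath, s] <- retention^(seq_along(onPath) - 1)
  }

  intermixTruth <- NULL
  if (!is.null(intermix)) {
    sm <- intermix$sample
    if (!sm %in% tumorSamples) stop("intermix$sample is not a tumor sample")
    foreign <- which(vapply(cloneLeafSets, function(lv) !(sm %in% lv), TRUE))
    if (length(foreign) == 0) stop("no foreign clone available for intermixing")
    fsize <- vapply(cloneLeafSets[foreign], length, 0L)
    shared <- foreign[fsize >= 2]
    # spill from the smallest shared foreign clade: a minority signal
    # that does not overturn the backbone topology
    pick <- if (length(shared) > 0) {
      shared[which.min(fsize[fsize >= 2])]
    } else foreign[1]
    ccfClone[pick, sm] <- intermix$ccf
    intermixTruth <- list(sample = sm, clone = cloneIds[pick],
                          ccf = intermix$ccf,
                          cladeLeaves = cloneLeafSets[[pick]])
  }

  # mutations
  if (is.null(signature_mix)) {
    signature_mix <- numeric(30)
    signature_mix[c(1, 2, 13, 3)] <- c(0.35, 0.2, 0.2, 0.25)
  }
  if (length(signature_mix) != 30 || any(signature_mix < 0)) {
    stop("signature_mix must be a non-negative 30-vector")
  }
  signature_mix <- signature_mix / sum(signature_mix)
  catalog <- signatureCatalog()
  channelProbs <- as.vector(catalog %*% signature_mix)

  nMut <- n_clones * muts_per_clone
  mutClone <- rep(cloneIds, each = muts_per_clone)
  chIdx <- sample.int(96, nMut, replace = TRUE, prob = channelProbs)
  chs <- substitutionChannels()[chIdx]
  ra <- .parseChannel(chs)
  chrom <- as.character(sample.int(22, nMut, replace = TRUE))
  pos <- sample.int(1e8, nMut, replace = FALSE)
  gene <- sprintf("G%03d", sample.int(300, nMut, replace = TRUE))
  consequence <- sample(c("missense", "silent", "nonsense"), nMut,
                        replace = TRUE, prob = c(0.7, 0.25, 0.05))
  mutIds <- mutationId(patient_id, chrom, pos, ra$ref, ra$alt)

  ccfMut <- ccfClone[mutClone, , drop = FALSE]
  rownames(ccfMut) <- mutIds
  vafExp <- purity * ccfMut / 2

  rows <- vector("list", length(tumorSamples) + 1L)
  for (j in seq_along(tumorSamples)) {
    s <- tumorSamples[j]
    cov <- if (noiseless) rep(depth, nMut) else rpois(nMut, depth)
    cov[cov == 0] <- 1L
    alt <- if (noiseless) round(cov * vafExp[, s]) else
      rbinom(nMut, cov, vafExp[, s])
    rows[[j]] <- data.frame(
      patient_id = patient_id, sample_id = s, chrom = chrom, pos = pos,
      ref = ra$ref, alt = ra$alt, variant_type = "SNV", gene = gene,
      consequence = consequence, tri_context = ra$tri_context,
      alt_reads = as.integer(alt), ref_reads = as.integer(cov - alt),
      mutation_id = mutIds, stringsAsFactors = FALSE)
  }
  covN <- if (noiseless) rep(normal_depth, nMut) else rpois(nMut, normal_depth)
  covN[covN == 0] <- 1L
  rows[[length(rows)]] <- data.frame(
    patient_id = patient_id, sample_id = normal, chrom = chrom, pos = pos,
    ref = ra$ref, alt = ra$alt, variant_type = "SNV", gene = gene,
    consequence = consequence, tri_context = ra$tri_context,
    alt_reads = 0L, ref_reads = as.integer(covN),
    mutation_id = mutIds, stringsAsFactors = FALSE)
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL

  samples <- data.frame(
    patient_id = patient_id,
    sample_id = c(tumorSamples, normal),
    sample_type = c(ifelse(tumorSamples %in% mets, "lymph_node_met",
                           "primary_region"), "normal_tissue"),
    purity = c(rep(purity, length(tumorSamples)), NA_real_),
    ploidy = c(rep(2, length(tumorSamples)), NA_real_),
    mean_depth = c(rep(depth, length(tumorSamples)), normal_depth),
    stringsAsFactors = FALSE)

  present <- ccfMut > 0
  nPresent <- rowSums(present)
  timing <- ifelse(nPresent == length(tumorSamples), "trunk",
                   ifelse(nPresent == 1, "private", "shared"))

  truth <- list(
    topologyNewick = .treeToNewick(tree),
    cloneLeafSets = cloneLeafSets,
    mutationClone = setNames(mutClone, mutIds),
    ccfClone = ccfClone,
    ccfMutation = ccfMut,
    expectedVaf = vafExp,
    timing = setNames(timing, mutIds),
    signatureMix = signature_mix,
    seeding = seeding,
    intermix = intermixTruth,
    purity = purity)
  list(mutations = mutations, samples = samples, truth = truth)
}

.replaceLeaf <- function(tree, target, replacement) {
  if (is.character(tree)) {
    if (identical(tree, target)) return(replacement)
    return(tree)
  }
  lapply(tree, .replaceLeaf, target = target, replacement = replacement)
}

#' Simulate read counts under the neutral tumor growth model
#'
#' Draws variant allele frequencies with density proportional to
#' 1/f^2 + 1/f_max on (`f_min`, sqrt(`f_max`)), which makes the cumulative
#' count exactly M(f) = (mu/beta)(1/f - f/f_max) with M(sqrt(f_max)) = 0
#' (for f_max = 0.25 the support ends at 0.5, the clonal VAF of a pure
#' diploid tumor). Read counts are then resampled at the given depth:
#' coverage ~ Poisson(depth), alt ~ Binomial(coverage, f).
#'
#' The 1/f^2 shape is parameter-free, so `mu_eff` only sets the expected
#' mutation count: when `n_mut` is given it takes precedence and the
#' implied true slope is recorded in the returned truth attribute;
#' otherwise the count is Poisson with mean `mu_eff` times the support mass.
#'
#' An optional subclonal cluster (`subclone`) adds mutations at VAF
#' purity x ccf / 2, the non-neutral alternative used in power checks.
#'
#' @param n_mut Number of neutral-tail mutations (exact); `NULL` to derive
#'   the count from `mu_eff`.
#' @param mu_eff Mutation rate per effective division (the slope mu/beta).
#' @param f_max Expected clonal VAF parameter of the model (default 0.25).
#' @param f_min Lower edge of the simulated frequency support.
#' @param depth Mean sequencing depth.
#' @param subclone `NULL` or `list(ccf=, n=, purity=)`: planted subclone.
#' @param seed Integer seed.
#' @return data.frame with columns `alt`, `total` and attribute `truth`
#'   (list with `vaf` true frequencies, `mu_over_beta` implied slope,
#'   `f_min`, `f_max`).
#' @export
simulateNeutralVafs <- function(n_mut = 5000, mu_eff = NULL, f_max = 0.25,
                                f_min = 0.05, depth = 200, subclone = NULL,
                                seed = 1) {
  if (f_max <= 0 || f_max > 0.5) stop("f_max must lie in (0, 0.5]")
  if (f_min <= 0 || f_min >= sqrt(f_max)) stop("f_min out of range")
  if (!is.null(mu_eff) && mu_eff <= 0) stop("mu_eff must be positive")
  set.seed(seed)
  fU <- sqrt(f_max)
  mass <- (1 / f_min - f_min / f_max)      # total M(f_min); M(fU) = 0
  if (is.null(n_mut)) {
    if (is.null(mu_eff)) stop("give n_mut or mu_eff")
    n_mut <- rpois(1, mu_eff * mass)
  }
  if (n_mut == 0 && (is.null(subclone) || subclone$n == 0)) {
    out <- data.frame(alt = integer(0), total = integer(0))
    attr(out, "truth") <- list(vaf = numeric(0), mu_over_beta = 0,
                               f_min = f_min, f_max = f_max)
    return(out)
  }
  u <- runif(n_mut)
  # invert F(v) = (1/f_min - 1/v) + (v - f_min)/f_max = mass * u
  b <- 1 / f_min - f_min / f_max - mass * u
  v <- f_max * (-b + sqrt(b^2 + 4 / f_max)) / 2
  trueVaf <- v
  if (!is.null(subclone)) {
    pur <- if (is.null(subclone$purity)) 1 else subclone$purity
    trueVaf <- c(trueVaf, rep(pur * subclone$ccf / 2, subclone$n))
  }
  total <- rpois(length(trueVaf), depth)
  total[total == 0] <- 1L
  alt <- rbinom(length(trueVaf), total, trueVaf)
  out <- data.frame(alt = as.integer(alt), total = as.integer(total))
  attr(out, "truth") <- list(vaf = trueVaf, mu_over_beta = n_mut / mass,
                             f_min = f_min, f_max = f_max)
  out
}

#' Simulate per-SNP B-allele counts on a shared segment
#'
#' One copy-number segment observed in several samples of one patient.
#' Each heterozygous SNP's B allele lies on haplotype 1 or 2 (the shared
#' `phase_id`); within a sample, the major copy-number haplotype is
#' haplotype 1, unless `mirrored = TRUE`, in which case even-numbered
#' samples favor haplotype 2 — a mirrored subclonal allelic imbalance
#' event. B reads are Binomial around the theoretical BAF given purity and
#' the sample's (n_major, n_minor) state (see [expectedBaf()]).
#'
#' @param n_snps Number of heterozygous SNPs on the segment.
#' @param purity Tumor purity in (0, 1] (shared across samples).
#' @param states List with one `c(n_major, n_minor)` per sample.
#' @param mirrored Plant a mirrored event (haplotype flip in even samples).
#' @param depth Mean read depth per SNP.
#' @param seed Integer seed.
#' @return `list(snps, segments)`: per-SNP BAF records (with `phase_id`
#'   haplotype truth) and per-sample segment records.
#' @export
simulateBafSegments <- function(n_snps = 200, purity = 0.8,
                                states = list(c(2, 1), c(2, 1)),
                                mirrored = FALSE, depth = 120, seed = 1) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  set.seed(seed)
  nS <- length(states)
  sampleIds <- if (!is.null(names(states))) names(states) else
    paste0("S", seq_len(nS))
  pos <- seq_len(n_snps) * 1000L
  bOnHap1 <- runif(n_snps) < 0.5
  snps <- vector("list", nS)
  segs <- vector("list", nS)
  for (i in seq_len(nS)) {
    st <- states[[i]]
    majorHap <- if (mirrored && i %% 2 == 0) 2L else 1L
    bMajor <- (bOnHap1 & majorHap == 1L) | (!bOnHap1 & majorHap == 2L)
    ebaf <- ifelse(bMajor,
                   expectedBaf(purity, st[1], st[2], "major"),
                   expectedBaf(purity, st[1], st[2], "minor"))
    tot <- rpois(n_snps, depth)
    tot[tot == 0] <- 1L
    b <- rbinom(n_snps, tot, ebaf)
    snps[[i]] <- data.frame(
      sample_id = sampleIds[i], chrom = "1", pos = pos,
      a_reads = as.integer(tot - b), b_reads = as.integer(b),
      phase_id = ifelse(bOnHap1, "hap1", "hap2"),
      stringsAsFactors = FALSE)
    segs[[i]] <- data.frame(
      sample_id = sampleIds[i], chrom = "1", start = 1L,
      end = n_snps * 1000L, log_r = log2((st[1] + st[2]) / 2),
      n_major = st[1], n_minor = st[2], stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snps)
  snps$baf <- snps$b_reads / (snps$a_reads + snps$b_reads)
  list(snps = snps, segments = do.call(rbind, segs))
}

#' Build a TCR sharing design with planted clone overlap
#'
#' Convenience constructor for [simulateTcrCohort()]: every sample carries
#' `n_shared` clones common to all samples plus `n_private` clones of its
#' own, for both chains. With `n_private = n_shared` the pairwise Jaccard
#' index is 1/3 by construction.
#'
#' @param samples Character vector of sample ids.
#' @param n_shared,n_private Shared/private clone counts per sample.
#' @param total Total reads per sample and chain.
#' @param alpha Power-law abundance exponent.
#' @return Design list understood by [simulateTcrCohort()].
#' @export
tcrSharingDesign <- function(samples, n_shared = 50, n_private = 50,
                             total = 1e5, alpha = 1.5) {
  design <- list()
  for (chain in c("TRA", "TRB")) {
    shared <- sprintf("%s_shared%03d", chain, seq_len(n_shared))
    membership <- lapply(samples, function(s) {
      c(shared, if (n_private > 0)
        sprintf("%s_%s_priv%03d", chain, s, seq_len(n_private)))
    })
    names(membership) <- samples
    design[[chain]] <- list(membership = membership,
                            total = total, alpha = alpha)
  }
  design
}

#' Simulate a TCR clone table from a sharing design
#'
#' Realizes a cohort of AIRR-style clone records in which clone-identity
#' sharing between samples is exactly the planted design and within-sample
#' abundances follow a power law: the clone of rank r gets a count
#' proportional to r^-alpha (ranks randomly permuted per sample), scaled
#' to the design total, with every planted clone kept at count >= 1.
#'
#' @param design Per-chain design list (see [tcrSharingDesign()]): each
#'   chain entry holds `membership` (named list sample -> clone ids),
#'   `total`, `alpha`.
#' @param seed Integer seed.
#' @return data.frame of TCR clone records (all productive).
#' @export
simulateTcrCohort <- function(design, seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  out <- list()
  for (chain in names(design)) {
    d <- design[[chain]]
    allClones <- unique(unlist(d$membership))
    if (length(allClones) == 0) stop("empty clone pool in design")
    meta <- data.frame(
      clone_id = allClones,
      cdr3_aa = paste0("CAS", vapply(seq_along(allClones), function(i)
        paste(sample(aa, 9, replace = TRUE), collapse = ""), "") , "F"),
      v_gene = sprintf("%sV%d", chain, sample.int(20, length(allClones),
                                                  replace = TRUE)),
      j_gene = sprintf("%sJ%d", chain, sample.int(6, length(allClones),
                                                  replace = TRUE)),
      stringsAsFactors = FALSE)
    # clone identity must be unique: regenerate any colliding CDR3s
    while (anyDuplicated(meta$cdr3_aa)) {
      i <- which(duplicated(meta$cdr3_aa))
      meta$cdr3_aa[i] <- paste0("CAS", vapply(i, function(k)
        paste(sample(aa, 9, replace = TRUE), collapse = ""), ""), "F")
    }
    for (s in names(d$membership)) {
      ids <- d$membership[[s]]
      k <- length(ids)
      ranks <- sample.int(k)
      w <- ranks^(-d$alpha)
      counts <- pmax(1L, as.integer(round(d$total * w / sum(w))))
      m <- meta[match(ids, meta$clone_id), ]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, chain = chain, cdr3_aa = m$cdr3_aa,
        v_gene = m$v_gene, j_gene = m$j_gene, count = counts,
        productive = TRUE, clone_id = ids, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-patient signature-3 activity for BRCA1/2 prediction
#'
#' Draws latent scores z ~ N(0, 1) for BRCA-wild-type patients and
#' z ~ N(`sep`, 1) for BRCA-deficient patients, mapped to (0, 1) through
#' the logistic function (a monotone map, so the AUC is unchanged). The
#' closed-form AUC of this normal-shift model is Phi(sep / sqrt(2)),
#' recorded in the `auc_true` attribute.
#'
#' @param n_pos,n_neg Numbers of BRCA-deficient / wild-type patients.
#' @param sep Mean shift of the deficient group (>= 0).
#' @param seed Integer seed.
#' @return data.frame with `sig3` (activity score in (0,1)) and `brca`
#'   (logical label); attribute `auc_true`.
#' @export
simulateBrcaCohort <- function(n_pos, n_neg, sep, seed = 1) {
  if (n_pos < 1 || n_neg < 1) stop("n_pos and n_neg must be >= 1")
  if (sep < 0) stop("sep must be >= 0")
  set.seed(seed)
  z <- c(rnorm(n_pos, mean = sep), rnorm(n_neg))
  out <- data.frame(sig3 = 1 / (1 + exp(-z)),
                    brca = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
  attr(out, "auc_true") <- pnorm(sep / sqrt(2))
  out
}
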