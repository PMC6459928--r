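#' @include io.R filters.R ccf.R phylogeny.R signatures.R msai.R neutral.R tcr.R
NULL

.pipelineDefaults <- function() {
  list(
    stages = c("filter", "tree", "ccf", "signatures", "msai", "neutral",
               "tcr"),
    vaf_min = 0.02, min_alt = 2,
    snv_t_alt_min = 4, snv_t_cov_min = 14, snv_n_alt_max = 2,
    snv_n_cov_min = 10,
    neutral_window = c(0.12, 0.24), r2_threshold = 0.98,
    msai_alpha = 0.05,
    tcr_downsample = 1e6, tcr_min_per_million = 2,
    seed = 1)
}

#' Run the multi-region analysis pipeline
#'
#' Orchestrates all stages over tabular inputs for one or more patients
#' and writes per-patient outputs plus a machine-readable summary
#' (`summary.json`) and a log of every threshold actually used
#' (`log.txt`) into `outdir`. A stage that fails (or lacks its inputs,
#' e.g. CCF without purity) is logged and skipped together with its
#' downstream dependents only; independent stages still run. Given the
#' same inputs, configuration and seed, outputs are byte-identical
#' across runs.
#'
#' @param config List with input tables (in-memory data.frames
#'   `mutations`, `samples`, and optionally `segments`, `snps`, `tcr` —
#'   or file paths `mutation_table`, `sample_table`, `segment_table`,
#'   `snp_baf_table`, `tcr_table`) and optional overrides of the
#'   defaults: `stages`, `vaf_min`, `min_alt`, SNV filter thresholds,
#'   `neutral_window`, `r2_threshold`, `msai_alpha`, `tcr_downsample`,
#'   `seed`. A character scalar is taken as the path to a JSON config.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(.pipelineDefaults(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  logf <- function(...) logLines <<- c(logLines, sprintf(...))
  set.seed(cfg$seed)
  logf("seed=%d", as.integer(cfg$seed))
  for (k in c("vaf_min", "min_alt", "snv_t_alt_min", "snv_t_cov_min",
              "snv_n_alt_max", "snv_n_cov_min", "r2_threshold",
              "msai_alpha", "tcr_downsample", "tcr_min_per_million")) {
    logf("threshold %s=%s", k, paste(cfg[[k]], collapse = ","))
  }
  logf("threshold neutral_window=%s", paste(cfg$neutral_window,
                                            collapse = ","))

  mutations <- cfg$mutations
  if (is.null(mutations) && !is.null(cfg$mutation_table)) {
    mutations <- readMutationTable(cfg$mutation_table)
  }
  samples <- cfg$samples
  if (is.null(samples) && !is.null(cfg$sample_table)) {
    samples <- readSampleTable(cfg$sample_table)
  }
  segments <- cfg$segments
  if (is.null(segments) && !is.null(cfg$segment_table)) {
    segments <- readSegmentTable(cfg$segment_table)
  }
  snps <- cfg$snps
  if (is.null(snps) && !is.null(cfg$snp_baf_table)) {
    snps <- readSnpBafTable(cfg$snp_baf_table)
  }
  tcr <- cfg$tcr
  if (is.null(tcr) && !is.null(cfg$tcr_table)) {
    tcr <- readTcrTable(cfg$tcr_table)
  }
  if (is.null(samples)) stop("sample metadata is required")

  summary <- list(config = cfg[c("stages", "vaf_min", "min_alt",
                                 "r2_threshold", "msai_alpha", "seed")],
                  patients = list())
  on <- function(stage) stage %in% cfg$stages

  for (pid in unique(samples$patient_id)) {
    psum <- list(patient_id = pid)
    pdir <- file.path(outdir, pid)
    dir.create(pdir, showWarnings = FALSE)
    smeta <- samples[samples$patient_id == pid, ]
    tumorIds <- smeta$sample_id[smeta$sample_type %in%
                                  c("primary_region", "lymph_node_met")]
    normalIds <- smeta$sample_id[smeta$sample_type %in%
                                   c("normal_tissue", "blood")]
    pmut <- if (!is.null(mutations)) {
      mutations[mutations$patient_id == pid, ]
    } else NULL

    filtered <- NULL
    if (on("filter") && !is.null(pmut) && nrow(pmut) > 0) {
      filtered <- tryCatch({
        res <- .filterStage(pmut, tumorIds, normalIds, cfg)
        writeTsv(res$passed, file.path(pdir, "filtered_mutations.tsv"))
        writeTsv(res$rejected, file.path(pdir, "rejected_mutations.tsv"))
        psum$n_mutations_input <- length(unique(pmut$mutation_id))
        psum$n_mutations_passed <- length(unique(res$passed$mutation_id))
        logf("[%s] filter: %d -> %d mutations", pid,
             psum$n_mutations_input, psum$n_mutations_passed)
        res$passed
      }, error = function(e) {
        logf("[%s] filter FAILED: %s", pid, conditionMessage(e))
        NULL
      })
    } else if (!on("filter")) {
      filtered <- pmut
    }

    tree <- NULL
    timing <- NULL
    if (on("tree") && !is.null(filtered) && length(tumorIds) >= 2) {
      tree <- tryCatch({
        pm <- buildPresenceMatrix(filtered, smeta, cfg$vaf_min, cfg$min_alt)
        tr <- inferParsimonyTree(pm, patient = pid)
        writeNewick(tr, file.path(pdir, "tree.nwk"))
        tim <- classifyTiming(tr)
        timing <- tim$labels
        writeTsv(data.frame(mutation_id = names(tim$labels),
                            timing = tim$labels),
                 file.path(pdir, "mutation_timing.tsv"))
        psum$timing <- as.list(tim$summary)
        psum$tree_newick <- ape::write.tree(asPhylo(tr))
        psum$parsimony_score <- parsimonyScore(tr)
        logf("[%s] tree: score=%g, co-optimal=%d", pid,
             parsimonyScore(tr), length(tr@coOptimal))
        tr
      }, error = function(e) {
        logf("[%s] tree FAILED: %s", pid, conditionMessage(e))
        NULL
      })
    }

    ccf <- NULL
    if (on("ccf") && !is.null(filtered)) {
      if (all(is.na(smeta$purity[smeta$sample_id %in% tumorIds]))) {
        logf("[%s] ccf SKIPPED: purity missing", pid)
      } else {
        ccf <- tryCatch({
          cc <- ccfTable(filtered, smeta, segments)
          writeTsv(cc, file.path(pdir, "ccf.tsv"))
          psum$n_subclonal <- sum(cc$clonality == "subclonal")
          psum$n_ccf_rows <- nrow(cc)
          cc
        }, error = function(e) {
          logf("[%s] ccf FAILED: %s", pid, conditionMessage(e))
          NULL
        })
      }
    }

    if (!is.null(tree) && !is.null(ccf)) {
      tryCatch({
        im <- detectIntermixing(tree, ccf)
        writeTsv(im, file.path(pdir, "intermixing.tsv"))
        psum$n_intermixed_flags <- nrow(im)
        if (any(smeta$sample_type == "lymph_node_met")) {
          psum$seeding_pattern <- classifySeeding(tree, smeta)
        }
      }, error = function(e) {
        logf("[%s] intermixing/seeding FAILED: %s", pid,
             conditionMessage(e))
      })
    }

    if (on("signatures") && !is.null(filtered)) {
      tryCatch({
        uniq <- filtered[!duplicated(filtered$mutation_id), ]
        expo <- fitExposures(buildSpectrum(uniq), id = pid)
        writeTsv(data.frame(signature = names(expo@proportions),
                            contribution = unname(expo@contributions),
                            proportion = unname(expo@proportions)),
                 file.path(pdir, "signature_exposures.tsv"))
        psum$dominant_signature <- dominantSignature(expo)
        if (!is.null(timing)) {
          phe <- phaseExposures(filtered, timing)
          writeTsv(phe$table, file.path(pdir, "signature_phases.tsv"))
        }
      }, error = function(e) {
        logf("[%s] signatures FAILED: %s", pid, conditionMessage(e))
      })
    }

    if (on("msai") && !is.null(segments) && !is.null(snps)) {
      tryCatch({
        pseg <- segments[segments$sample_id %in% tumorIds, ]
        psnp <- snps[snps$sample_id %in% tumorIds, ]
        pur <- setNames(smeta$purity, smeta$sample_id)
        if (nrow(pseg) > 0 && nrow(psnp) > 0 && !all(is.na(pur))) {
          ms <- msaiScan(pseg, psnp, pur, cfg$msai_alpha)
          writeTsv(ms, file.path(pdir, "msai.tsv"))
          psum$n_msai_events <- sum(ms$mirrored, na.rm = TRUE)
        } else logf("[%s] msai SKIPPED: missing inputs", pid)
      }, error = function(e) {
        logf("[%s] msai FAILED: %s", pid, conditionMessage(e))
      })
    }

    if (on("neutral") && !is.null(filtered)) {
      tryCatch({
        tdf <- filtered[filtered$sample_id %in% tumorIds, ]
        reads <- data.frame(sample_id = tdf$sample_id,
                            alt = tdf$alt_reads,
                            total = tdf$alt_reads + tdf$ref_reads)
        pur <- setNames(smeta$purity, smeta$sample_id)
        ne <- classifyNeutralCohort(reads, pur, cfg$neutral_window,
                                    r2_threshold = cfg$r2_threshold)
        writeTsv(ne$table, file.path(pdir, "neutral.tsv"))
        psum$fraction_neutral <- ne$fraction_neutral
        psum$n_neutral_eligible <- ne$n_eligible
      }, error = function(e) {
        logf("[%s] neutral FAILED: %s", pid, conditionMessage(e))
      })
    }

    if (on("tcr") && !is.null(tcr)) {
      tryCatch({
        pids <- intersect(unique(tcr$sample_id), smeta$sample_id)
        if (length(pids) > 0) {
          reps <- list()
          mets <- list()
          for (s in pids) {
            reps[[s]] <- list()
            for (ch in intersect(c("TRA", "TRB"),
                                 unique(tcr$chain[tcr$sample_id == s]))) {
              rp <- preprocessRepertoire(tcr, s, ch,
                                         cfg$tcr_downsample,
                                         cfg$tcr_min_per_million,
                                         seed = cfg$seed)
              reps[[s]][[ch]] <- rp
              mets[[length(mets) + 1L]] <- repertoireDiversity(rp)
            }
          }
          writeTsv(do.call(rbind, mets), file.path(pdir, "tcr_metrics.tsv"))
          if (length(pids) >= 2) {
            D <- matrix(0, length(pids), length(pids),
                        dimnames = list(pids, pids))
            for (i in seq_len(length(pids) - 1)) {
              for (j in seq(i + 1, length(pids))) {
                d <- repertoireDistance(reps[[pids[i]]], reps[[pids[j]]])
                D[i, j] <- D[j, i] <- d$distance_overlap
              }
            }
            writeTsv(data.frame(sample_id = rownames(D), D,
                                check.names = FALSE),
                     file.path(pdir, "tcr_distance.tsv"))
            if (length(pids) >= 3) {
              nj <- buildNjTree(D)
              writeNewick(nj, file.path(pdir, "tcr_tree.nwk"))
              psum$tcr_tree_newick <- ape::write.tree(nj)
            }
          }
          psum$n_tcr_samples <- length(pids)
        }
      }, error = function(e) {
        logf("[%s] tcr FAILED: %s", pid, conditionMessage(e))
      })
    }

    summary$patients[[pid]] <- psum
  }

  writeLines(logLines, file.path(outdir, "log.txt"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# per-(mutation, tumor sample) SNV/indel filters against the matched
# normal; a mutation passes when it passes in at least one tumor sample
.filterStage <- function(pmut, tumorIds, normalIds, cfg) {
  if (length(normalIds) == 0) stop("no matched normal sample")
  normal <- pmut[pmut$sample_id == normalIds[1], ]
  nmap <- match(pmut$mutation_id, normal$mutation_id)
  tumor <- pmut[pmut$sample_id %in% tumorIds, ]
  nIdx <- match(tumor$mutation_id, normal$mutation_id)
  isSnv <- tumor$variant_type == "SNV"
  passKey <- character(0)
  rejRows <- list()
  if (any(isSnv)) {
    d <- tumor[isSnv, ]
    fin <- filterSomaticSnvs(data.frame(
      mutation_id = d$mutation_id, sample_id = d$sample_id,
      t_alt = d$alt_reads, t_cov = d$alt_reads + d$ref_reads,
      n_alt = normal$alt_reads[nIdx[isSnv]],
      n_cov = normal$alt_reads[nIdx[isSnv]] +
        normal$ref_reads[nIdx[isSnv]],
      stringsAsFactors = FALSE),
      cfg$snv_t_alt_min, cfg$snv_t_cov_min, cfg$snv_n_alt_max,
      cfg$snv_n_cov_min)
    passKey <- c(passKey, unique(fin$passed$mutation_id))
    rejRows[[1]] <- fin$rejected[, c("mutation_id", "sample_id", "reason")]
  }
  if (any(!isSnv)) {
    d <- tumor[!isSnv, ]
    fin <- filterSomaticIndels(data.frame(
      mutation_id = d$mutation_id, sample_id = d$sample_id,
      alt = d$alt_reads, cov = d$alt_reads + d$ref_reads,
      stringsAsFactors = FALSE))
    passKey <- c(passKey, unique(fin$passed$mutation_id))
    rejRows[[2]] <- fin$rejected[, c("mutation_id", "sample_id", "reason")]
  }
  rejected <- do.call(rbind, rejRows)
  if (is.null(rejected)) {
    rejected <- data.frame(mutation_id = character(0),
                           sample_id = character(0),
                           reason = character(0))
  }
  list(passed = pmut[pmut$mutation_id %in% passKey, ],
       rejected = rejected)
}
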