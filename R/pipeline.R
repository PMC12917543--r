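#' @include cohort.R preprocess.R dics.R parcellation.R stats.R comparison.R io.R
NULL

#' Construct a pipeline run configuration
#'
#' Defaults reproduce the reference study design: the full 256-channel
#' montage as reference plus reductions to 192, 128, 64, 48, 32, 25 and 19
#' channels, the six standard bands, both head-model modes, all three
#' parcellations, 30 clean trials per subject, and theta as the band whose
#' effect-size maps enter the spatial comparisons.
#'
#' @param cohort a \linkS4class{CohortSpec}.
#' @param channelSets descending montage sizes (must include the cohort's
#'   full montage).
#' @param bands list of \linkS4class{BandSpec}.
#' @param headModels character subset of c("individual", "canonical").
#' @param parcellations character subset of c("vertices", "regions", "networks").
#' @param nTrialsSelect clean trials drawn per subject.
#' @param nPerm permutations for the group statistics.
#' @param nRotations spin-test rotations.
#' @param seed integer seed for analysis-stage randomness.
#' @param spinBand band name for the spatial comparisons.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(cohort = cohortSpec(),
                      channelSets = c(256L, 192L, 128L, 64L, 48L, 32L, 25L, 19L),
                      bands = defaultBands(),
                      headModels = c("individual", "canonical"),
                      parcellations = c("vertices", "regions", "networks"),
                      nTrialsSelect = 30L, nPerm = 1000L, nRotations = 1000L,
                      seed = 1L, spinBand = "theta") {
  new("RunConfig", cohort = cohort, channelSets = as.integer(channelSets),
      bands = bands, headModels = headModels, parcellations = parcellations,
      nTrialsSelect = as.integer(nTrialsSelect), nPerm = as.integer(nPerm),
      nRotations = as.integer(nRotations), seed = as.integer(seed),
      spinBand = spinBand)
}

# Observed (non-permutation) group contrast: t and Cohen d per unit.
glmContrast <- function(Y, design) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  X <- design$X
  XtXinv <- solve(crossprod(X))
  fit <- list(X = X, pinv = XtXinv %*% t(X), ci = design$contrastIndex,
              cgg = XtXinv[design$contrastIndex, design$contrastIndex],
              df = nrow(X) - ncol(X))
  tv <- glmTStats(Y, fit)
  n1 <- as.integer(sum(X[, design$contrastIndex] == 1))
  n2 <- as.integer(sum(X[, design$contrastIndex] == 0))
  list(t = tv, d = as.numeric(cohenDFromT(tv, n1, n2)))
}

checkpointed <- function(dir, name, verbose, expr) {
  if (is.null(dir)) return(force(expr))
  path <- file.path(dir, paste0(name, ".rds"))
  if (file.exists(path)) {
    if (verbose) message("  [resume] ", name)
    return(readRDS(path))
  }
  value <- force(expr)
  saveRDS(value, path)
  value
}

# Per-subject source metrics for every (head model, channel set, band):
# global power/connectivity plus vertex maps for the spin band.
subjectMetrics <- function(config, index, channelSubsets, canonicalLF) {
  spec <- config@cohort
  ctx <- cohortContext(spec)
  rec <- simulateSubject(spec, index)
  trials <- preprocessRecording(rec)
  trials <- dropMarkedTrials(trials, rec@marks)
  trials <- selectTrials(trials, config@nTrialsSelect,
                         seed = deriveSeed(config@seed, 5000L + index),
                         subject = rec@id)
  csds <- lapply(config@bands, function(b) computeBandCsd(trials, b))

  indivLF <- if ("individual" %in% config@headModels)
    computeLeadfield(rec@layout, ctx$sourceSpace, rec@geometry) else NULL

  out <- list(covariates = data.frame(subject = rec@id, group = rec@group,
                                      age = rec@age, sex = rec@sex,
                                      site = rec@site),
              global = list(), spinMaps = list())
  for (model in config@headModels) {
    for (set in names(channelSubsets)) {
      labels <- channelSubsets[[set]]
      lf <- if (model == "individual") {
        idx <- match(labels, indivLF@labels)
        averageReference(new("LeadField",
                             gain = indivLF@gain[idx, , drop = FALSE],
                             referenced = FALSE, labels = labels))
      } else canonicalLF[[set]]
      for (b in config@bands) {
        csd <- subsetCsd(csds[[b@name]], labels)
        fl <- computeDicsFilters(csd, lf, 0.05)
        pw <- computeSourcePower(fl, csd, band = b@name, headModel = model,
                                 subject = rec@id)
        cn <- computeSourceConnectivity(fl, csd, band = b@name,
                                        headModel = model, subject = rec@id)
        key <- paste(model, set, b@name, sep = ".")
        out$global[[paste(key, "power", sep = ".")]] <- globalMean(pw)
        out$global[[paste(key, "connectivity", sep = ".")]] <- globalMean(cn$map)
        if (b@name == config@spinBand) {
          out$spinMaps[[paste(key, "power", sep = ".")]] <- pw@values
          out$spinMaps[[paste(key, "connectivity", sep = ".")]] <- cn$map@values
        }
      }
    }
  }
  out
}

#' Run the full simulated study
#'
#' Simulates the cohort, preprocesses every subject, computes DICS source
#' power and imaginary-coherency connectivity for every channel set, head
#' model and band, then produces (i) the global group-contrast table with
#' Cohen d and FDR flags per band across channel sets, (ii) spatial
#' correlations of the spin-band effect-size maps against the full-montage
#' reference across channel densities and parcellations with spin tests,
#' Fisher z and z-difference statistics, and (iii) the individual-versus-
#' canonical head-model comparison. Every stochastic step derives its seed
#' from the configuration, so identical configurations yield identical
#' outputs; with \code{outDir} set, per-stage checkpoints allow resuming a
#' partial run.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param outDir optional output directory for tables and checkpoints.
#' @param verbose print progress messages.
#' @return list with data.frames \code{globalEffects},
#'   \code{densityComparison}, \code{headModelComparison}, plus
#'   \code{covariates}, \code{balance}, \code{truth} and \code{config}.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
  validObject(config)
  spec <- config@cohort
  ckDir <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ckDir <- file.path(outDir, "checkpoints")
    dir.create(ckDir, showWarnings = FALSE)
  }
  ctx <- cohortContext(spec)
  truth <- groundTruth(spec)

  # nested channel subsets from the template layout
  sets <- sort(config@channelSets, decreasing = TRUE)
  channelSubsets <- list()
  lay <- ctx$layout
  for (s in sets) {
    lay <- reduceLayout(lay, s)
    channelSubsets[[as.character(s)]] <- channelLabels(lay)
  }

  canonicalLF <- NULL
  if ("canonical" %in% config@headModels) {
    fullLF <- computeLeadfield(ctx$layout, ctx$sourceSpace, ctx$geometry)
    canonicalLF <- lapply(channelSubsets, function(labels) {
      idx <- match(labels, fullLF@labels)
      averageReference(new("LeadField",
                           gain = fullLF@gain[idx, , drop = FALSE],
                           referenced = FALSE, labels = labels))
    })
  }

  nTot <- spec@nPatients + spec@nControls
  metrics <- checkpointed(ckDir, "subject_metrics", verbose, {
    lapply(seq_len(nTot), function(i) {
      if (verbose) message(sprintf("subject %d/%d", i, nTot))
      subjectMetrics(config, i, channelSubsets, canonicalLF)
    })
  })
  covariates <- do.call(rbind, lapply(metrics, `[[`, "covariates"))
  design <- buildDesign(covariates)
  balance <- balanceTests(covariates)

  bandNames <- vapply(config@bands, function(b) b@name, character(1L))
  setNamesCh <- names(channelSubsets)

  globalEffects <- checkpointed(ckDir, "global_effects", verbose, {
    rows <- list()
    for (model in config@headModels) for (metric in c("connectivity", "power"))
      for (b in bandNames) {
        dd <- pp <- numeric(0L)
        for (set in setNamesCh) {
          key <- paste(model, set, b, metric, sep = ".")
          y <- vapply(metrics, function(m) m$global[[key]], numeric(1L))
          res <- permutationGlm(y, design, nPerm = config@nPerm,
                                seed = deriveSeed(config@seed, 31L))
          dd <- c(dd, res@dMap); pp <- c(pp, res@pFwe)
        }
        fdr <- fdrBH(pp)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, band = b, headModel = model,
          channels = as.integer(setNamesCh), d = dd, p = pp, q = fdr$q,
          significant = fdr$significant)
      }
    do.call(rbind, rows)
  })

  # observed effect-size maps of the spin band, per model/metric/set
  dmaps <- list()
  for (model in config@headModels) for (metric in c("connectivity", "power"))
    for (set in setNamesCh) {
      key <- paste(model, set, config@spinBand, metric, sep = ".")
      Y <- do.call(rbind, lapply(metrics, function(m) m$spinMaps[[key]]))
      dmaps[[key]] <- glmContrast(Y, design)$d
    }
  parcelize <- function(v, scheme) aggregateValues(v, ctx$sourceSpace, scheme)
  # coarse parcellations can produce rank-identical maps (|r| = 1); keep the
  # Fisher transform finite in the report tables
  clampR <- function(r) max(-1 + 1e-12, min(1 - 1e-12, r))

  refSet <- as.character(spec@nChannels)
  densityComparison <- checkpointed(ckDir, "density_comparison", verbose, {
    rows <- list()
    lower <- setdiff(setNamesCh, refSet)
    for (model in config@headModels) for (metric in c("connectivity", "power")) {
      refKey <- paste(model, refSet, config@spinBand, metric, sep = ".")
      sub <- list()
      for (set in lower) {
        key <- paste(model, set, config@spinBand, metric, sep = ".")
        sp <- spinTest(dmaps[[refKey]], dmaps[[key]], ctx$sourceSpace,
                       nRotations = config@nRotations,
                       seed = deriveSeed(config@seed, 57L))
        row <- data.frame(metric = metric, headModel = model,
                          channels = as.integer(set),
                          r_vertices = sp@rObserved,
                          z_vertices = fisherZ(sp@rObserved),
                          p_spin = sp@pSpin)
        for (scheme in intersect(config@parcellations, c("regions", "networks"))) {
          ra <- clampR(spearmanRank(parcelize(dmaps[[refKey]], scheme),
                                    parcelize(dmaps[[key]], scheme)))
          nU <- if (scheme == "regions") spec@nRegions else spec@nNetworks
          cmp <- compareCorrelations(clampR(sp@rObserved), nVertices(ctx$sourceSpace),
                                     ra, nU)
          row[[paste0("r_", scheme)]] <- ra
          row[[paste0("z_", scheme)]] <- fisherZ(ra)
          row[[paste0("p_zdiff_", scheme)]] <- cmp@p
        }
        sub[[set]] <- row
      }
      sub <- do.call(rbind, sub)
      fdr <- fdrBH(sub$p_spin)
      sub$q_spin <- fdr$q
      sub$significant_spin <- fdr$significant
      for (scheme in intersect(config@parcellations, c("regions", "networks"))) {
        fz <- fdrBH(sub[[paste0("p_zdiff_", scheme)]])
        sub[[paste0("q_zdiff_", scheme)]] <- fz$q
        sub[[paste0("sig_zdiff_", scheme)]] <- fz$significant
      }
      rows[[length(rows) + 1L]] <- sub
    }
    do.call(rbind, rows)
  })

  headModelComparison <- NULL
  if (all(c("individual", "canonical") %in% config@headModels)) {
    headModelComparison <- checkpointed(ckDir, "headmodel_comparison", verbose, {
      rows <- list()
      for (metric in c("connectivity", "power")) {
        sub <- list()
        for (set in setNamesCh) {
          ki <- paste("individual", set, config@spinBand, metric, sep = ".")
          kc <- paste("canonical", set, config@spinBand, metric, sep = ".")
          sp <- spinTest(dmaps[[ki]], dmaps[[kc]], ctx$sourceSpace,
                         nRotations = config@nRotations,
                         seed = deriveSeed(config@seed, 58L))
          row <- data.frame(metric = metric, channels = as.integer(set),
                            r_vertices = sp@rObserved,
                            z_vertices = fisherZ(sp@rObserved),
                            p_spin = sp@pSpin)
          for (scheme in intersect(config@parcellations, c("regions", "networks"))) {
            ra <- clampR(spearmanRank(parcelize(dmaps[[ki]], scheme),
                                      parcelize(dmaps[[kc]], scheme)))
            nU <- if (scheme == "regions") spec@nRegions else spec@nNetworks
            cmp <- compareCorrelations(clampR(sp@rObserved), nVertices(ctx$sourceSpace),
                                       ra, nU)
            row[[paste0("r_", scheme)]] <- ra
            row[[paste0("z_", scheme)]] <- fisherZ(ra)
            row[[paste0("p_zdiff_", scheme)]] <- cmp@p
          }
          sub[[set]] <- row
        }
        sub <- do.call(rbind, sub)
        fdr <- fdrBH(sub$p_spin)
        sub$q_spin <- fdr$q
        sub$significant_spin <- fdr$significant
        rows[[length(rows) + 1L]] <- sub
      }
      do.call(rbind, rows)
    })
  }

  results <- list(globalEffects = globalEffects,
                  densityComparison = densityComparison,
                  headModelComparison = headModelComparison,
                  covariates = covariates, balance = balance,
                  dMaps = dmaps, truth = truth, config = config)
  if (!is.null(outDir)) {
    utils::write.table(globalEffects, file.path(outDir, "global_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(densityComparison,
                       file.path(outDir, "density_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(headModelComparison))
      utils::write.table(headModelComparison,
                         file.path(outDir, "headmodel_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(covariates, file.path(outDir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(writeReport(results), file.path(outDir, "report.txt"))
  }
  results
}

#' Render a human-readable pipeline report
#'
#' Per-band global effect sizes with FDR significance stars across channel
#' sets, followed by the spatial-correlation tables.
#'
#' @param results output of \code{\link{runPipeline}}.
#' @return character vector of report lines.
#' @export
writeReport <- function(results) {
  if (is.null(results) || is.null(results$globalEffects) ||
      !nrow(results$globalEffects))
    stop("empty results: nothing to report")
  ge <- results$globalEffects
  out <- c("Group contrast (patients > controls), global source metrics",
           "===========================================================", "")
  for (b in unique(ge$band)) {
    out <- c(out, sprintf("Band %s:", b))
    sub <- ge[ge$band == b, ]
    for (i in seq_len(nrow(sub)))
      out <- c(out, sprintf("  %-13s %-10s %4d ch: d = %6.2f, p = %6.4f, q = %6.4f%s",
                            sub$metric[i], sub$headModel[i], sub$channels[i],
                            sub$d[i], sub$p[i], sub$q[i],
                            ifelse(sub$significant[i], " *", "")))
    out <- c(out, "")
  }
  dc <- results$densityComparison
  if (!is.null(dc) && nrow(dc)) {
    out <- c(out, "Spatial correlation with the full-montage effect-size map",
             "(z-difference tests against parcel resolutions are approximate:",
             " all correlations share the reference map)", "")
    for (i in seq_len(nrow(dc)))
      out <- c(out, sprintf("  %-13s %-10s %4d ch: r = %5.2f (z = %5.2f), p_spin = %6.4f%s",
                            dc$metric[i], dc$headModel[i], dc$channels[i],
                            dc$r_vertices[i], dc$z_vertices[i], dc$p_spin[i],
                            ifelse(dc$significant_spin[i], " *", "")))
    out <- c(out, "")
  }
  hm <- results$headModelComparison
  if (!is.null(hm) && nrow(hm)) {
    out <- c(out, "Individual vs canonical head model (effect-size maps)", "")
    for (i in seq_len(nrow(hm)))
      out <- c(out, sprintf("  %-13s %4d ch: r = %5.2f (z = %5.2f), p_spin = %6.4f%s",
                            hm$metric[i], hm$channels[i], hm$r_vertices[i],
                            hm$z_vertices[i], hm$p_spin[i],
                            ifelse(hm$significant_spin[i], " *", "")))
    out <- c(out, "")
  }
  bal <- results$balance
  out <- c(out, sprintf("Cohort balance: chi2(sex) = %.2f (p = %.2f), F(age) = %.2f (p = %.2f)",
                        bal$chiSquareSex, bal$pSex, bal$Fage, bal$pAge))
  out
}
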