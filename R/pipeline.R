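#' Imaging condition presets for the PINK1 variants
#'
#' Quantitative knobs for the named variants, restricted to what the
#' enrichment and morphology assays support: the R98W-like condition
#' carries mitochondrial enrichment of 2.98 and a fragmented network;
#' the other variants behave like the wild type (enrichment 1, networked
#' morphology). These presets document observed phenotypes, not biological
#' mechanism.
#'
#' @return named list of lists with elements \code{enrichment} and
#'   \code{mitoMode}
#' @export
variantPresets <- function() {
  list(
    WT = list(enrichment = 1.0, mitoMode = "networked"),
    C92F = list(enrichment = 1.0, mitoMode = "networked"),
    R98W = list(enrichment = 2.98, mitoMode = "fragmented"),
    I111S = list(enrichment = 1.0, mitoMode = "networked"))
}

#' Kinetics condition presets
#'
#' Michaelis-Menten parameter pairs for simulated substrate conditions.
#' The \code{R98W} preset encodes a 30-fold catalytic-efficiency gain of
#' the variant peptide over its matched wild-type peptide, realised as a
#' 2.5-fold higher kcat and a 12-fold lower Km; absolute rates are in the
#' slow regime typical of rhomboid-family intramembrane proteases.
#'
#' @return named list with elements \code{wt} and \code{variant}, each a
#'   list(kcat, Km) in min^-1 and micromolar
#' @export
kineticsPresets <- function() {
  list(
    R98W = list(wt = list(kcat = 0.02, Km = 60),
                variant = list(kcat = 0.05, Km = 5)))
}

.writeManifest <- function(outDir, config, seed) {
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    seed = seed,
    config_file = "config.json",
    config_md5 = unname(tools::md5sum(cfgPath)),
    package = "mitopink",
    version = as.character(packageVersion("mitopink")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run a full imaging experiment over named conditions
#'
#' Generates a seeded batch of synthetic cells per condition, quantifies
#' mitochondrial enrichment for every scene, computes network morphology
#' on the pipeline's mitochondrial masks, and compares the condition
#' ratios with a Brown-Forsythe one-way ANOVA. QC-failing scenes are kept
#' in the per-cell table but excluded from summaries and testing.
#'
#' @param conditions named list; each element may override
#'   \code{enrichment} and \code{mitoMode} (see
#'   \code{\link{variantPresets}})
#' @param n cells per condition
#' @param config base \code{\link{sceneConfig}}
#' @param seed master seed
#' @param outDir optional directory for per-cell and summary CSVs plus a
#'   run manifest
#' @param morphology if TRUE (default) compute skeleton morphology per
#'   scene
#' @return list(cells = per-cell data.frame, summary = per-condition
#'   data.frame, anova = htest or NULL when fewer than 2 conditions pass
#'   QC)
#' @export
runImagingExperiment <- function(conditions = variantPresets()[c("WT", "R98W")],
                                 n = 20L, config = sceneConfig(),
                                 seed = 1L, outDir = NULL,
                                 morphology = TRUE) {
  if (!length(conditions) || is.null(names(conditions)))
    stop("configuration error: 'conditions' must be a non-empty named list")
  cellRows <- list()
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    cfg <- config
    ov <- conditions[[ci]]
    if (!is.null(ov$enrichment)) cfg$enrichment <- ov$enrichment
    if (!is.null(ov$mitoMode)) cfg$mitoMode <- ov$mitoMode
    batch <- generateBatch(cfg, n, seed = .deriveSeed(seed, ci * 1000L))
    rows <- lapply(batch, function(p) {
      q <- quantifyScene(p$scene)
      masks <- attr(q, "masks")
      attr(q, "masks") <- NULL
      q$true_enrichment <- trueEnrichment(p$truth)
      if (morphology) {
        st <- if (is.null(masks$mito) || !any(masks$mito))
          data.frame(mean_branch_length = NA_real_,
                     summed_branch_length = NA_real_, footprint = 0,
                     n_branches = 0L, n_individuals = 0L, n_networks = 0L,
                     empty_mask = TRUE)
        else morphologyStats(masks$mito, pixelSize(p$scene))
        q <- cbind(q, st)
      }
      q
    })
    df <- do.call(rbind, rows)
    df$condition <- cname
    cellRows[[ci]] <- df
  }
  cells <- do.call(rbind, cellRows)
  ok <- cells$qc_pass & !is.na(cells$ratio)
  summarise <- function(d) {
    data.frame(n = nrow(d), n_pass = sum(d$qc_pass),
               mean_ratio = mean(d$ratio[d$qc_pass]),
               sd_ratio = sd(d$ratio[d$qc_pass]),
               mean_true = if ("true_enrichment" %in% names(d))
                 mean(d$true_enrichment) else NA_real_,
               mean_branch_length = if ("mean_branch_length" %in% names(d))
                 mean(d$mean_branch_length[d$qc_pass], na.rm = TRUE)
               else NA_real_,
               mean_footprint = if ("footprint" %in% names(d))
                 mean(d$footprint[d$qc_pass], na.rm = TRUE) else NA_real_)
  }
  summary <- do.call(rbind, lapply(split(cells[ok, ], cells$condition[ok]),
                                   summarise))
  summary <- cbind(condition = rownames(summary), summary)
  rownames(summary) <- NULL
  anova <- NULL
  if (length(unique(cells$condition[ok])) >= 2L)
    anova <- brownForsytheAnova(cells$ratio[ok], cells$condition[ok])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells, file.path(outDir, "cells.csv"), row.names = FALSE)
    write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)
    .writeManifest(outDir, list(conditions = conditions, n = n,
                                config = unclass(config)), seed)
  }
  list(cells = cells, summary = summary, anova = anova)
}

#' Run a full kinetics experiment (wild type versus variant substrate)
#'
#' Simulates noiseless progress curves for both substrate conditions under
#' the assay design (3-min sampling over 2.5 h, substrate 0.1-100
#' micromolar, enzyme 0.8 micromolar), runs blank subtraction, full-digest
#' calibration and initial-velocity extraction, then perturbs the
#' velocities of each technical well with multiplicative Gaussian noise at
#' \code{velocityNoise}, averages technical duplicates, fits the
#' Michaelis-Menten model per biological replicate, and summarises kcat,
#' Km and kcat/Km as mean +/- SEM. The catalytic-efficiency ratio is taken
#' between the replicate-mean efficiencies and compared across replicates
#' with a paired t test.
#'
#' @param wt,variant lists with elements \code{kcat} (min^-1) and
#'   \code{Km} (micromolar); defaults to the R98W kinetics preset
#' @param nReplicates biological replicates (default 3)
#' @param nDuplicates technical duplicates per replicate (default 2)
#' @param substrateConcs micromolar
#' @param times minutes
#' @param enzymeConc micromolar
#' @param velocityNoise relative SD of the multiplicative velocity noise
#' @param seed master seed
#' @param outDir optional output directory for the summary CSV + manifest
#' @return list(summary data.frame, efficiencyRatio, pairedT htest or
#'   NULL, fits nested list, replicateEfficiency matrix)
#' @export
runKineticsExperiment <- function(wt = kineticsPresets()$R98W$wt,
                                  variant = kineticsPresets()$R98W$variant,
                                  nReplicates = 3L, nDuplicates = 2L,
                                  substrateConcs = c(0.1, 0.3, 1, 3, 10,
                                                     30, 100),
                                  times = seq(0, 150, by = 3),
                                  enzymeConc = 0.8,
                                  velocityNoise = 0.05, seed = 1L,
                                  outDir = NULL) {
  if (nReplicates < 1L) stop("need at least one replicate")
  conditions <- list(wt = wt, variant = variant)
  base <- lapply(conditions, function(p) {
    key <- paste(p$kcat, p$Km, enzymeConc,
                 paste(substrateConcs, collapse = ","),
                 length(times), max(times), sep = "|")
    if (is.null(.simCache[[key]]))
      .simCache[[key]] <- analyzeCurveSet(simulateProgressCurves(
        kcat = p$kcat, Km = p$Km, enzymeConc = enzymeConc,
        substrateConcs = substrateConcs, times = times,
        noiseSigma = 0, seed = 1L))
    .simCache[[key]]
  })
  fits <- list(); eff <- matrix(NA_real_, nReplicates, 2L,
                                dimnames = list(NULL, names(conditions)))
  kcatM <- eff; kmM <- eff
  .withSeed(.deriveSeed(seed, 77L), {
    for (cn in names(conditions)) {
      v0 <- base[[cn]]$velocities$v
      fits[[cn]] <- vector("list", nReplicates)
      for (r in seq_len(nReplicates)) {
        wells <- replicate(nDuplicates,
                           v0 * (1 + rnorm(length(v0), 0, velocityNoise)))
        vbar <- rowMeans(wells)
        fit <- fitMM(base[[cn]]$velocities$s, vbar, enzymeConc)
        fits[[cn]][[r]] <- fit
        eff[r, cn] <- catalyticEfficiency(fit)
        kcatM[r, cn] <- kcat(fit)
        kmM[r, cn] <- Km(fit)
      }
    }
  })
  sem <- function(x) sd(x) / sqrt(length(x))
  summary <- do.call(rbind, lapply(names(conditions), function(cn)
    data.frame(condition = cn,
               kcat_mean = mean(kcatM[, cn]),
               kcat_sem = if (nReplicates > 1L) sem(kcatM[, cn]) else NA_real_,
               Km_mean = mean(kmM[, cn]),
               Km_sem = if (nReplicates > 1L) sem(kmM[, cn]) else NA_real_,
               efficiency_mean = mean(eff[, cn]),
               efficiency_sem = if (nReplicates > 1L) sem(eff[, cn])
               else NA_real_)))
  if (nReplicates == 1L)
    warning("single replicate: SEM undefined")
  ratio <- mean(eff[, "variant"]) / mean(eff[, "wt"])
  # efficiencies are ratio-scaled, so the replicate comparison is done on
  # the log scale where their noise is symmetric
  ttest <- if (nReplicates >= 2L)
    tryCatch(pairedT(log(eff[, "variant"]), log(eff[, "wt"])),
             error = function(e) NULL) else NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(outDir, "kinetics_summary.csv"),
              row.names = FALSE)
    .writeManifest(outDir, list(wt = wt, variant = variant,
                                nReplicates = nReplicates,
                                nDuplicates = nDuplicates,
                                substrateConcs = substrateConcs,
                                enzymeConc = enzymeConc,
                                velocityNoise = velocityNoise), seed)
  }
  list(summary = summary, efficiencyRatio = ratio, pairedT = ttest,
       fits = fits, replicateEfficiency = eff)
}
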