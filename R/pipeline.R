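## End-to-end orchestration: registration -> segmentation -> geometry ->
## VTA overlap -> paired statistics, for every patient x atlas x method.

.regionIds <- function(bundle, side, cls) {
  tb <- subnucleusData(bundle)
  tb$label[tb$hemisphere == side & tb$class == cls]
}

#' Run the full atlas-comparison and segmentation analysis
#'
#' Executes, for every patient x atlas pair: ICP registration of the atlas
#' hemisphere surface to the patient thalamus surface, ABS and/or DTIBS
#' segmentation, motor/sensory geometry extraction, and VTA-region overlap
#' scoring; then the paired Wilcoxon comparisons with Bonferroni-Holm
#' adjustment across atlases within each analysis family. Optionally also
#' the inter-atlas Dice tables.
#'
#' @param atlases list of AtlasBundles (or a single bundle).
#' @param cohort a cohort from \code{\link{makeCohort}} or a manifest path
#'   from \code{\link{writeCohort}}.
#' @param methods subset of c("ABS", "DTIBS").
#' @param alpha DTIBS tensor shape/orientation weight.
#' @param icpMode ICP mode for atlas-to-patient registration (similarity
#'   by default: atlas and patient thalami differ in size).
#' @param interAtlas compute the inter-atlas Dice tables (rigid ICP).
#' @param outDir optional directory for CSV outputs (dice_whole.csv,
#'   dice_motor.csv, dice_sensory.csv, geometry.csv, overlap.csv,
#'   stats.csv, run.log).
#' @param signifLevel significance threshold applied to Holm-adjusted
#'   p-values.
#' @return list(dice, geometry, overlap, stats, segmentations, log).
#'   Failed patient x atlas cells are recorded in the log and skipped.
#' @export
runPipeline <- function(atlases, cohort, methods = c("ABS", "DTIBS"),
                        alpha = 0.5, icpMode = "similarity",
                        interAtlas = TRUE, outDir = NULL,
                        signifLevel = 0.05) {
  if (is(atlases, "AtlasBundle")) atlases <- list(atlases)
  if (is.character(cohort)) cohort <- loadCohort(cohort)
  methods <- match.arg(methods, c("ABS", "DTIBS"), several.ok = TRUE)
  side <- cohort$side
  logLines <- character()
  note <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }

  dice <- NULL
  if (interAtlas && length(atlases) >= 2L) {
    dice <- interAtlasDice(atlases, side = side, mode = "rigid")
    note("inter-atlas Dice computed for %d atlases", length(atlases))
  }

  geometry <- list()
  overlap <- list()
  segs <- list()
  for (p in cohort$patients) {
    patSurf <- surfacePoints(p$mask)
    for (bundle in atlases) {
      aid <- atlasId(bundle)
      cell <- sprintf("%s x %s", p$id, aid)
      res <- tryCatch({
        hemi <- extractHemisphere(bundle, side)
        # Register the sparse patient surface onto the dense atlas surface
        # (less correspondence quantization), then invert to map atlas ->
        # patient.
        reg <- icpRegister(patSurf, surfacePoints(hemi), mode = icpMode)
        note("%s: ICP rms %.3f mm in %d iterations (converged: %s)",
             cell, reg$rms, reg$iterations, reg$converged)
        atlasToPatient <- invertTransform(reg$transform)
        registered <- transformLabels(hemi, atlasToPatient, p$mask)
        out <- list()
        if ("ABS" %in% methods)
          out$ABS <- absSegment(p$mask, registered, atlasId = aid,
                                provenance = list(transform = atlasToPatient))
        if ("DTIBS" %in% methods) {
          seeds <- atlasSeedStatistics(registered, p$field)
          dt <- dtibsSegment(p$mask, p$field, seeds, alpha = alpha,
                             atlasId = aid)
          if (length(dt$state@emptied))
            note("%s: DTIBS emptied clusters %s", cell,
                 paste(dt$state@emptied, collapse = ","))
          note("%s: DTIBS %d iterations (converged: %s)", cell,
               dt$state@iterations, dt$state@converged)
          out$DTIBS <- dt$segmentation
        }
        out
      }, error = function(e) {
        note("%s: FAILED: %s", cell, conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      segs[[paste(p$id, aid, sep = ".")]] <- res
      for (method in names(res)) {
        seg <- res[[method]]
        for (cls in c("motor", "sensory")) {
          ids <- .regionIds(bundle, side, cls)
          vol <- suppressWarnings(regionVolume(seg, ids))
          cd <- if (vol > 0) centroidDistance(seg, ids, p$mask) else NA_real_
          geometry[[length(geometry) + 1L]] <- data.frame(
            patient_id = p$id, atlas_id = aid, method = method,
            region = cls, volume = vol, centroid_distance = cd)
          regMask <- BinaryMask(
            array(seg@labels@labels %in% ids, dim = dim(p$mask@mask)),
            p$mask@affine)
          for (v in p$vtas) {
            overlap[[length(overlap) + 1L]] <- data.frame(
              patient_id = p$id, atlas_id = aid, method = method,
              region = cls, vta_id = v$id, outcome = v$outcome,
              overlap_percent = vtaOverlap(v$mask, regMask))
          }
        }
      }
    }
  }
  geometry <- if (length(geometry)) do.call(rbind, geometry) else
    data.frame()
  overlap <- if (length(overlap)) do.call(rbind, overlap) else data.frame()

  stats <- .pipelineStats(dice, geometry, overlap, methods, signifLevel,
                          note)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(dice))
      for (m in names(dice))
        utils::write.csv(dice[[m]],
                         file.path(outDir, sprintf("dice_%s.csv", m)))
    utils::write.csv(geometry, file.path(outDir, "geometry.csv"),
                     row.names = FALSE)
    utils::write.csv(overlap, file.path(outDir, "overlap.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(outDir, "stats.csv"),
                     row.names = FALSE)
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  list(dice = dice, geometry = geometry, overlap = overlap, stats = stats,
       segmentations = segs, log = logLines)
}

# Paired comparisons: each analysis family spans the atlases; Holm is
# applied within family (the "six atlas comparisons").
.pipelineStats <- function(dice, geometry, overlap, methods, signifLevel,
                           note) {
  rows <- list()
  addRow <- function(family, atlas, method, comparison, w) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, atlas_id = atlas, method = method,
      comparison = comparison, n = w$n, statistic = w$statistic,
      p_raw = w$p, stringsAsFactors = FALSE)
  }

  if (!is.null(dice)) {
    off <- upper.tri(dice$whole) | lower.tri(dice$whole)
    for (cls in c("motor", "sensory")) {
      w <- wilcoxonSignedRank(dice$whole[off], dice[[cls]][off])
      addRow("interatlas_dice", "all", "none",
             sprintf("whole_vs_%s", cls), w)
    }
  }

  if (nrow(geometry) && all(c("ABS", "DTIBS") %in% methods)) {
    for (cls in c("motor", "sensory")) {
      for (feat in c("volume", "centroid_distance")) {
        fam <- sprintf("geometry_%s_%s", cls, feat)
        for (aid in unique(geometry$atlas_id)) {
          g <- geometry[geometry$atlas_id == aid & geometry$region == cls, ]
          ga <- g[g$method == "ABS", ]
          gd <- g[g$method == "DTIBS", ]
          m <- match(ga$patient_id, gd$patient_id)
          if (!nrow(ga) || anyNA(m)) next
          ok <- stats::complete.cases(ga[[feat]], gd[[feat]][m])
          if (!any(ok)) next
          w <- wilcoxonSignedRank(ga[[feat]][ok], gd[[feat]][m][ok])
          addRow(fam, aid, "ABS_vs_DTIBS", sprintf("%s_%s", cls, feat), w)
        }
      }
    }
  }

  if (nrow(overlap)) {
    for (method in intersect(methods, unique(overlap$method))) {
      for (aid in unique(overlap$atlas_id)) {
        o <- overlap[overlap$method == method & overlap$atlas_id == aid, ]
        ther <- o[o$outcome == "therapeutic", ]
        if (nrow(ther)) {
          tm <- ther[ther$region == "motor", ]
          ts <- ther[ther$region == "sensory", ]
          m <- match(tm$vta_id, ts$vta_id)
          w <- wilcoxonSignedRank(tm$overlap_percent,
                                  ts$overlap_percent[m])
          addRow(sprintf("therapeutic_motor_vs_sensory_%s", method), aid,
                 method, "motor_vs_sensory", w)
        }
        sens <- o[o$region == "sensory", ]
        pr <- tryCatch(buildParesthesiaPairs(sens), error = function(e) {
          note("paresthesia pairing failed for %s/%s: %s", aid, method,
               conditionMessage(e))
          NULL
        })
        if (!is.null(pr) && nrow(pr)) {
          w <- wilcoxonSignedRank(pr$therapeutic, pr$paresthesia)
          addRow(sprintf("paresthesia_vs_therapeutic_sensory_%s", method),
                 aid, method, "therapeutic_vs_paresthesia", w)
        }
      }
    }
  }

  if (!length(rows))
    return(data.frame(family = character(), atlas_id = character(),
                      method = character(), comparison = character(),
                      n = integer(), statistic = numeric(),
                      p_raw = numeric(), p_holm = numeric(),
                      significant = logical()))
  stats <- do.call(rbind, rows)
  stats$p_holm <- NA_real_
  for (fam in unique(stats$family)) {
    sel <- stats$family == fam
    stats$p_holm[sel] <- holmAdjust(stats$p_raw[sel])
  }
  stats$significant <- stats$p_holm < signifLevel
  stats
}
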