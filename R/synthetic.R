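## Synthetic study data: bilateral thalamic atlas phantoms with Voronoi
## subnuclei, patient thalami derived by a known similarity transform plus
## surface noise, region-dependent diffusion tensor fields, ellipsoidal VTA
## masks, and whole cohorts with ground truth.
##
## Geometry: each hemisphere is an "egg" — an ellipsoid whose cross-section
## widens toward the anterior pole (width taper) and whose cross-section
## centre bends dorsally with a quadratic profile (banana bend). The taper
## breaks anterior-posterior flips and the bend breaks the remaining
## 180-degree rotation, so the shape has no nontrivial proper
## self-symmetry and transform recovery by ICP is well posed.

.eggParams <- list(center = 13, offsetYZ = c(0, 0), radii = c(7.7, 11.9, 6.3),
                   widthTaper = 0.25, bendZ = 0.35)

# Inside test for the egg. x is N x 3 world mm, side +-1 (left = -1 in RAS).
.eggInside <- function(x, side = -1, p = .eggParams) {
  u <- (x[, 1] - side * p$center) / p$radii[1]
  v <- (x[, 2] - p$offsetYZ[1]) / p$radii[2]
  w <- (x[, 3] - p$offsetYZ[2]) / p$radii[3]
  g <- 1 + p$widthTaper * v
  (u^2 + (w - p$bendZ * v^2)^2) / pmax(g, 0.05)^2 + v^2 <= 1
}

# Per-atlas shape perturbation: published atlases disagree on the outer
# thalamic boundary as well as on parcellation, so each synthetic atlas
# jitters the egg deterministically from its seed.
.jitterEgg <- function(p = .eggParams) {
  p$radii <- p$radii * (1 + stats::runif(3, -0.08, 0.08))
  p$widthTaper <- p$widthTaper + stats::runif(1, -0.06, 0.06)
  p$bendZ <- p$bendZ + stats::runif(1, -0.08, 0.08)
  p$offsetYZ <- c(stats::runif(1, -0.8, 0.8), stats::runif(1, -0.6, 0.6))
  p
}

#' Generate a bilateral synthetic thalamic atlas
#'
#' Each hemisphere is a tapered ellipsoid ("egg") on a 0.5 mm isotropic
#' grid, partitioned into \code{nSubnuclei} contiguous Voronoi cells from
#' seeded generator points. Motor cells sit anterior-lateral and sensory
#' cells posterior, mimicking the topology of published motor/sensory
#' parcellations. The right hemisphere mirrors the left.
#'
#' @param nSubnuclei cells per hemisphere (>= 2).
#' @param nMotor,nSensory number of motor / sensory cells
#'   (nMotor + nSensory <= nSubnuclei).
#' @param voxelSize mm triple (default 0.5 isotropic).
#' @param seed RNG seed; the construction is deterministic given the seed.
#' @param atlasId identifier stored in the bundle.
#' @param includeGeniculate add two small extra-thalamic "geniculate"
#'   labels (class other) for exercising thalamus isolation.
#' @param shapeJitter perturb the outer egg shape deterministically from
#'   the seed, so different synthetic atlases disagree on the thalamic
#'   boundary (as published atlases do), not only on the parcellation.
#' @return An \linkS4class{AtlasBundle}.
#' @export
makeAtlas <- function(nSubnuclei = 10L, nMotor = 4L, nSensory = 1L,
                      voxelSize = c(0.5, 0.5, 0.5), seed = 1L,
                      atlasId = sprintf("synth%02d", nSubnuclei),
                      includeGeniculate = FALSE, shapeJitter = TRUE) {
  stopifnot(nSubnuclei >= 2L, nMotor + nSensory <= nSubnuclei)
  set.seed(seed)
  p <- if (shapeJitter) .jitterEgg(.eggParams) else .eggParams
  ext <- c(26, 14, 12)                      # world half-extents, mm
  dims <- as.integer(ceiling(2 * ext / voxelSize))
  affine <- rbind(cbind(diag(voxelSize), -ext + voxelSize / 2), c(0, 0, 0, 1))
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  world <- voxelToWorldMat(idx, affine)

  # Generator points in the left egg, Poisson-disk-ish with bounded retries.
  sampleGenerators <- function() {
    dmin <- 0.6 * (prod(p$radii) * 4 / 3 * pi / nSubnuclei)^(1 / 3)
    pts <- matrix(NA_real_, nSubnuclei, 3)
    got <- 0L; tries <- 0L
    while (got < nSubnuclei && tries < 5000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, -p$center - p$radii[1], -p$center + p$radii[1]),
                stats::runif(1, -p$radii[2] * 1.2, p$radii[2] * 1.2),
                stats::runif(1, -p$radii[3] * 1.2, p$radii[3] * 1.2))
      if (!.eggInside(matrix(cand, 1), side = -1, p = p)) next
      if (got > 0L &&
          min(sqrt(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2,
                                 cand)^2))) < dmin) next
      got <- got + 1L
      pts[got, ] <- cand
    }
    if (got < nSubnuclei) stop("could not place generator points")
    pts
  }

  buildHemi <- function(gen, side) {
    inside <- .eggInside(world, side = side, p = p)
    lab <- integer(nrow(world))
    lab[inside] <- .nnIndexCpp(world[inside, , drop = FALSE], gen)$index
    array(as.integer(lab), dim = dims)
  }

  for (attempt in seq_len(20L)) {
    genL <- sampleGenerators()
    labL <- buildHemi(genL, side = -1)
    genR <- genL; genR[, 1] <- -genR[, 1]
    labR <- buildHemi(genR, side = +1)
    okL <- all(seq_len(nSubnuclei) %in% labL)
    okR <- all(seq_len(nSubnuclei) %in% labR)
    if (okL && okR) break
    if (attempt == 20L) stop("Voronoi cells kept collapsing to zero voxels")
  }

  # Functional classes: motor = anterior-lateral generators, sensory = the
  # most posterior of the rest.
  lateral <- (abs(genL[, 1]) - p$center) / p$radii[1]
  scoreM <- genL[, 2] / p$radii[2] + 0.7 * lateral
  motorIds <- order(scoreM, decreasing = TRUE)[seq_len(nMotor)]
  rest <- setdiff(seq_len(nSubnuclei), motorIds)
  sensoryIds <- rest[order(genL[rest, 2])][seq_len(nSensory)]
  cls <- rep("other", nSubnuclei)
  cls[motorIds] <- "motor"
  cls[sensoryIds] <- "sensory"
  nm <- sprintf("sub%02d_%s", seq_len(nSubnuclei), cls)

  if (includeGeniculate) {
    gen2 <- rbind(c(-23, -13, -3), c(-21.5, -13.5, -5))
    gnames <- c("medial_geniculate", "lateral_geniculate")
    for (g in 1:2) {
      for (sgn in c(-1, 1)) {
        ctr <- gen2[g, ]; ctr[1] <- sgn * abs(ctr[1])
        d2 <- rowSums(sweep(world, 2, ctr)^2)
        sel <- d2 <= 1.2^2
        if (sgn < 0) labL[array(sel, dims)] <- nSubnuclei + g
        else labR[array(sel, dims)] <- nSubnuclei + g
      }
    }
    nm <- c(nm, gnames)
    cls <- c(cls, "other", "other")
  }
  nLab <- length(nm)
  tb <- data.frame(
    label = rep(seq_len(nLab), 2L),
    name = rep(nm, 2L),
    class = rep(cls, 2L),
    hemisphere = rep(c("left", "right"), each = nLab),
    stringsAsFactors = FALSE)
  new("AtlasBundle",
      left = LabelVolume(labL, affine), right = LabelVolume(labR, affine),
      table = SubnucleusTable(tb, atlasId = atlasId), atlasId = atlasId)
}

#' Generate a synthetic patient thalamus from an atlas hemisphere
#'
#' The patient thalamus is the atlas hemisphere mapped through a known
#' similarity transform, its surface perturbed by smooth radial noise, and
#' re-voxelized on a 1 x 1 x 2 mm grid (clinical DTI resolution). The
#' returned truth records the transform and the mapped subnucleus labels
#' (a partition of the patient mask).
#'
#' @param atlas an AtlasBundle.
#' @param side hemisphere matching the simulated implant side.
#' @param transform the true SimilarityTransform (scale in [0.7, 1.3]).
#' @param surfaceNoiseSd surface perturbation amplitude in mm (>= 0; 0
#'   reproduces the re-voxelized atlas support exactly).
#' @param seed RNG seed for the surface noise.
#' @param voxelSize patient grid resolution (default c(1, 1, 2) mm).
#' @param grid optional BinaryMask supplying the target grid; an error is
#'   raised if the transformed thalamus does not fit inside it.
#' @return list(mask = BinaryMask, truth = SyntheticTruth).
#' @export
makePatient <- function(atlas, side = "left", transform,
                        surfaceNoiseSd = 0.4, seed = 1L,
                        voxelSize = c(1, 1, 2), grid = NULL) {
  stopifnot(transform@scale >= 0.7, transform@scale <= 1.3,
            surfaceNoiseSd >= 0)
  set.seed(seed)
  hemi <- extractHemisphere(atlas, side)
  mapped <- applyTransform(transform, worldCoordinates(hemi))
  lo <- apply(mapped, 2, min) - 4
  hi <- apply(mapped, 2, max) + 4
  if (is.null(grid)) {
    dims <- as.integer(ceiling((hi - lo) / voxelSize)) + 1L
    affine <- rbind(cbind(diag(voxelSize), lo), c(0, 0, 0, 1))
    grid <- BinaryMask(array(FALSE, dims), affine)
  } else {
    dims <- dim(grid@mask)
    crn <- voxelToWorldMat(rbind(c(1, 1, 1), dims), grid@affine)
    if (any(apply(mapped, 2, min) < pmin(crn[1, ], crn[2, ])) ||
        any(apply(mapped, 2, max) > pmax(crn[1, ], crn[2, ])))
      stop("transform maps the thalamus outside the supplied grid")
  }
  truthLab <- transformLabels(hemi, transform, grid)
  support <- truthLab@labels > 0L
  if (!any(support)) stop("transformed thalamus is empty on the target grid")

  mask <- support
  if (surfaceNoiseSd > 0) {
    supportMask <- BinaryMask(support, truthLab@affine)
    surf <- surfacePoints(supportMask)
    # Outside boundary voxels: complement voxels 6-adjacent to the support.
    outBoundIdx <- which(.dilate6(support) & !support, arr.ind = TRUE)
    outPts <- voxelToWorldMat(outBoundIdx, truthLab@affine)
    idxAll <- which(array(TRUE, dims), arr.ind = TRUE)
    wAll <- voxelToWorldMat(idxAll, truthLab@affine)
    # Signed distance with the zero level set on the in/out interface:
    # inside voxels measure to the nearest outside centre and vice versa.
    dOut <- .nnIndexCpp(wAll, outPts)$distance
    dIn <- .nnIndexCpp(wAll, surf)$distance
    signed <- ifelse(as.vector(support), -dOut, dIn)
    # Smooth noise field: Gaussian kernels anchored on the surface with
    # iid normal coefficients, self-normalized so the pointwise variance
    # is exactly surfaceNoiseSd^2 wherever kernel coverage exists.
    nb <- 24L
    ctr <- surf[sample.int(nrow(surf), min(nb, nrow(surf))), , drop = FALSE]
    amp <- stats::rnorm(nrow(ctr))
    num <- numeric(nrow(wAll))
    den2 <- numeric(nrow(wAll))
    for (b in seq_len(nrow(ctr))) {
      kb <- exp(-rowSums(sweep(wAll, 2, ctr[b, ])^2) / (2 * 16))
      num <- num + amp[b] * kb
      den2 <- den2 + kb^2
    }
    nu <- ifelse(den2 > 1e-12, surfaceNoiseSd * num / sqrt(den2), 0)
    mask <- array(signed <= nu, dims)
    comp <- .ccLabelCpp(as.vector(mask), dims)       # keep largest component
    keep <- which.max(tabulate(comp))
    mask <- array(comp == keep, dims)
  }

  lab <- array(0L, dims)
  inL <- mask & support
  lab[inL] <- truthLab@labels[inL]
  extra <- mask & !support
  if (any(extra)) {
    ref <- which(support, arr.ind = TRUE)
    lab[which(extra, arr.ind = TRUE)] <- .nearestLabelCpp(
      voxelToWorldMat(which(extra, arr.ind = TRUE), truthLab@affine),
      voxelToWorldMat(ref, truthLab@affine),
      as.integer(truthLab@labels[ref]))
  }
  truth <- new("SyntheticTruth", transform = transform,
               labels = LabelVolume(lab, truthLab@affine),
               tensorParams = list(), vtaSpec = list())
  list(mask = BinaryMask(mask, truthLab@affine), truth = truth)
}

#' Default per-subnucleus diffusion tensor parameters
#'
#' Assigns each subnucleus an axially symmetric tensor with a distinct
#' principal direction (spread over the unit hemisphere) and a distinct
#' (mean diffusivity, FA) pair, plus a component noise sd. Defaults give
#' well-separated regions so segmentation recovery is testable; see the
#' methods vignette for the tunable contrast knobs.
#'
#' @param labels integer subnucleus labels to parameterize.
#' @param mdRange mean-diffusivity range (mm^2/s).
#' @param faRange fractional-anisotropy range.
#' @param noiseSd per-component tensor noise sd (mm^2/s).
#' @return named list per label: list(eigenvalues, direction, noiseSd).
#' @export
defaultTensorParams <- function(labels, mdRange = c(0.60e-3, 0.85e-3),
                                faRange = c(0.30, 0.75), noiseSd = 4e-5) {
  K <- length(labels)
  out <- vector("list", K)
  names(out) <- as.character(labels)
  golden <- pi * (3 - sqrt(5))
  for (i in seq_len(K)) {
    z <- (i - 0.5) / K                        # upper hemisphere: dyadic-distinct
    phi <- i * golden
    dirn <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    fr <- if (K > 1) (i - 1) / (K - 1) else 0
    md <- mdRange[1] + fr * diff(mdRange)
    fa <- faRange[1] + fr * diff(faRange)
    delta <- fa * sqrt(3 / (9 - 6 * fa^2))    # axially symmetric tensor
    out[[i]] <- list(eigenvalues = c(md * (1 + 2 * delta),
                                     md * (1 - delta), md * (1 - delta)),
                     direction = dirn, noiseSd = noiseSd)
  }
  out
}

#' Generate a diffusion tensor field from ground-truth labels
#'
#' Every supported voxel receives the tensor R diag(lambda) R' of its true
#' subnucleus (principal axis along the region direction) plus symmetric
#' component noise, then is projected back to SPD by eigenvalue flooring.
#'
#' @param truth a SyntheticTruth whose \code{tensorParams} cover all labels
#'   (see \code{\link{defaultTensorParams}}).
#' @param grid optional BinaryMask support; defaults to the truth labels'
#'   support.
#' @param seed RNG seed.
#' @return A \linkS4class{TensorField}.
#' @export
makeTensorField <- function(truth, grid = NULL, seed = 1L) {
  set.seed(seed)
  lab <- truth@labels
  if (is.null(grid)) grid <- BinaryMask(lab@labels > 0L, lab@affine)
  labs <- labelSet(lab)
  pars <- truth@tensorParams
  missingPars <- setdiff(as.character(labs), names(pars))
  if (length(missingPars))
    stop("tensorParams missing for labels: ",
         paste(missingPars, collapse = ", "))
  dims <- dim(lab@labels)
  comp <- matrix(0, prod(dims), 6L)
  for (l in labs) {
    prm <- pars[[as.character(l)]]
    d <- prm$direction / sqrt(sum(prm$direction^2))
    e <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b2 <- c(d[2] * e[3] - d[3] * e[2], d[3] * e[1] - d[1] * e[3],
            d[1] * e[2] - d[2] * e[1])
    b2 <- b2 / sqrt(sum(b2^2))
    b3 <- c(d[2] * b2[3] - d[3] * b2[2], d[3] * b2[1] - d[1] * b2[3],
            d[1] * b2[2] - d[2] * b2[1])
    B <- cbind(d, b2, b3)
    D0 <- .matToSym6(B %*% (prm$eigenvalues * t(B)))
    sel <- which(lab@labels == l & grid@mask)
    if (!length(sel)) next
    n <- length(sel)
    noise <- if (prm$noiseSd > 0)
      matrix(stats::rnorm(n * 6, sd = prm$noiseSd), n, 6) else 0
    comp[sel, ] <- matrix(D0, n, 6, byrow = TRUE) + noise
  }
  tensorField(array(comp, c(dims, 6L)), lab@affine, support = grid)
}

#' Ellipsoidal VTA mask
#'
#' Marks the voxels whose world coordinates satisfy the ellipsoid
#' inequality sum(((x - center) / radii)^2) <= 1.
#'
#' @param center world-mm triple.
#' @param radii positive mm triple.
#' @param grid BinaryMask supplying the target grid.
#' @return A BinaryMask; empty results are an error.
#' @export
makeVta <- function(center, radii, grid) {
  stopifnot(all(radii > 0))
  dims <- dim(grid@mask)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  w <- voxelToWorldMat(idx, grid@affine)
  inside <- rowSums(sweep(sweep(w, 2, center), 2, radii, `/`)^2) <= 1
  if (!any(inside)) stop("VTA is empty on this grid (center outside bounds?)")
  BinaryMask(array(inside, dims), grid@affine)
}

# 6-connectivity binary dilation by one voxel.
.dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# Random rotation matrix with angle drawn in [minDeg, maxDeg].
.randomRotation <- function(minDeg = 5, maxDeg = 20) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, minDeg, maxDeg) * pi / 180
  Kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

#' Generate a synthetic patient cohort with ground truth
#'
#' Each patient gets a thalamus mask (atlas hemisphere through a random
#' similarity transform plus surface noise), a diffusion tensor field,
#' one therapeutic VTA centred in the true motor region, and 0-4
#' paresthesia VTAs displaced toward the true sensory region. The mix
#' mirrors the clinical cohort the analysis emulates: about 12/22 of
#' patients have paresthesia VTAs, 2-4 each.
#'
#' @param nPatients cohort size (>= 1).
#' @param atlas generating AtlasBundle.
#' @param seed master RNG seed; the cohort is deterministic given it.
#' @param side implant hemisphere.
#' @param surfaceNoiseSd patient surface noise (mm).
#' @param paresthesiaProb probability a patient has paresthesia VTAs.
#' @param paresthesiaFraction fractional displacement of paresthesia VTA
#'   centres along the motor-to-sensory centroid axis.
#' @param vtaRadii nominal VTA radii (mm).
#' @param dir optional output directory; when given, all volumes are
#'   written as NIfTI, truth as JSON, and a manifest JSON listing every
#'   path is written (byte-identical across runs with the same seed).
#' @return a cohort list (class "thalasegCohort") with elements atlasId,
#'   side, seed, patients; when \code{dir} is given also
#'   \code{manifestPath}.
#' @export
makeCohort <- function(nPatients, atlas, seed = 1L, side = "left",
                       surfaceNoiseSd = 0.4, paresthesiaProb = 12 / 22,
                       paresthesiaFraction = 0.7,
                       vtaRadii = c(2.5, 2.5, 2.5), dir = NULL) {
  stopifnot(nPatients >= 1L)
  set.seed(seed)
  tb <- subnucleusData(atlas)
  tb <- tb[tb$hemisphere == side, ]
  motorIds <- tb$label[tb$class == "motor"]
  sensoryIds <- tb$label[tb$class == "sensory"]
  patients <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    tf <- similarityTransform(.randomRotation(5, 20),
                              stats::runif(3, -5, 5),
                              stats::runif(1, 0.9, 1.1))
    pseed <- sample.int(2^30, 1)
    pat <- makePatient(atlas, side = side, transform = tf,
                       surfaceNoiseSd = surfaceNoiseSd, seed = pseed)
    truth <- pat$truth
    truth@tensorParams <- defaultTensorParams(labelSet(truth@labels))
    field <- makeTensorField(truth, grid = pat$mask,
                             seed = sample.int(2^30, 1))
    labArr <- truth@labels@labels
    regionCentroid <- function(ids) {
      sel <- which(array(labArr %in% ids, dim = dim(labArr)), arr.ind = TRUE)
      colMeans(voxelToWorldMat(sel, truth@labels@affine))
    }
    mC <- regionCentroid(motorIds)
    sC <- regionCentroid(sensoryIds)
    grid <- pat$mask
    insideMotor <- function(ctr) {
      v <- round(worldToVoxelMat(matrix(ctr, 1), grid@affine))
      d <- dim(labArr)
      all(v >= 1) && all(v <= d) && labArr[v[1], v[2], v[3]] %in% motorIds
    }
    vtas <- list()
    for (try in 1:50) {                      # therapeutic: inside true motor
      ctr <- mC + stats::rnorm(3, sd = 0.5)
      if (insideMotor(ctr)) break
      if (try == 50) ctr <- mC
    }
    rad <- vtaRadii * stats::runif(1, 0.9, 1.1)
    vtas[[1]] <- list(id = sprintf("P%02d_T1", i), outcome = "therapeutic",
                      center = ctr, radii = rad,
                      mask = makeVta(ctr, rad, grid))
    if (stats::runif(1) < paresthesiaProb) {
      np <- sample(2:4, 1)
      for (v in seq_len(np)) {
        ctr <- mC + paresthesiaFraction * (sC - mC) + stats::rnorm(3, sd = 1)
        rad <- vtaRadii * stats::runif(1, 0.9, 1.1)
        vtas[[length(vtas) + 1L]] <- list(
          id = sprintf("P%02d_S%d", i, v), outcome = "paresthesia",
          center = ctr, radii = rad, mask = makeVta(ctr, rad, grid))
      }
    }
    truth@vtaSpec <- lapply(vtas, function(v)
      v[c("id", "outcome", "center", "radii")])
    patients[[i]] <- list(id = sprintf("P%02d", i), mask = pat$mask,
                          field = field, truth = truth, vtas = vtas)
  }
  cohort <- structure(list(atlasId = atlasId(atlas), side = side,
                           seed = seed, patients = patients),
                      class = c("thalasegCohort", "list"))
  if (!is.null(dir)) cohort$manifestPath <- writeCohort(cohort, dir)
  cohort
}

#' Write a cohort to disk (NIfTI volumes + truth and manifest JSON)
#'
#' @param cohort a cohort from \code{\link{makeCohort}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(atlas_id = cohort$atlasId, side = cohort$side,
                   seed = cohort$seed, patients = list())
  for (p in cohort$patients) {
    dir.create(file.path(dir, p$id), showWarnings = FALSE)
    # manifest paths are relative to the manifest directory, so cohorts are
    # relocatable and manifests byte-identical across runs
    maskPath <- file.path(p$id, "thalamus_mask.nii.gz")
    writeVolume(p$mask, file.path(dir, maskPath))
    tensPath <- file.path(p$id, "tensors.nii.gz")
    writeTensorField(p$field, file.path(dir, tensPath))
    labPath <- file.path(p$id, "truth_labels.nii.gz")
    writeVolume(p$truth@labels, file.path(dir, labPath))
    vtaEntries <- list()
    for (v in p$vtas) {
      vp <- file.path(p$id, paste0(v$id, ".nii.gz"))
      writeVolume(v$mask, file.path(dir, vp))
      vtaEntries[[length(vtaEntries) + 1L]] <- list(
        id = v$id, outcome = v$outcome, path = vp,
        center = v$center, radii = v$radii)
    }
    tf <- p$truth@transform
    manifest$patients[[length(manifest$patients) + 1L]] <- list(
      id = p$id, mask = maskPath, tensors = tensPath,
      truth_labels = labPath,
      transform = list(rotation = as.vector(tf@rotation),
                       translation = tf@translation, scale = tf@scale),
      vtas = vtaEntries)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Load a cohort written by \code{\link{writeCohort}}
#'
#' @param manifestPath path to manifest.json.
#' @return a cohort list (class "thalasegCohort"). Tensor parameters are
#'   not restored (they are generator internals, not analysis inputs).
#' @export
loadCohort <- function(manifestPath) {
  m <- jsonlite::read_json(manifestPath, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(manifestPath))
  patients <- lapply(m$patients, function(p) {
    p$mask <- file.path(base, p$mask)
    p$tensors <- file.path(base, p$tensors)
    p$truth_labels <- file.path(base, p$truth_labels)
    p$vtas <- lapply(p$vtas, function(v) {
      v$path <- file.path(base, v$path); v
    })
    tf <- similarityTransform(matrix(unlist(p$transform$rotation), 3, 3),
                              unlist(p$transform$translation),
                              p$transform$scale)
    truth <- new("SyntheticTruth", transform = tf,
                 labels = readLabelVolume(p$truth_labels),
                 tensorParams = list(),
                 vtaSpec = lapply(p$vtas, function(v)
                   v[c("id", "outcome", "center", "radii")]))
    list(id = p$id, mask = readBinaryMask(p$mask),
         field = readTensorField(p$tensors), truth = truth,
         vtas = lapply(p$vtas, function(v)
           list(id = v$id, outcome = v$outcome,
                center = unlist(v$center), radii = unlist(v$radii),
                mask = readBinaryMask(v$path))))
  })
  structure(list(atlasId = m$atlas_id, side = m$side, seed = m$seed,
                 patients = patients, manifestPath = manifestPath),
            class = c("thalasegCohort", "list"))
}
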