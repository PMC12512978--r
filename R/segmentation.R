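## Patient thalamus segmentation: prescriptive atlas labelling (ABS) and
## seeded k-means over spatial + diffusion-tensor features (DTIBS), plus the
## seed-perturbation sensitivity analysis.

#' Atlas-based segmentation (ABS)
#'
#' Patient thalamic voxels are categorized by the subnucleus they reside in;
#' voxels inside the patient mask but outside every subnucleus receive the
#' label of the nearest labelled voxel (Euclidean distance in world mm,
#' ties broken toward the lowest label id).
#'
#' @param patient BinaryMask of the patient thalamus.
#' @param registeredAtlas LabelVolume already resampled on the patient grid
#'   (see \code{\link{transformLabels}}).
#' @param atlasId identifier recorded in the result.
#' @param provenance optional provenance list.
#' @return A \linkS4class{Segmentation} covering the patient mask exactly.
#' @export
absSegment <- function(patient, registeredAtlas, atlasId = "atlas",
                       provenance = list()) {
  if (!all(dim(patient@mask) == dim(registeredAtlas@labels)))
    stop("registered atlas must be resampled on the patient grid")
  labs <- registeredAtlas@labels
  out <- array(0L, dim = dim(labs))
  inMask <- patient@mask
  out[inMask] <- labs[inMask]
  unfilled <- inMask & out == 0L
  if (any(unfilled)) {
    labelled <- which(labs > 0L, arr.ind = TRUE)
    if (!nrow(labelled))
      stop("registered atlas carries no labels on the patient grid")
    refW <- voxelToWorldMat(labelled, patient@affine)
    refLab <- labs[labelled]
    qIdx <- which(unfilled, arr.ind = TRUE)
    qW <- voxelToWorldMat(qIdx, patient@affine)
    out[qIdx] <- .nearestLabelCpp(qW, refW, as.integer(refLab))
  }
  new("Segmentation", labels = LabelVolume(out, patient@affine),
      method = "ABS", atlasId = atlasId, provenance = provenance)
}

#' Subnucleus centroids of a registered atlas
#'
#' One centroid per subnucleus, computed by averaging the world coordinates
#' of all its voxels. These centroids serve as the k-means seed points for
#' DTIBS, so k equals the subnucleus count of the atlas.
#'
#' @param registeredAtlas a LabelVolume.
#' @return K x 3 matrix of world-mm centroids with a \code{labels}
#'   attribute mapping rows to subnucleus label ids. Subnuclei that lost
#'   all voxels in registration are excluded with a warning.
#' @export
seedCentroids <- function(registeredAtlas) {
  labs <- labelSet(registeredAtlas)
  if (!length(labs)) stop("atlas has no labels")
  idx <- which(registeredAtlas@labels > 0L, arr.ind = TRUE)
  w <- voxelToWorldMat(idx, registeredAtlas@affine)
  lab <- registeredAtlas@labels[idx]
  cen <- t(vapply(labs, function(l) colMeans(w[lab == l, , drop = FALSE]),
                  numeric(3)))
  structure(cen, labels = labs)
}

#' Rotation-invariant shape features of a diffusion tensor
#'
#' Returns the feature triple (trace, fractional anisotropy, tensor mode)
#' describing the shape of the tensor independently of its orientation.
#' Trace is the sum of eigenvalues (mm^2/s); FA in [0, 1] measures
#' eigenvalue dispersion; mode in [-1, 1] distinguishes linear (+1) from
#' planar (-1) anisotropy. For the zero tensor FA and mode are defined
#' as 0.
#'
#' @param D symmetric 3x3 matrix (or its 6-component vector
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return numeric triple c(trace, fa, mode).
#' @export
tensorShapeInvariants <- function(D) {
  if (!is.matrix(D)) D <- .sym6ToMat(D)
  tr <- sum(diag(D))
  A <- D - diag(tr / 3, 3)              # deviatoric part
  na <- sqrt(sum(A^2))
  nd <- sqrt(sum(D^2))
  fa <- if (nd < 1e-300) 0 else sqrt(1.5) * na / nd
  # a deviatoric part at floating-point noise level has no meaningful mode
  mode <- if (na < 1e-9 * max(nd, 1e-300)) 0 else 3 * sqrt(6) * det(A / na)
  c(trace = tr, fa = min(fa, 1), mode = max(-1, min(1, mode)))
}

#' Orientation dyadic of a diffusion tensor
#'
#' The dyadic U = e1 e1' of the unit principal eigenvector e1. U is
#' invariant to the sign of e1 and has unit Frobenius norm, so the
#' Frobenius distance between dyadics compares primary diffusion
#' orientations without the eigenvector sign ambiguity.
#'
#' @param D symmetric 3x3 matrix (or its 6-component vector).
#' @param degenerateTol gap below which the leading eigenvalue is flagged
#'   as degenerate.
#' @return 3x3 matrix with attribute \code{degenerate} (logical).
#' @export
orientationDyadic <- function(D, degenerateTol = 1e-12) {
  if (!is.matrix(D)) D <- .sym6ToMat(D)
  e <- eigen(D, symmetric = TRUE)
  e1 <- e$vectors[, 1]
  structure(tcrossprod(e1), degenerate = (e$values[1] - e$values[2]) < degenerateTol)
}

# Per-voxel DTIBS features on the field support: coordinates, shape
# invariants and orientation dyadics (6 components).
.voxelFeatures <- function(field, maskIdx) {
  w <- voxelToWorldMat(maskIdx, field@affine)
  flat <- matrix(field@tensors, ncol = 6L)
  lin <- maskIdx[, 1] +
    dim(field@tensors)[1] * ((maskIdx[, 2] - 1) +
    dim(field@tensors)[2] * (maskIdx[, 3] - 1))
  comp <- flat[lin, , drop = FALSE]
  n <- nrow(comp)
  feats <- matrix(0, n, 3)
  dyads <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    D <- .sym6ToMat(comp[i, ])
    feats[i, ] <- tensorShapeInvariants(D)
    dyads[i, ] <- .matToSym6(orientationDyadic(D))
  }
  list(coords = w, feats = feats, dyads = dyads, comp = comp)
}

# Robust per-feature scales (median absolute deviation over the patient's
# thalamic voxels); zero scales fall back to 1 so constant features drop
# out of the distance without dividing by zero.
.featureScales <- function(feats, scaling) {
  if (is.numeric(scaling)) return(scaling)
  if (identical(scaling, "none")) return(c(1, 1, 1))
  s <- apply(feats, 2, stats::mad)
  s[!is.finite(s) | s <= 0] <- 1
  s
}

# Regularize a spatial covariance: W + eps*I with eps = 1e-4 tr(W)/3
# (floor 1e-6 mm^2), then invert.
.regularizedInverse <- function(W) {
  eps <- max(1e-4 * sum(diag(W)) / 3, 1e-6)
  solve(W + diag(eps, 3))
}

# Ridged determinant, for the covariance volume cap below.
.ridgedDet <- function(W) {
  eps <- max(1e-4 * sum(diag(W)) / 3, 1e-6)
  det(W + diag(eps, 3))
}

#' Seed statistics from a registered atlas under the patient tensor field
#'
#' Computes, per subnucleus of the registered atlas, the seed centroid, the
#' spatial covariance of its voxel coordinates, and the mean diffusion
#' tensor over its voxels under the patient field. These are the natural
#' iteration-0 statistics for \code{\link{dtibsSegment}} since the seeds
#' are the atlas subnuclei centroids.
#'
#' @param registeredAtlas LabelVolume on the patient grid.
#' @param field TensorField on the patient grid.
#' @param minVoxels clusters smaller than this use the pooled covariance.
#' @return list(centroids, labels, covariances, meanTensors).
#' @export
atlasSeedStatistics <- function(registeredAtlas, field, minVoxels = 10L) {
  labs <- labelSet(registeredAtlas)
  if (!length(labs)) stop("registered atlas has no labels")
  supp <- field@support@mask
  keep <- registeredAtlas@labels > 0L & supp
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx))
    stop("no overlap between registered atlas and tensor-field support")
  w <- voxelToWorldMat(idx, registeredAtlas@affine)
  lab <- registeredAtlas@labels[idx]
  flat <- matrix(field@tensors, ncol = 6L)
  lin <- idx[, 1] + dim(supp)[1] * ((idx[, 2] - 1) + dim(supp)[2] * (idx[, 3] - 1))
  comp <- flat[lin, , drop = FALSE]
  present <- labs[labs %in% unique(lab)]
  dropped <- setdiff(labs, present)
  if (length(dropped))
    warning("subnuclei with no voxels excluded from seeding: ",
            paste(dropped, collapse = ", "))
  K <- length(present)
  cen <- matrix(0, K, 3)
  covs <- array(0, c(3, 3, K))
  mt <- matrix(0, K, 6)
  ns <- integer(K)
  for (k in seq_len(K)) {
    sel <- lab == present[k]
    ns[k] <- sum(sel)
    cen[k, ] <- colMeans(w[sel, , drop = FALSE])
    covs[, , k] <- if (ns[k] > 1) stats::cov(w[sel, , drop = FALSE]) else diag(0, 3)
    mt[k, ] <- colMeans(comp[sel, , drop = FALSE])
  }
  big <- ns >= minVoxels
  pooled <- if (any(big)) {
    Reduce(`+`, lapply(which(big), function(k) (ns[k] - 1) * covs[, , k])) /
      sum(ns[big] - 1)
  } else stats::cov(w)
  for (k in which(!big)) covs[, , k] <- pooled
  list(centroids = cen, labels = present, covariances = covs,
       meanTensors = mt)
}

#' DTIBS distance between a voxel and a cluster
#'
#' The distance is a linear combination of the Mahalanobis voxel distance
#' and a hybrid tensor distance:
#' \deqn{d = \|x - \bar x_k\|_{W_k} + \alpha \|K(D) - K(\bar D_k)\| +
#'   (1 - \alpha) \|U(D) - U(\bar D_k)\|_F}
#' where the Mahalanobis norm uses the cluster's (regularized) spatial
#' covariance, K is the shape-invariant triple (optionally standardized by
#' \code{featureScales}), and U the orientation dyadic.
#'
#' @param x world-mm voxel coordinate (length 3).
#' @param D voxel diffusion tensor (3x3 or 6-vector).
#' @param centroid cluster centroid (length 3).
#' @param covariance cluster spatial covariance (3x3, SPD after
#'   regularization).
#' @param meanTensor cluster mean diffusion tensor (3x3 or 6-vector).
#' @param alpha shape-vs-orientation weight in [0, 1].
#' @param featureScales per-feature divisors for the shape features
#'   (default no scaling).
#' @return non-negative scalar distance.
#' @export
dtibsDistance <- function(x, D, centroid, covariance, meanTensor,
                          alpha = 0.5, featureScales = c(1, 1, 1)) {
  stopifnot(alpha >= 0, alpha <= 1)
  Winv <- .regularizedInverse(covariance)
  dx <- as.numeric(x) - as.numeric(centroid)
  m <- sqrt(max(0, sum(dx * (Winv %*% dx))))
  f <- (tensorShapeInvariants(D) - tensorShapeInvariants(meanTensor)) /
    featureScales
  Ud <- orientationDyadic(D) - orientationDyadic(meanTensor)
  m + alpha * sqrt(sum(f^2)) + (1 - alpha) * sqrt(sum(Ud^2))
}

#' DTI-based segmentation (DTIBS)
#'
#' Seeded k-means over the patient's thalamic voxels using the combined
#' spatial-Mahalanobis + tensor-shape/orientation distance (see
#' \code{\link{dtibsDistance}}). Each iteration assigns every voxel to its
#' nearest cluster and recomputes centroids, spatial covariances and mean
#' tensors; iteration stops when every centroid moves less than
#' \code{convTol} mm or after \code{maxIter} iterations. Clusters that
#' empty are frozen at their last nonempty statistics.
#'
#' @param patient BinaryMask of the patient thalamus.
#' @param field TensorField covering the patient mask.
#' @param seeds either a K x 3 centroid matrix (optionally with a
#'   \code{labels} attribute) or the list returned by
#'   \code{\link{atlasSeedStatistics}}. With a plain centroid matrix,
#'   iteration-0 covariances are identity and mean tensors are taken from
#'   the field at the voxel nearest each seed.
#' @param alpha tensor shape-vs-orientation weight (default 0.5).
#' @param convTol centroid-movement convergence criterion in mm
#'   (default 0.1).
#' @param maxIter iteration cap.
#' @param featureScaling "mad" (standardize shape features by their median
#'   absolute deviation over the thalamic voxels), "none", or a numeric
#'   triple of divisors.
#' @param tensorMean "euclidean" (arithmetic component mean) or
#'   "logEuclidean".
#' @param atlasId identifier recorded in the result.
#' @return list with \code{segmentation} (a Segmentation whose labels are
#'   the seed subnucleus labels) and \code{state} (a ClusterState).
#' @export
dtibsSegment <- function(patient, field, seeds, alpha = 0.5, convTol = 0.1,
                         maxIter = 100L, featureScaling = "mad",
                         tensorMean = c("euclidean", "logEuclidean"),
                         atlasId = "atlas") {
  tensorMean <- match.arg(tensorMean)
  stopifnot(alpha >= 0, alpha <= 1)
  maskIdx <- which(patient@mask & field@support@mask, arr.ind = TRUE)
  if (!nrow(maskIdx)) stop("patient mask has no supported voxels")
  fv <- .voxelFeatures(field, maskIdx)
  scales <- .featureScales(fv$feats, featureScaling)
  featsS <- sweep(fv$feats, 2, scales, `/`)

  if (is.list(seeds)) {
    cen <- seeds$centroids
    labs <- seeds$labels
    covs <- seeds$covariances
    mt <- seeds$meanTensors
  } else {
    cen <- as.matrix(seeds)
    labs <- attr(seeds, "labels") %||% seq_len(nrow(cen))
    K0 <- nrow(cen)
    covs <- array(rep(diag(3), K0), c(3, 3, K0))
    nn <- .nnIndexCpp(cen, fv$coords)$index
    mt <- fv$comp[nn, , drop = FALSE]
  }
  K <- nrow(cen)
  if (K < 1L) stop("need at least one seed")
  if (K == 1L) warning("single-cluster segmentation is degenerate")

  clusterFeatures <- function(mt) {
    cf <- matrix(0, K, 3); cu <- matrix(0, K, 6)
    for (k in seq_len(K)) {
      cf[k, ] <- tensorShapeInvariants(mt[k, ]) / scales
      cu[k, ] <- .matToSym6(orientationDyadic(mt[k, ]))
    }
    list(cf = cf, cu = cu)
  }
  invCovs <- function(covs) {
    w <- array(0, c(3, 3, K))
    for (k in seq_len(K)) w[, , k] <- .regularizedInverse(covs[, , k])
    w
  }
  # Covariance volume cap: per-cluster Mahalanobis k-means has a runaway
  # mode where one cluster's growing covariance shrinks its normalized
  # distances until it swallows the thalamus. Updates keep their shape but
  # their determinant is capped at 25x the geometric-mean initial cluster
  # determinant; the cap only engages in runaway.
  capDet <- 25 * exp(mean(log(vapply(seq_len(K), function(k)
    .ridgedDet(covs[, , k]), numeric(1)))))
  capCov <- function(W) {
    d <- .ridgedDet(W)
    if (d > capDet) W * (capDet / d)^(1 / 3) else W
  }
  meanTensor <- function(rows) {
    if (tensorMean == "euclidean") return(colMeans(rows))
    logs <- t(apply(rows, 1, function(v) {
      e <- eigen(.sym6ToMat(v), symmetric = TRUE)
      .matToSym6(e$vectors %*% (log(pmax(e$values, 1e-12)) * t(e$vectors)))
    }))
    e <- eigen(.sym6ToMat(colMeans(logs)), symmetric = TRUE)
    .matToSym6(e$vectors %*% (exp(e$values) * t(e$vectors)))
  }

  emptied <- integer()
  converged <- FALSE
  iter <- 0L
  assign <- integer(nrow(maskIdx))
  repeat {
    iter <- iter + 1L
    cf <- clusterFeatures(mt)
    res <- .dtibsAssignCpp(fv$coords, featsS, fv$dyads, cen, invCovs(covs),
                           cf$cf, cf$cu, alpha)
    assign <- as.integer(res$assign)
    newCen <- cen
    for (k in seq_len(K)) {
      sel <- assign == k
      n <- sum(sel)
      if (n == 0L) {
        emptied <- union(emptied, k)  # frozen at last nonempty state
        next
      }
      pts <- fv$coords[sel, , drop = FALSE]
      newCen[k, ] <- colMeans(pts)
      covs[, , k] <- if (n > 1) capCov(stats::cov(pts)) else diag(0, 3)
      mt[k, ] <- meanTensor(fv$comp[sel, , drop = FALSE])
    }
    movement <- sqrt(max(rowSums((newCen - cen)^2)))
    cen <- newCen
    if (movement < convTol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  if (length(unique(assign)) == 1L && K > 1L)
    warning("all voxels assigned to a single cluster")

  labOut <- array(0L, dim = dim(patient@mask))
  labOut[maskIdx] <- as.integer(labs[assign])
  state <- new("ClusterState", centroids = cen, covariances = covs,
               meanTensors = mt, assignments = assign,
               labels = as.integer(labs), iterations = iter,
               converged = converged, emptied = as.integer(sort(emptied)))
  seg <- new("Segmentation",
             labels = LabelVolume(labOut, patient@affine),
             method = "DTIBS", atlasId = atlasId,
             provenance = list(alpha = alpha, convTol = convTol,
                               featureScales = scales,
                               iterations = iter, converged = converged))
  list(segmentation = seg, state = state)
}

#' Seed-perturbation sensitivity of DTIBS
#'
#' Repeats the DTIBS segmentation \code{nRuns} times, each time displacing
#' every seed centroid independently and uniformly within a ball of
#' \code{radius} mm, and summarizes stability as (i) the per-voxel modal
#' assignment agreement and (ii) the distribution of pairwise adjusted
#' Rand indices between runs.
#'
#' @param patient BinaryMask of the patient thalamus.
#' @param field TensorField.
#' @param seeds seeds as in \code{\link{dtibsSegment}}.
#' @param nRuns number of perturbed segmentations (>= 2).
#' @param radius displacement radius in mm.
#' @param seed RNG seed for the displacements.
#' @param ... further arguments passed to \code{\link{dtibsSegment}}.
#' @return list(modalAgreement, meanModalAgreement, ariPairwise, meanAri,
#'   assignments).
#' @export
seedSensitivity <- function(patient, field, seeds, nRuns = 100L, radius = 2,
                            seed = 1L, ...) {
  if (nRuns < 2L) stop("nRuns must be >= 2")
  set.seed(seed)
  baseCen <- if (is.list(seeds)) seeds$centroids else as.matrix(seeds)
  K <- nrow(baseCen)
  runs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    disp <- matrix(0, K, 3)
    if (radius > 0) {
      for (k in seq_len(K)) {
        repeat {                       # uniform in the solid ball
          u <- stats::runif(3, -radius, radius)
          if (sum(u^2) <= radius^2) break
        }
        disp[k, ] <- u
      }
    }
    s <- if (is.list(seeds)) {
      m <- seeds; m$centroids <- baseCen + disp; m
    } else structure(baseCen + disp, labels = attr(seeds, "labels"))
    runs[[r]] <- dtibsSegment(patient, field, s, ...)$state@assignments
  }
  A <- do.call(rbind, runs)            # nRuns x nVoxels
  modal <- apply(A, 2, function(v) max(tabulate(v, nbins = K)) / length(v))
  pairs <- utils::combn(nRuns, 2)
  ari <- vapply(seq_len(ncol(pairs)), function(i)
    mclust::adjustedRandIndex(A[pairs[1, i], ], A[pairs[2, i], ]),
    numeric(1))
  list(modalAgreement = modal, meanModalAgreement = mean(modal),
       ariPairwise = ari, meanAri = mean(ari), assignments = A)
}
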