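## ICP co-registration of thalamic surfaces and label resampling.

#' Boundary voxel centres of a mask as a point cloud
#'
#' A boundary voxel is a true voxel with at least one false 6-neighbour
#' (voxels on the grid edge count as boundary). Registration operates on
#' these surface points: the thalami are solid blobs whose interiors carry
#' no shape information.
#'
#' @param mask a BinaryMask (or LabelVolume, thresholded at > 0).
#' @return N x 3 matrix of world-mm surface points.
#' @export
surfacePoints <- function(mask) {
  if (is(mask, "LabelVolume"))
    mask <- BinaryMask(mask@labels > 0L, mask@affine)
  m <- mask@mask
  if (!any(m)) stop("mask is empty")
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(m & !interior, arr.ind = TRUE)
  voxelToWorldMat(idx, mask@affine)
}

# Closed-form least-squares similarity fit (Umeyama): finds s, R, t
# minimising sum || s R a_i + t - b_i ||^2 over corresponding rows of A, B.
.umeyama <- function(A, B, withScale = TRUE) {
  ma <- colMeans(A); mb <- colMeans(B)
  Ac <- sweep(A, 2, ma); Bc <- sweep(B, 2, mb)
  n <- nrow(A)
  S <- crossprod(Bc, Ac) / n
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  if (withScale) {
    varA <- sum(Ac^2) / n
    s <- sum(sv$d * c(1, 1, d)) / varA
  } else s <- 1
  t <- mb - s * as.vector(R %*% ma)
  similarityTransform(R, t, s)
}

# Principal-axes initialization candidates: centroid + covariance
# eigenvectors of both clouds, one candidate per proper sign combination
# of the axes.
.icpInitCandidates <- function(moving, fixed) {
  em <- eigen(stats::cov(moving), symmetric = TRUE)
  ef <- eigen(stats::cov(fixed), symmetric = TRUE)
  Vm <- em$vectors; Vf <- ef$vectors
  if (det(Vm) < 0) Vm[, 3] <- -Vm[, 3]
  if (det(Vf) < 0) Vf[, 3] <- -Vf[, 3]
  cm <- colMeans(moving); cf <- colMeans(fixed)
  lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
         function(signs) {
           # proper rotation: det = det(Vf) det(Vm) prod(signs) = 1
           R <- Vf %*% diag(signs) %*% t(Vm)
           similarityTransform(R, cf - as.vector(R %*% cm), 1)
         })
}

# Symmetric (bidirectional) RMS surface distance under a transform; used to
# select among converged ICP branches, where the one-way residual is too
# forgiving of pose flips.
.symmetricRms <- function(tf, moving, fixed) {
  pr <- applyTransform(tf, moving)
  d1 <- .nnIndexCpp(pr, fixed)$distance
  d2 <- .nnIndexCpp(fixed, pr)$distance
  sqrt(mean(c(d1^2, d2^2)))
}

#' Iterative closest point registration of two point clouds
#'
#' Alternates exact nearest-neighbour correspondence with a closed-form
#' least-squares (Umeyama/Procrustes) rigid update until the change in RMS
#' residual falls below \code{tol} or \code{maxIter} is reached. In
#' similarity mode the isotropic scale is estimated once, in closed form,
#' as the ratio of the clouds' RMS radii about their centroids (exact on
#' noiseless data and immune to the scale-collapse degeneracy of
#' per-iteration scale refits), and the rigid ICP runs on the pre-scaled
#' cloud. Initialization aligns centroids and principal axes; because the
#' axis signs are ambiguous, ICP is run from each of the four proper sign
#' combinations and the branch with the lowest symmetric surface RMS is
#' returned (see the methods vignette). Rigid mode fixes scale = 1.
#'
#' @param moving N x 3 matrix of moving-cloud world points (N >= 3).
#' @param fixed M x 3 matrix of fixed-cloud world points.
#' @param mode "similarity" (rotation + translation + isotropic scale) or
#'   "rigid".
#' @param maxIter maximum number of iterations per branch.
#' @param tol convergence tolerance on the change in RMS residual (mm).
#' @param maxPoints cap on the number of points used per cloud (uniform
#'   deterministic stride subsampling); keeps the exact nearest-neighbour
#'   correspondence affordable on dense surfaces without materially
#'   affecting the fit.
#' @return list with elements \code{transform} (SimilarityTransform mapping
#'   moving to fixed), \code{rms} (final one-way RMS residual, mm),
#'   \code{iterations}, \code{converged}, and \code{rmsHistory} (RMS after
#'   each accepted iteration of the winning branch).
#' @export
icpRegister <- function(moving, fixed, mode = c("similarity", "rigid"),
                        maxIter = 100L, tol = 1e-6, maxPoints = 2000L) {
  mode <- match.arg(mode)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) < 3L || nrow(fixed) < 3L)
    stop("point clouds must have at least 3 points")
  if (nrow(moving) > maxPoints)
    moving <- moving[round(seq(1, nrow(moving), length.out = maxPoints)), ]
  if (nrow(fixed) > maxPoints)
    fixed <- fixed[round(seq(1, nrow(fixed), length.out = maxPoints)), ]
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("point clouds must be finite")
  for (cl in list(moving, fixed)) {
    ev <- eigen(stats::cov(cl), symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] < 1e-12 * max(ev[1], 1))
      stop("degenerate (collinear) point cloud")
  }
  s0 <- 1
  movingS <- moving
  if (mode == "similarity") {
    cm <- colMeans(moving); cf <- colMeans(fixed)
    s0 <- sqrt((sum(sweep(fixed, 2, cf)^2) / nrow(fixed)) /
               (sum(sweep(moving, 2, cm)^2) / nrow(moving)))
    movingS <- moving * s0
  }
  # One exact NN query per iteration: the residual of the current
  # transform is measured on the correspondence set found under it, then
  # the transform is refit. The residual sequence is non-increasing.
  runBranch <- function(tf, mov, fix) {
    prevRms <- Inf
    converged <- FALSE
    iter <- 0L
    rms <- NA_real_
    hist <- numeric()
    while (iter < maxIter) {
      iter <- iter + 1L
      pr <- applyTransform(tf, mov)
      nn <- .nnIndexCpp(pr, fix)
      rms <- sqrt(mean(nn$distance^2))
      hist <- c(hist, rms)
      if (abs(prevRms - rms) < tol) { converged <- TRUE; break }
      prevRms <- rms
      tf <- .umeyama(mov, fix[nn$index, , drop = FALSE], withScale = FALSE)
    }
    list(transform = tf, rms = rms, iterations = iter,
         converged = converged, rmsHistory = hist)
  }
  # Coarse multi-start over the four axis-sign branches, then polish the
  # winner at full resolution.
  sub <- function(x, n) if (nrow(x) > n)
    x[round(seq(1, nrow(x), length.out = n)), , drop = FALSE] else x
  movC <- sub(movingS, 800L); fixC <- sub(fixed, 800L)
  best0 <- NULL
  bestSym <- Inf
  for (tf0 in .icpInitCandidates(movingS, fixed)) {
    br <- runBranch(tf0, movC, fixC)
    sym <- .symmetricRms(br$transform, movC, fixC)
    if (sym < bestSym) { bestSym <- sym; best0 <- br }
  }
  best <- runBranch(best0$transform, movingS, fixed)
  # fold the closed-form scale into the returned transform:
  # fixed ~ R (s0 x) + t = similarity(R, t, s0) applied to moving
  tf <- best$transform
  best$transform <- similarityTransform(tf@rotation, tf@translation, s0)
  best
}

#' Resample an atlas label volume through a similarity transform
#'
#' Nearest-neighbour label resampling: each target voxel centre is mapped
#' through the inverse transform into atlas world space and picks up the
#' label of the enclosing atlas voxel (background where the mapped point
#' falls outside the atlas grid).
#'
#' @param atlas a LabelVolume.
#' @param transform SimilarityTransform mapping atlas world coordinates to
#'   target world coordinates.
#' @param targetGrid BinaryMask or LabelVolume defining the target grid
#'   (dimensions and affine); its contents are ignored.
#' @return A LabelVolume on the target grid.
#' @export
transformLabels <- function(atlas, transform, targetGrid) {
  dims <- if (is(targetGrid, "BinaryMask")) dim(targetGrid@mask)
          else dim(targetGrid@labels)
  taff <- affineMat(targetGrid)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  world <- voxelToWorldMat(idx, taff)
  src <- applyTransform(invertTransform(transform), world)
  vox <- round(worldToVoxelMat(src, atlas@affine))
  ad <- dim(atlas@labels)
  ok <- vox[, 1] >= 1 & vox[, 1] <= ad[1] &
        vox[, 2] >= 1 & vox[, 2] <= ad[2] &
        vox[, 3] >= 1 & vox[, 3] <= ad[3]
  out <- integer(nrow(vox))
  if (any(ok))
    out[ok] <- atlas@labels[cbind(vox[ok, 1], vox[ok, 2], vox[ok, 3])]
  LabelVolume(array(out, dim = dims), taff)
}
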