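## Overlap and geometry metrics: Dice coefficient, region volume, centroid
## distance, and VTA-region overlap.

.sameGrid <- function(a, b) {
  all(dim(maskData(a)) == dim(maskData(b))) &&
    max(abs(affineMat(a) - affineMat(b))) < 1e-6
}

#' Dice coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|) by voxel counts on a common grid. Symmetric in
#' its arguments; 1 for identical geometries, 0 for disjoint ones.
#'
#' @param fixed,moving BinaryMasks on the same grid (the moving mask is
#'   expected to be already transformed and resampled).
#' @return scalar in [0, 1].
#' @export
dice <- function(fixed, moving) {
  if (!.sameGrid(fixed, moving))
    stop("masks must share dimensions and affine")
  na <- sum(fixed@mask); nb <- sum(moving@mask)
  if (na + nb == 0L) stop("both masks are empty")
  2 * sum(fixed@mask & moving@mask) / (na + nb)
}

#' Volume of a set of labels in a segmentation
#'
#' Voxel count times voxel volume, in mm^3, computed in the volume's
#' native grid.
#'
#' @param seg a Segmentation or LabelVolume.
#' @param regionLabels integer labels forming the region.
#' @return volume in mm^3 (0 with a warning for an empty region).
#' @export
regionVolume <- function(seg, regionLabels) {
  if (is(seg, "Segmentation")) seg <- seg@labels
  if (!length(regionLabels)) stop("regionLabels must be nonempty")
  n <- sum(seg@labels %in% as.integer(regionLabels))
  if (n == 0L) {
    warning("empty region")
    return(0)
  }
  n * prod(.voxelSize(seg@affine))
}

#' Distance from a region's centroid to the thalamus centroid
#'
#' Both centroids are unweighted means of voxel-centre world coordinates.
#'
#' @param seg a Segmentation or LabelVolume.
#' @param regionLabels integer labels forming the region.
#' @param thalamus BinaryMask of the whole thalamus.
#' @return Euclidean distance in mm.
#' @export
centroidDistance <- function(seg, regionLabels, thalamus) {
  if (is(seg, "Segmentation")) seg <- seg@labels
  sel <- which(array(seg@labels %in% as.integer(regionLabels),
                     dim = dim(seg@labels)), arr.ind = TRUE)
  if (!nrow(sel)) stop("empty region")
  if (!any(thalamus@mask)) stop("empty thalamus mask")
  cr <- colMeans(voxelToWorldMat(sel, seg@affine))
  ct <- colMeans(worldCoordinates(thalamus))
  sqrt(sum((cr - ct)^2))
}

#' Percent of a VTA inside a region
#'
#' |VTA n Region| / |VTA| x 100. Note the asymmetry: the overlap is
#' normalized by the VTA volume only.
#'
#' @param vta BinaryMask of the volume of tissue activated (nonempty).
#' @param region BinaryMask of the motor or sensory region, same grid.
#' @return percent in [0, 100].
#' @export
vtaOverlap <- function(vta, region) {
  if (!.sameGrid(vta, region))
    stop("masks must share dimensions and affine")
  n <- sum(vta@mask)
  if (n == 0L) stop("empty VTA")
  100 * sum(vta@mask & region@mask) / n
}

#' Inter-atlas Dice tables
#'
#' For every ordered (fixed, moving) atlas pair: the moving atlas'
#' hemisphere surface is ICP-registered (rigid by default) to the fixed
#' atlas' surface, the moving label volume is resampled
#' nearest-neighbour onto the fixed grid, and Dice is computed by voxel
#' counts on the fixed grid for the whole thalamus and the motor and
#' sensory unions.
#'
#' @param bundles list of AtlasBundles.
#' @param side hemisphere used for the comparison (default "left").
#' @param mode ICP mode for the atlas-to-atlas registration.
#' @return list of three matrices (whole, motor, sensory) with unit
#'   diagonals; rows are fixed atlases, columns moving atlases.
#' @export
interAtlasDice <- function(bundles, side = "left",
                           mode = c("rigid", "similarity")) {
  mode <- match.arg(mode)
  ids <- vapply(bundles, atlasId, character(1))
  n <- length(bundles)
  hemis <- lapply(bundles, extractHemisphere, side = side)
  surfs <- lapply(hemis, surfacePoints)
  out <- list(whole = diag(n), motor = diag(n), sensory = diag(n))
  for (m in names(out)) dimnames(out[[m]]) <- list(fixed = ids, moving = ids)
  for (i in seq_len(n)) {
    fixHemi <- hemis[[i]]
    fixGrid <- BinaryMask(fixHemi@labels > 0L, fixHemi@affine)
    fixRegions <- list(
      whole = fixGrid,
      motor = buildRegionMask(fixHemi, bundles[[i]]@table, "motor", side),
      sensory = buildRegionMask(fixHemi, bundles[[i]]@table, "sensory", side))
    for (j in seq_len(n)) {
      if (i == j) next
      reg <- icpRegister(surfs[[j]], surfs[[i]], mode = mode)
      moved <- transformLabels(hemis[[j]], reg$transform, fixGrid)
      movRegions <- list(
        whole = BinaryMask(moved@labels > 0L, moved@affine),
        motor = buildRegionMask(moved, bundles[[j]]@table, "motor", side),
        sensory = buildRegionMask(moved, bundles[[j]]@table, "sensory", side))
      for (m in names(out))
        out[[m]][i, j] <- dice(fixRegions[[m]], movRegions[[m]])
    }
  }
  out
}
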