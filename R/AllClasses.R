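#' @useDynLib thalaseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## ---------------------------------------------------------------------------
## Central S4 containers. Voxel indexing convention: R arrays are 1-based, but
## the affine maps 0-based voxel indices to world RAS+ millimetres (NIfTI
## convention), i.e. world = affine %*% c(i - 1, j - 1, k - 1, 1).
## ---------------------------------------------------------------------------

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (!all(is.finite(affine)))
    return("affine must be finite")
  if (abs(det(affine)) < 1e-12)
    return("affine must be invertible")
  NULL
}

#' LabelVolume: an integer-labelled 3D volume
#'
#' Holds a 3D grid of non-negative integer labels (0 = background) together
#' with a 4x4 affine mapping 0-based voxel indices to world RAS+ mm.
#' Used for atlas subnuclei labelings and segmentations.
#'
#' @slot labels 3D integer array, non-negative.
#' @slot affine 4x4 voxel-index-to-world-mm matrix (invertible).
#' @export
setClass("LabelVolume", representation(labels = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (any(dim(object@labels) < 1L))
      msg <- c(msg, "grid dimensions must be >= 1")
    if (!is.integer(object@labels))
      msg <- c(msg, "labels must be integer storage mode")
    else if (anyNA(object@labels) || any(object@labels < 0L))
      msg <- c(msg, "labels must be non-negative and non-missing")
    a <- .checkAffine(object@affine)
    if (!is.null(a)) msg <- c(msg, a)
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a boolean 3D volume
#'
#' @slot mask 3D logical array.
#' @slot affine 4x4 voxel-index-to-world-mm matrix.
#' @export
setClass("BinaryMask", representation(mask = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3D array")
    if (!is.logical(object@mask) || anyNA(object@mask))
      msg <- c(msg, "mask must be logical and non-missing")
    a <- .checkAffine(object@affine)
    if (!is.null(a)) msg <- c(msg, a)
    if (length(msg)) msg else TRUE
  })

#' SubnucleusTable: per-subnucleus metadata for an atlas
#'
#' Rows pair label ids with names, a functional class (motor, sensory or
#' other) and a hemisphere. Label ids must be unique within a hemisphere.
#'
#' @slot table data.frame with columns label, name, class, hemisphere.
#' @slot atlasId character identifier of the atlas.
#' @export
setClass("SubnucleusTable",
  representation(table = "data.frame", atlasId = "character"),
  validity = function(object) {
    tb <- object@table
    need <- c("label", "name", "class", "hemisphere")
    if (!all(need %in% names(tb)))
      return(paste("table must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(tb)) {
      if (!all(tb$label == as.integer(tb$label)) || any(tb$label < 1))
        msg <- c(msg, "label ids must be positive integers")
      if (!all(tb$class %in% c("motor", "sensory", "other")))
        msg <- c(msg, "class must be motor, sensory or other")
      if (!all(tb$hemisphere %in% c("left", "right")))
        msg <- c(msg, "hemisphere must be left or right")
      for (h in unique(tb$hemisphere)) {
        lab <- tb$label[tb$hemisphere == h]
        if (anyDuplicated(lab))
          msg <- c(msg, sprintf("duplicate label ids in %s hemisphere", h))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' AtlasBundle: a bilateral thalamic atlas
#'
#' Bundles left- and right-hemisphere label volumes with their subnucleus
#' metadata table. Both hemispheres must be nonempty and every nonzero label
#' must appear in the table for its hemisphere.
#'
#' @slot left,right LabelVolume for each hemisphere.
#' @slot table SubnucleusTable.
#' @slot atlasId character identifier.
#' @export
setClass("AtlasBundle",
  representation(left = "LabelVolume", right = "LabelVolume",
                 table = "SubnucleusTable", atlasId = "character"),
  validity = function(object) {
    msg <- character()
    tb <- object@table@table
    for (h in c("left", "right")) {
      vol <- slot(object, h)
      labs <- setdiff(unique(as.vector(vol@labels)), 0L)
      if (!length(labs))
        msg <- c(msg, sprintf("%s hemisphere is empty", h))
      known <- tb$label[tb$hemisphere == h]
      if (length(setdiff(labs, known)))
        msg <- c(msg, sprintf("labels in %s hemisphere missing from table", h))
    }
    if (length(msg)) msg else TRUE
  })

#' SimilarityTransform: rotation + translation + isotropic scale
#'
#' Maps world points x to scale * rotation %*% x + translation.
#'
#' @slot rotation 3x3 proper orthonormal matrix.
#' @slot translation length-3 numeric, mm.
#' @slot scale positive scalar.
#' @export
setClass("SimilarityTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric"),
  validity = function(object) {
    R <- object@rotation
    msg <- character()
    if (!all(dim(R) == c(3L, 3L)))
      msg <- c(msg, "rotation must be 3x3")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-9)")
      if (abs(det(R) - 1) > 1e-9)
        msg <- c(msg, "rotation must be proper (det = 1 within 1e-9)")
    }
    if (length(object@translation) != 3L || !all(is.finite(object@translation)))
      msg <- c(msg, "translation must be a finite mm triple")
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
      msg <- c(msg, "scale must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' TensorField: per-voxel symmetric diffusion tensors
#'
#' Stores the six unique components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) of a
#' symmetric 3x3 diffusion tensor per voxel (mm^2/s), with a support mask
#' marking voxels where the tensor is defined. Tensors are made symmetric
#' positive definite at load time by flooring eigenvalues.
#'
#' @slot tensors 4D array (nx, ny, nz, 6).
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot support BinaryMask on the same grid.
#' @export
setClass("TensorField",
  representation(tensors = "array", affine = "matrix", support = "BinaryMask"),
  validity = function(object) {
    d <- dim(object@tensors)
    msg <- character()
    if (length(d) != 4L || d[4] != 6L)
      msg <- c(msg, "tensors must be a 4D array with 6 components")
    if (!all(d[1:3] == dim(object@support@mask)))
      msg <- c(msg, "support grid must match tensor grid")
    a <- .checkAffine(object@affine)
    if (!is.null(a)) msg <- c(msg, a)
    if (length(msg)) msg else TRUE
  })

#' ClusterState: state of the DTIBS k-means
#'
#' @slot centroids K x 3 world-mm cluster centroids.
#' @slot covariances 3 x 3 x K spatial covariances (mm^2).
#' @slot meanTensors K x 6 mean diffusion tensors.
#' @slot assignments integer cluster index per supported voxel.
#' @slot labels integer subnucleus label for each cluster.
#' @slot iterations number of completed iterations.
#' @slot converged logical convergence flag.
#' @slot emptied indices of clusters that became empty (frozen).
#' @export
setClass("ClusterState",
  representation(centroids = "matrix", covariances = "array",
                 meanTensors = "matrix", assignments = "integer",
                 labels = "integer", iterations = "integer",
                 converged = "logical", emptied = "integer"),
  validity = function(object) {
    K <- nrow(object@centroids)
    msg <- character()
    if (ncol(object@centroids) != 3L)
      msg <- c(msg, "centroids must be K x 3")
    if (!all(dim(object@covariances) == c(3L, 3L, K)))
      msg <- c(msg, "covariances must be 3 x 3 x K")
    if (!all(dim(object@meanTensors) == c(K, 6L)))
      msg <- c(msg, "meanTensors must be K x 6")
    if (length(object@assignments) &&
        (min(object@assignments) < 1L || max(object@assignments) > K))
      msg <- c(msg, "assignments out of range")
    if (length(object@labels) != K)
      msg <- c(msg, "labels must have one entry per cluster")
    if (length(msg)) msg else TRUE
  })

#' Segmentation: a labelled patient thalamus
#'
#' @slot labels LabelVolume on the patient grid.
#' @slot method "ABS" or "DTIBS".
#' @slot atlasId atlas that informed the segmentation.
#' @slot provenance list (transform, seed, parameters, ...).
#' @export
setClass("Segmentation",
  representation(labels = "LabelVolume", method = "character",
                 atlasId = "character", provenance = "list"),
  validity = function(object) {
    if (!object@method %in% c("ABS", "DTIBS"))
      return("method must be ABS or DTIBS")
    TRUE
  })

#' SyntheticTruth: ground truth for one synthetic patient
#'
#' @slot transform the true atlas-to-patient SimilarityTransform.
#' @slot labels ground-truth LabelVolume on the patient grid.
#' @slot tensorParams per-subnucleus list(eigenvalues, direction, noiseSd).
#' @slot vtaSpec list of VTA specifications (center, radii, outcome).
#' @export
setClass("SyntheticTruth",
  representation(transform = "SimilarityTransform", labels = "LabelVolume",
                 tensorParams = "list", vtaSpec = "list"))

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Construct a LabelVolume
#'
#' @param labels 3D array of non-negative integers (numeric arrays with
#'   integer values are cast).
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, affine) {
  if (!is.integer(labels)) {
    if (max(abs(labels - round(labels))) > 1e-6)
      stop("labels must be integer-valued")
    labels <- array(as.integer(round(labels)), dim = dim(labels))
  }
  new("LabelVolume", labels = labels, affine = affine)
}

#' Construct a BinaryMask
#'
#' @param mask 3D logical array (numeric arrays are thresholded at != 0).
#' @param affine 4x4 voxel-to-world matrix.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(mask, affine) {
  if (!is.logical(mask))
    mask <- array(mask != 0, dim = dim(mask))
  new("BinaryMask", mask = mask, affine = affine)
}

#' Construct a SubnucleusTable
#'
#' @param table data.frame with columns label, name, class, hemisphere.
#' @param atlasId atlas identifier string.
#' @return A \linkS4class{SubnucleusTable}.
#' @export
SubnucleusTable <- function(table, atlasId = "atlas") {
  table$label <- as.integer(table$label)
  rownames(table) <- NULL
  new("SubnucleusTable", table = table, atlasId = atlasId)
}

#' Construct a SimilarityTransform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation mm triple.
#' @param scale positive scalar (1 for rigid).
#' @return A \linkS4class{SimilarityTransform}.
#' @export
similarityTransform <- function(rotation = diag(3),
                                translation = c(0, 0, 0), scale = 1) {
  new("SimilarityTransform", rotation = rotation,
      translation = as.numeric(translation), scale = as.numeric(scale))
}

## ---------------------------------------------------------------------------
## Accessors and small generics
## ---------------------------------------------------------------------------

#' Voxel-to-world affine of a volume
#' @param x a LabelVolume, BinaryMask or TensorField.
#' @return 4x4 matrix.
#' @export
setGeneric("affineMat", function(x) standardGeneric("affineMat"))
#' @rdname affineMat
setMethod("affineMat", "LabelVolume", function(x) x@affine)
#' @rdname affineMat
setMethod("affineMat", "BinaryMask", function(x) x@affine)
#' @rdname affineMat
setMethod("affineMat", "TensorField", function(x) x@affine)

#' Voxel size in mm derived from the affine
#' @param x a LabelVolume, BinaryMask or TensorField.
#' @return numeric mm triple (column norms of the affine).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
.voxelSize <- function(affine) unname(sqrt(colSums(affine[1:3, 1:3]^2)))
#' @rdname voxelSize
setMethod("voxelSize", "LabelVolume", function(x) .voxelSize(x@affine))
#' @rdname voxelSize
setMethod("voxelSize", "BinaryMask", function(x) .voxelSize(x@affine))
#' @rdname voxelSize
setMethod("voxelSize", "TensorField", function(x) .voxelSize(x@affine))

#' Volume of one voxel in mm^3
#' @param x a volume object.
#' @return scalar mm^3.
#' @export
voxelVolume <- function(x) prod(voxelSize(x))

#' Label array of a LabelVolume
#' @param x a LabelVolume.
#' @return 3D integer array.
#' @export
labelData <- function(x) x@labels

#' Logical array of a BinaryMask
#' @param x a BinaryMask.
#' @return 3D logical array.
#' @export
maskData <- function(x) x@mask

#' Sorted set of nonzero labels present in a LabelVolume
#' @param x a LabelVolume.
#' @return integer vector.
#' @export
labelSet <- function(x) sort(setdiff(unique(as.vector(x@labels)), 0L))

#' Metadata data.frame of a SubnucleusTable
#' @param x a SubnucleusTable (or AtlasBundle).
#' @return data.frame with columns label, name, class, hemisphere.
#' @export
setGeneric("subnucleusData", function(x) standardGeneric("subnucleusData"))
#' @rdname subnucleusData
setMethod("subnucleusData", "SubnucleusTable", function(x) x@table)
#' @rdname subnucleusData
setMethod("subnucleusData", "AtlasBundle", function(x) x@table@table)

#' Atlas identifier
#' @param x a SubnucleusTable, AtlasBundle or Segmentation.
#' @return character id.
#' @export
setGeneric("atlasId", function(x) standardGeneric("atlasId"))
#' @rdname atlasId
setMethod("atlasId", "SubnucleusTable", function(x) x@atlasId)
#' @rdname atlasId
setMethod("atlasId", "AtlasBundle", function(x) x@atlasId)
#' @rdname atlasId
setMethod("atlasId", "Segmentation", function(x) x@atlasId)

#' Label volume of a Segmentation
#' @param x a Segmentation.
#' @return LabelVolume.
#' @export
segmentationLabels <- function(x) x@labels

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume %dx%dx%d, %d labels, voxel %s mm\n",
              d[1], d[2], d[3], length(labelSet(object)),
              paste(signif(voxelSize(object), 3), collapse = "x")))
})
setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask %dx%dx%d, %d true voxels, voxel %s mm\n",
              d[1], d[2], d[3], sum(object@mask),
              paste(signif(voxelSize(object), 3), collapse = "x")))
})
setMethod("show", "SubnucleusTable", function(object) {
  tb <- object@table
  cat(sprintf("SubnucleusTable '%s': %d rows (%d motor, %d sensory)\n",
              object@atlasId, nrow(tb), sum(tb$class == "motor"),
              sum(tb$class == "sensory")))
})
setMethod("show", "AtlasBundle", function(object) {
  cat(sprintf("AtlasBundle '%s': left %d voxels, right %d voxels, %d subnuclei/hemisphere\n",
              object@atlasId, sum(object@left@labels > 0L),
              sum(object@right@labels > 0L),
              sum(object@table@table$hemisphere == "left")))
})
setMethod("show", "SimilarityTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("SimilarityTransform: rotation %.2f deg, translation (%s) mm, scale %.4f\n",
              ang, paste(sprintf("%.2f", object@translation), collapse = ", "),
              object@scale))
})
setMethod("show", "TensorField", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("TensorField %dx%dx%d, %d supported voxels\n",
              d[1], d[2], d[3], sum(object@support@mask)))
})
setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation (%s, atlas '%s'): %d voxels, %d labels\n",
              object@method, object@atlasId, sum(object@labels@labels > 0L),
              length(labelSet(object@labels))))
})
setMethod("show", "ClusterState", function(object) {
  cat(sprintf("ClusterState: K = %d, %d voxels, %d iterations, converged: %s\n",
              nrow(object@centroids), length(object@assignments),
              object@iterations, object@converged))
})

## ---------------------------------------------------------------------------
## Coordinate helpers and transform algebra
## ---------------------------------------------------------------------------

#' World coordinates of voxel indices
#'
#' @param idx N x 3 matrix of 1-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix (0-based convention).
#' @return N x 3 matrix of world mm coordinates.
#' @export
voxelToWorldMat <- function(idx, affine) {
  idx <- rbind(t(idx - 1), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

#' Voxel indices (1-based, fractional) of world coordinates
#'
#' @param pts N x 3 matrix of world mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return N x 3 matrix of fractional 1-based voxel indices.
#' @export
worldToVoxelMat <- function(pts, affine) {
  pts <- rbind(t(pts), 1)
  t(solve(affine) %*% pts)[, 1:3, drop = FALSE] + 1
}

#' World coordinates of the true voxels of a mask (or labelled voxels)
#' @param x BinaryMask or LabelVolume.
#' @return N x 3 matrix of voxel-centre world coordinates.
#' @export
worldCoordinates <- function(x) {
  if (is(x, "BinaryMask")) idx <- which(x@mask, arr.ind = TRUE)
  else idx <- which(x@labels > 0L, arr.ind = TRUE)
  voxelToWorldMat(idx, affineMat(x))
}

#' Apply a similarity transform to points
#'
#' @param transform a SimilarityTransform.
#' @param pts N x 3 matrix of world coordinates.
#' @return N x 3 matrix of transformed coordinates.
#' @export
applyTransform <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(transform@scale * pts %*% t(transform@rotation), 2,
        transform@translation, `+`)
}

#' Invert a similarity transform
#' @param transform a SimilarityTransform.
#' @return the inverse SimilarityTransform.
#' @export
invertTransform <- function(transform) {
  Rinv <- t(transform@rotation)
  s <- 1 / transform@scale
  similarityTransform(Rinv, -s * as.vector(Rinv %*% transform@translation), s)
}

#' Compose two similarity transforms (apply \code{inner} first)
#' @param outer,inner SimilarityTransforms.
#' @return the composed SimilarityTransform outer(inner(x)).
#' @export
composeTransforms <- function(outer, inner) {
  similarityTransform(
    outer@rotation %*% inner@rotation,
    outer@scale * as.vector(outer@rotation %*% inner@translation) +
      outer@translation,
    outer@scale * inner@scale)
}
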