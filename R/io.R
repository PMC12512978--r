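## NIfTI and metadata I/O. All volume I/O goes through RNifti; the sform
## carries the affine (0-based voxel convention, RAS+ mm).

.readNiftiVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))   # plain array, no image class
  list(data = data, affine = affine)
}

.writeNiftiVolume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- .voxelSize(affine)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' The voxel data must be integer-valued (integer storage, or floats that
#' round exactly); anything else is a format error.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path) {
  v <- .readNiftiVolume(path)
  if (length(dim(v$data)) != 3L)
    stop("expected a 3D volume: ", path, call. = FALSE)
  if (max(abs(v$data - round(v$data)), 0) > 1e-6)
    stop("volume is not integer-valued: ", path, call. = FALSE)
  LabelVolume(v$data, v$affine)
}

#' Read a binary mask from NIfTI (nonzero voxels are TRUE)
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A \linkS4class{BinaryMask}.
#' @export
readBinaryMask <- function(path) {
  v <- .readNiftiVolume(path)
  if (length(dim(v$data)) != 3L)
    stop("expected a 3D volume: ", path, call. = FALSE)
  BinaryMask(v$data != 0, v$affine)
}

#' Write a LabelVolume or BinaryMask to NIfTI
#'
#' @param x a LabelVolume or BinaryMask.
#' @param path destination .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "LabelVolume"))
    .writeNiftiVolume(x@labels, x@affine, path)
  else if (is(x, "BinaryMask"))
    .writeNiftiVolume(array(as.integer(x@mask), dim = dim(x@mask)),
                      x@affine, path)
  else stop("writeVolume handles LabelVolume and BinaryMask")
  invisible(path)
}

#' Read a diffusion tensor field from a 6-component NIfTI
#'
#' Component order along the 4th dimension is Dxx, Dxy, Dxz, Dyy, Dyz, Dzz
#' (mm^2/s). Voxels whose six components are all zero are outside the
#' support. Tensors are floored to be symmetric positive definite
#' (eigenvalues below \code{floor} are raised to it).
#'
#' @param path path to a 4D NIfTI with 6 volumes.
#' @param floor eigenvalue floor in mm^2/s.
#' @return A \linkS4class{TensorField}.
#' @export
readTensorField <- function(path, floor = 1e-6) {
  v <- .readNiftiVolume(path)
  if (length(dim(v$data)) != 4L || dim(v$data)[4] != 6L)
    stop("expected a 4D NIfTI with 6 tensor components: ", path,
         call. = FALSE)
  tensorField(v$data, v$affine, floor = floor)
}

#' Construct a TensorField from a component array
#'
#' @param tensors 4D array (nx, ny, nz, 6), order Dxx, Dxy, Dxz, Dyy, Dyz,
#'   Dzz.
#' @param affine 4x4 voxel-to-world matrix.
#' @param support optional BinaryMask; defaults to voxels with any nonzero
#'   component.
#' @param floor eigenvalue floor applied to supported voxels (mm^2/s).
#' @return A \linkS4class{TensorField}.
#' @export
tensorField <- function(tensors, affine, support = NULL, floor = 1e-6) {
  d <- dim(tensors)
  if (is.null(support)) {
    nz <- apply(tensors != 0, 1:3, any)
    support <- BinaryMask(array(nz, dim = d[1:3]), affine)
  }
  flat <- matrix(tensors, ncol = 6L)
  idx <- which(as.vector(support@mask))
  if (length(idx)) {
    floored <- .floorTensors(flat[idx, , drop = FALSE], floor)
    flat[idx, ] <- floored
    tensors <- array(flat, dim = d)
  }
  new("TensorField", tensors = tensors, affine = affine, support = support)
}

# Floor eigenvalues of rows of an N x 6 symmetric-component matrix.
.floorTensors <- function(comp, floor) {
  for (i in seq_len(nrow(comp))) {
    D <- .sym6ToMat(comp[i, ])
    e <- eigen(D, symmetric = TRUE)
    if (min(e$values) < floor) {
      vals <- pmax(e$values, floor)
      D <- e$vectors %*% (vals * t(e$vectors))
      comp[i, ] <- .matToSym6(D)
    }
  }
  comp
}

.sym6ToMat <- function(v)
  matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
.matToSym6 <- function(M)
  c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])

#' Write a TensorField to a 6-component NIfTI
#'
#' @param x a TensorField.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeTensorField <- function(x, path) {
  .writeNiftiVolume(x@tensors, x@affine, path)
  invisible(path)
}

#' Read a subnucleus metadata table from JSON
#'
#' Expected form: \code{{"atlas_id": "...", "entries": [{"label": 1,
#' "name": "...", "class": "motor", "hemisphere": "left"}, ...]}}.
#'
#' @param path path to the JSON file.
#' @return A \linkS4class{SubnucleusTable}.
#' @export
readSubnucleusTable <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- as.data.frame(j$entries)
  SubnucleusTable(tb, atlasId = j$atlas_id %||% "atlas")
}

#' Write a SubnucleusTable to JSON
#'
#' @param x a SubnucleusTable.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeSubnucleusTable <- function(x, path) {
  jsonlite::write_json(
    list(atlas_id = x@atlasId, entries = x@table),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged atlas metadata (six published thalamic atlases)
#'
#' Returns the shipped metadata fixture: per-hemisphere total, motor and
#' sensory subnucleus counts for the six atlases analysed (Ding, Ewert,
#' Iglesias, Ilinsky, Jakab, Saranathan), with their short abbreviations.
#' Counts are recorded as per-hemisphere values.
#'
#' @return data.frame with columns atlas, abbreviation, total, motor,
#'   sensory.
#' @export
atlasMetadata <- function() {
  path <- system.file("extdata", "atlas_metadata.json", package = "thalaseg")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(j$atlases)
}
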