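## Atlas preprocessing: thalamus isolation, hemisphere extraction, and
## motor/sensory region unions.

#' Isolate the thalamus proper in an atlas label volume
#'
#' Removes subnuclei that do not belong to the thalamus proper (typically
#' the medial and lateral geniculate nuclei) and cleans residual artifact
#' voxels by dropping, for each remaining label, connected components
#' (26-connectivity) smaller than \code{minComponentVoxels}.
#'
#' @param vol a LabelVolume.
#' @param table the matching SubnucleusTable.
#' @param excludedNames character vector of subnucleus names to remove
#'   (must all be present in the table).
#' @param minComponentVoxels minimum connected-component size kept per
#'   label; 1 disables the artifact threshold.
#' @return A LabelVolume. If thresholding empties a label entirely a
#'   warning is emitted and the label is absent from the output.
#' @export
isolateThalamus <- function(vol, table, excludedNames = character(),
                            minComponentVoxels = 5L) {
  tb <- subnucleusData(table)
  unknown <- setdiff(excludedNames, tb$name)
  if (length(unknown))
    stop("excluded names not in table: ", paste(unknown, collapse = ", "))
  drop <- unique(tb$label[tb$name %in% excludedNames])
  labs <- vol@labels
  if (length(drop)) labs[labs %in% drop] <- 0L
  if (minComponentVoxels > 1L) {
    for (lab in setdiff(unique(as.vector(labs)), 0L)) {
      m <- labs == lab
      comp <- .ccLabelCpp(as.vector(m), dim(labs))
      sizes <- tabulate(comp)
      small <- which(sizes < minComponentVoxels)
      if (length(small)) {
        kill <- array(comp %in% small, dim = dim(labs)) & m
        labs[kill] <- 0L
        if (!any(labs == lab))
          warning(sprintf("label %d emptied by artifact thresholding", lab))
      }
    }
  }
  LabelVolume(labs, vol@affine)
}

#' Extract one hemisphere of an atlas bundle
#'
#' @param bundle an AtlasBundle.
#' @param side "left" or "right".
#' @return the hemisphere's LabelVolume.
#' @export
extractHemisphere <- function(bundle, side = c("left", "right")) {
  side <- match.arg(side)
  vol <- slot(bundle, side)
  if (!any(vol@labels > 0L))
    stop(side, " hemisphere is empty")
  vol
}

#' Union mask of all subnuclei of a functional class
#'
#' The motor and sensory regions are defined as the union of the
#' respective subnuclei.
#'
#' @param vol a LabelVolume.
#' @param table the matching SubnucleusTable.
#' @param funcClass "motor" or "sensory".
#' @param hemisphere optional hemisphere filter for the table lookup; by
#'   default all rows matching the class are used (labels carried by
#'   single-hemisphere volumes are consistent across hemispheres in this
#'   package's synthetic atlases).
#' @return A BinaryMask.
#' @export
buildRegionMask <- function(vol, table, funcClass = c("motor", "sensory"),
                            hemisphere = NULL) {
  funcClass <- match.arg(funcClass)
  tb <- subnucleusData(table)
  if (!is.null(hemisphere)) tb <- tb[tb$hemisphere == hemisphere, ]
  ids <- unique(tb$label[tb$class == funcClass])
  if (!length(ids))
    stop("no subnuclei of class '", funcClass, "' in table")
  BinaryMask(array(vol@labels %in% ids, dim = dim(vol@labels)), vol@affine)
}

#' Number of subnuclei in one hemisphere of an atlas
#'
#' This count determines the number of clusters k used by DTIBS.
#'
#' @param table a SubnucleusTable (or AtlasBundle).
#' @param hemisphere which hemisphere to count; default "left".
#' @return integer count.
#' @export
subnucleiCount <- function(table, hemisphere = "left") {
  tb <- subnucleusData(table)
  if (!nrow(tb)) stop("empty subnucleus table")
  n <- sum(tb$hemisphere == hemisphere)
  if (n == 0L) n <- nrow(tb)   # single-hemisphere table without split
  as.integer(n)
}
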