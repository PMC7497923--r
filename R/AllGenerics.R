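# Accessor generics and show methods. Slots are never reached into by
# user code; these accessors are the supported surface.

#' Extract the voxel data array
#' @param x a Volume or ROIMask.
#' @return The underlying 3D array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname volData
setMethod("volData", "Volume", function(x) x@data)

#' Voxel spacing in mm
#' @param x a Volume, ROIMask or DeformationField.
#' @return numeric(3), mm per voxel.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
setMethod("voxelSpacing", "Volume", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "ROIMask", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "DeformationField", function(x) x@spacing)

#' Physical origin in mm
#' @param x a Volume.
#' @return numeric(3).
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' @rdname volOrigin
setMethod("volOrigin", "Volume", function(x) x@origin)

#' Modality tag of a volume
#' @param x a Volume.
#' @return character(1).
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname modality
setMethod("modality", "Volume", function(x) x@modality)

#' Label array of an ROI mask
#' @param x an ROIMask.
#' @return 3D integer array (0 = background).
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname maskLabels
setMethod("maskLabels", "ROIMask", function(x) x@labels)

#' Label-name lookup of an ROI mask
#' @param x an ROIMask.
#' @return named character vector.
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname labelNames
setMethod("labelNames", "ROIMask", function(x) x@labelNames)

#' Displacement array of a deformation field
#' @param x a DeformationField.
#' @return 4D array `(nx, ny, nz, 3)` in voxel units.
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname displacements
setMethod("displacements", "DeformationField", function(x) x@displacements)

#' Landmark coordinates
#' @param x a LandmarkSet.
#' @return numeric matrix (n x 3), physical mm.
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))

#' @rdname landmarkPoints
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

#' @describeIn volData dimensions of the voxel grid
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' @describeIn maskLabels dimensions of the label grid
#' @export
setMethod("dim", "ROIMask", function(x) dim(x@labels))

#' @describeIn displacements spatial dimensions of the field grid
#' @export
setMethod("dim", "DeformationField", function(x) dim(x@displacements)[1:3])

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume [%s]: %d x %d x %d voxels, spacing %s mm\n",
              object@modality, d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%s) mm\n",
              min(object@data), max(object@data),
              paste(format(object@origin, trim = TRUE), collapse = ", ")))
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@labels)
  labs <- sort(unique(as.vector(object@labels)))
  labs <- labs[labs != 0L]
  cat(sprintf("ROIMask: %d x %d x %d voxels, %d label(s)\n",
              d[1], d[2], d[3], length(labs)))
  for (l in labs) {
    nm <- object@labelNames[as.character(l)]
    cat(sprintf("  label %d%s: %d voxels\n", l,
                if (is.na(nm)) "" else paste0(" (", nm, ")"),
                sum(object@labels == l)))
  }
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@displacements)
  mag <- sqrt(rowSums(matrix(object@displacements, ncol = 3)^2))
  cat(sprintf(
    "DeformationField: %d x %d x %d voxels, |u| mean %.3f / max %.3f vox\n",
    d[1], d[2], d[3], mean(mag), max(mag)))
})

setMethod("show", "RegistrationNetwork", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "RegistrationNetwork: %s input, %d scales, %d residual blocks, %d parameters\n",
    paste(cfg@inSize, collapse = "x"), cfg@nScales, cfg@nResBlocks, np))
})

setMethod("show", "TrainState", function(object) {
  cat(sprintf("TrainState: %d epoch(s) trained, %d loss records\n",
              object@epoch, nrow(object@lossHistory)))
  if (nrow(object@lossHistory)) {
    last <- object@lossHistory[nrow(object@lossHistory), ]
    cat(sprintf("  last total loss: %.5f\n", last$total))
  }
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase (synthetic multimodal pair)\n")
  cat("  A: "); show(object@volA)
  cat("  B: "); show(object@volB)
  cat(sprintf("  %d landmark pairs, ground-truth field |u| max %.2f vox\n",
              nrow(object@landmarksA@points),
              max(abs(object@gtField@displacements))))
})
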