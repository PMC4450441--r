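#' @name accessors
#' @title Accessors for rootquant objects
#'
#' @description Small accessor layer over the S4 containers: channel names
#' and voxel arrays of an [ImageStack], the per-cell table and label
#' volume of a [GroundTruth], the label image and region table of a
#' [PlaneSegmentation], and the cell and region tables of a [CellSet].
#'
#' @param x the object.
#' @param channel channel name, e.g. `"wall"` or `"reporter_1"`.
#' @return See the individual generics.
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@voxels))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setMethod("getChannel", "ImageStack", function(x, channel) {
  if (!channel %in% names(x@voxels))
    stop("no such channel: '", channel, "' (have: ",
         paste(names(x@voxels), collapse = ", "), ")")
  x@voxels[[channel]]
})

#' @rdname accessors
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @rdname accessors
#' @export
setMethod("nPlanes", "ImageStack", function(x) dim(x@voxels[[1]])[3])

#' @rdname accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname accessors
#' @export
setMethod("truthCells", "GroundTruth", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setMethod("truthLabels", "GroundTruth", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))
#' @rdname accessors
#' @export
setMethod("segLabels", "PlaneSegmentation", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("segTable", function(x) standardGeneric("segTable"))
#' @rdname accessors
#' @export
setMethod("segTable", "PlaneSegmentation", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setMethod("cellTable", "CellSet", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("cellRegions", function(x) standardGeneric("cellRegions"))
#' @rdname accessors
#' @export
setMethod("cellRegions", "CellSet", function(x) x@regions)
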