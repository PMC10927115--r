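#' Platform tag of a spot-level object
#' @param x a SpotDataset or VirtualImage.
#' @return `"visium"` or `"stereo"`.
#' @export
setGeneric("platformOf", function(x) standardGeneric("platformOf"))

#' @rdname platformOf
#' @export
setMethod("platformOf", "SpotDataset", function(x) metadata(x)$platform)

#' @rdname platformOf
#' @export
setMethod("platformOf", "VirtualImage", function(x) x@platform)

#' Spot identifiers
#' @param x a SpotDataset.
#' @export
setGeneric("spotIds", function(x) standardGeneric("spotIds"))

#' @rdname spotIds
#' @export
setMethod("spotIds", "SpotDataset", function(x) as.character(colData(x)$spot_id))

#' Pixel (image) coordinates, spots x 2
#' @param x a SpotDataset.
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "SpotDataset", function(x) {
  cd <- colData(x)
  cbind(x = cd$pixel_x, y = cd$pixel_y)
})

#' Lattice (array) coordinates, spots x 2, 0-based
#' @param x a SpotDataset or VirtualImage.
#' @export
setGeneric("latticeCoords", function(x) standardGeneric("latticeCoords"))

#' @rdname latticeCoords
#' @export
setMethod("latticeCoords", "SpotDataset", function(x) {
  cd <- colData(x)
  cbind(row = as.integer(cd$array_row), col = as.integer(cd$array_col))
})

#' @rdname latticeCoords
#' @export
setMethod("latticeCoords", "VirtualImage", function(x) x@spot_index)

#' PCA accessors
#' @param x a PcaModel.
#' @name pca-accessors
NULL

#' @rdname pca-accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname pca-accessors
#' @export
setMethod("pcaScores", "PcaModel", function(x) x@scores)
#' @rdname pca-accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname pca-accessors
#' @export
setMethod("pcaLoadings", "PcaModel", function(x) x@loadings)
#' @rdname pca-accessors
#' @export
setGeneric("pcaMean", function(x) standardGeneric("pcaMean"))
#' @rdname pca-accessors
#' @export
setMethod("pcaMean", "PcaModel", function(x) x@mean)

#' Graph accessors
#' @param x a SpotGraph.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname graph-accessors
#' @export
setMethod("adjacency", "SpotGraph", function(x) x@A)
#' @rdname graph-accessors
#' @export
setGeneric("laplacian", function(x) standardGeneric("laplacian"))
#' @rdname graph-accessors
#' @export
setMethod("laplacian", "SpotGraph", function(x) x@L)
#' @rdname graph-accessors
#' @export
setGeneric("graphSigma", function(x) standardGeneric("graphSigma"))
#' @rdname graph-accessors
#' @export
setMethod("graphSigma", "SpotGraph", function(x) x@sigma)

#' Pre-clustering accessors
#' @param x a PreClusterResult.
#' @name precluster-accessors
NULL

#' @rdname precluster-accessors
#' @export
setGeneric("preLabels", function(x) standardGeneric("preLabels"))
#' @rdname precluster-accessors
#' @export
setMethod("preLabels", "PreClusterResult", function(x) x@labels)
#' @rdname precluster-accessors
#' @export
setGeneric("intraTrace", function(x) standardGeneric("intraTrace"))
#' @rdname precluster-accessors
#' @export
setMethod("intraTrace", "PreClusterResult", function(x) x@intra_trace)

#' Virtual image accessors
#' @param x a VirtualImage.
#' @name image-accessors
NULL

#' @rdname image-accessors
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))
#' @rdname image-accessors
#' @export
setMethod("imageArray", "VirtualImage", function(x) x@X)
#' @rdname image-accessors
#' @export
setGeneric("pixelClass", function(x) standardGeneric("pixelClass"))
#' @rdname image-accessors
#' @export
setMethod("pixelClass", "VirtualImage", function(x) x@pixel_class)
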