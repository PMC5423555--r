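# Accessor generics (Bioconductor style: accessors, never slot access).

#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @export
setGeneric("gridDirection", function(x) standardGeneric("gridDirection"))
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @export
setGeneric("fovMask", function(x) standardGeneric("fovMask"))
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
#' @export
setGeneric("probArray", function(x) standardGeneric("probArray"))
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))
#' @export
setGeneric("t2Volume", function(x) standardGeneric("t2Volume"))
#' @export
setGeneric("t1Volume", function(x) standardGeneric("t1Volume"))
#' @export
setGeneric("ctVolume", function(x) standardGeneric("ctVolume"))
#' @export
setGeneric("segVolume", function(x) standardGeneric("segVolume"))
#' @export
setGeneric("isFlipped", function(x) standardGeneric("isFlipped"))
#' @export
setGeneric("atlasRecords", function(x) standardGeneric("atlasRecords"))
#' @export
setGeneric("labelDict", function(x) standardGeneric("labelDict"))
#' @export
setGeneric("similarityScores", function(x) standardGeneric("similarityScores"))
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @export
setGeneric("fusionWeights", function(x) standardGeneric("fusionWeights"))
#' @export
setGeneric("fusableMask", function(x) standardGeneric("fusableMask"))
#' @export
setGeneric("atlasRanks", function(x) standardGeneric("atlasRanks"))
#' @export
setGeneric("transformAffine", function(x) standardGeneric("transformAffine"))
#' @export
setGeneric("displacementField", function(x) standardGeneric("displacementField"))
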