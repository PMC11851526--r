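#' @import methods
NULL

#' @rdname LandmarkSequence-class
#' @param x,object A package object.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("segmentId", function(x) standardGeneric("segmentId"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("segmentClass", function(x) standardGeneric("segmentClass"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("auPresence", function(x) standardGeneric("auPresence"))

#' @rdname LandmarkSequence-class
#' @export
setGeneric("auIntensity", function(x) standardGeneric("auIntensity"))

#' @rdname LandmarkDataset-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname LandmarkDataset-class
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
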