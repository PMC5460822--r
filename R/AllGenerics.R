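#' @name RadTex3D-generics
#' @title Accessor generics
#' @description Accessors for the pipeline's S4 classes. \code{counts} is
#'   the BiocGenerics generic, with methods for
#'   \linkS4class{CooccurrenceMatrix} and \linkS4class{RunLengthMatrix}.
#' @param x,object An object of the documented class.
#' @param ... Further arguments (unused).
#' @keywords internal
NULL

#' @rdname RadTex3D-generics
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("maxRunLength", function(x) standardGeneric("maxRunLength"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("phantomMask", function(x) standardGeneric("phantomMask"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("meanCV", function(x) standardGeneric("meanCV"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("sdCV", function(x) standardGeneric("sdCV"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("robustFlags", function(x) standardGeneric("robustFlags"))

#' @rdname RadTex3D-generics
#' @export
setGeneric("overallRobust", function(x) standardGeneric("overallRobust"))
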