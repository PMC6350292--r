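#' @rdname GCComposition-class
#' @param x,object An object.
#' @export
setGeneric("compositionTable", function(x) standardGeneric("compositionTable"))

#' @rdname OxygenPairSet-class
#' @param x,object An object.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname GCComposition-class
#' @export
setGeneric("organismIds", function(x) standardGeneric("organismIds"))

#' @rdname PGLSFit-class
#' @param x,object An object.
#' @export
setGeneric("lambdaHat", function(x) standardGeneric("lambdaHat"))
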