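#' @rdname IonImageStack-class
#' @param object,x an object.
#' @export
setGeneric("ionSpecies", function(x) standardGeneric("ionSpecies"))

#' @rdname IonImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname IonImageStack-class
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))

#' @rdname IonImageStack-class
#' @param species character(1), a species identifier.
#' @export
setGeneric("ionCounts", function(x, species) standardGeneric("ionCounts"))

#' Drift-correct a multi-plane ion image stack
#'
#' @param stack an [IonImageStack-class].
#' @param ... passed to methods.
#' @export
setGeneric("driftCorrect", function(stack, ...) standardGeneric("driftCorrect"))

#' Accumulate (sum) planes of an ion image stack
#'
#' @param stack an [IonImageStack-class].
#' @param ... passed to methods.
#' @export
setGeneric("accumulate", function(stack, ...) standardGeneric("accumulate"))
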