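#' @rdname ShadowFrame-class
#' @param object a `ShadowFrame`
#' @export
setGeneric("frameImage", function(object) standardGeneric("frameImage"))

#' @rdname ShadowFrame-class
#' @export
setGeneric("frameCells", function(object) standardGeneric("frameCells"))

#' @rdname ShadowFrame-class
#' @export
setGeneric("frameConfig", function(object) standardGeneric("frameConfig"))

#' @describeIn ShadowFrame-class the pixel matrix of the frame
setMethod("frameImage", "ShadowFrame", function(object) object@image)

#' @describeIn ShadowFrame-class the ground-truth cell table
setMethod("frameCells", "ShadowFrame", function(object) object@cells)

#' @describeIn ShadowFrame-class the optical configuration
setMethod("frameConfig", "ShadowFrame", function(object) object@config)

#' @rdname ShadowNet-class
#' @param object a `ShadowNet`
#' @export
setGeneric("modelHistory", function(object) standardGeneric("modelHistory"))

#' @describeIn ShadowNet-class per-epoch training history
setMethod("modelHistory", "ShadowNet", function(object) object@history)

#' @rdname ShadowNet-class
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))

#' @describeIn ShadowNet-class the architecture specification
setMethod("modelSpec", "ShadowNet", function(object) object@spec)
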