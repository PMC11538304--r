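#' @name accessors
#' @title Accessors for FlowTensor and CPModel objects
#' @description Slot access for the package's S4 containers.
#' @param x a \code{\linkS4class{FlowTensor}}, \code{\linkS4class{CPModel}}
#'   or \code{\linkS4class{MigrationSystem}} object.
#' @return The requested slot: arrays for \code{flowValues}/\code{flowMask},
#'   matrices for the factor accessors, character label vectors, numeric
#'   vectors for \code{systemScales}/\code{objectiveTrace}.
NULL

#' @rdname accessors
#' @export
setGeneric("flowValues", function(x) standardGeneric("flowValues"))
#' @rdname accessors
#' @export
setGeneric("flowMask", function(x) standardGeneric("flowMask"))
#' @rdname accessors
#' @export
setGeneric("geoLabels", function(x) standardGeneric("geoLabels"))
#' @rdname accessors
#' @export
setGeneric("periodLabels", function(x) standardGeneric("periodLabels"))
#' @rdname accessors
#' @export
setGeneric("originFactors", function(x) standardGeneric("originFactors"))
#' @rdname accessors
#' @export
setGeneric("destFactors", function(x) standardGeneric("destFactors"))
#' @rdname accessors
#' @export
setGeneric("temporalFactors", function(x) standardGeneric("temporalFactors"))
#' @rdname accessors
#' @export
setGeneric("systemScales", function(x) standardGeneric("systemScales"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("shockPeriods", function(x) standardGeneric("shockPeriods"))

#' Reconstruct the dense tensor implied by a CP model
#'
#' @param object a \code{\linkS4class{CPModel}}.
#' @return The \code{I x I x K} array \code{sum_f lambda_f a_f o b_f o c_f},
#'   with dimnames from the model's labels. All entries are nonnegative.
#' @export
setGeneric("reconstruct", function(object) standardGeneric("reconstruct"))

#' Masked least-squares objective of a model on a flow tensor
#'
#' Computes \code{|| W (*) (X - Xhat) ||_F^2}, the squared Frobenius norm of
#' the reconstruction error restricted to masked-in cells. Cells with mask 0
#' (the diagonal, plus any declared-missing cells) contribute exactly
#' nothing.
#'
#' @param x a \code{\linkS4class{FlowTensor}}.
#' @param model a \code{\linkS4class{CPModel}} on the same labels.
#' @return A nonnegative scalar.
#' @export
setGeneric("maskedObjective", function(x, model) standardGeneric("maskedObjective"))

setMethod("flowValues", "FlowTensor", function(x) x@values)
setMethod("flowMask", "FlowTensor", function(x) x@mask)
setMethod("geoLabels", "FlowTensor", function(x) x@geo)
setMethod("periodLabels", "FlowTensor", function(x) x@periods)
setMethod("geoLabels", "CPModel", function(x) x@geo)
setMethod("periodLabels", "CPModel", function(x) x@periods)
setMethod("originFactors", "CPModel", function(x) x@A)
setMethod("destFactors", "CPModel", function(x) x@B)
setMethod("temporalFactors", "CPModel", function(x) x@C)
setMethod("systemScales", "CPModel", function(x) x@lambda)
setMethod("nComponents", "CPModel", function(x) ncol(x@A))
setMethod("objectiveTrace", "CPModel", function(x) x@objectiveTrace)
setMethod("shockPeriods", "PlantedTruth", function(x) x@shockPeriods)

#' @describeIn FlowTensor-class tensor extents \code{c(I, I, K)}.
#' @param x a \code{FlowTensor}.
setMethod("dim", "FlowTensor", function(x) dim(x@values))

setMethod("reconstruct", "CPModel", function(object) {
  out <- .cpRecon(object@A, object@B, object@C, object@lambda)
  dimnames(out) <- list(object@geo, object@geo, object@periods)
  out
})

setMethod("maskedObjective", signature("FlowTensor", "CPModel"),
  function(x, model) {
    if (!identical(dim(x@values)[1], nrow(model@A)) ||
        !identical(dim(x@values)[3], nrow(model@C)))
      stop("tensor and model shapes do not agree")
    sum(x@mask * (x@values - reconstruct(model))^2)
  })
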