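#' @name latchSim-generics
#' @title Generics for latchSim classes
#' @description Accessor and computation generics shared across the model
#'   classes.  See the class pages for method details.
#' @param object,traj an object of the documented class.
#' @param ... passed to methods.
NULL

#' @rdname latchSim-generics
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @rdname latchSim-generics
#' @export
setGeneric("stateMatrix", function(object) standardGeneric("stateMatrix"))

#' @rdname latchSim-generics
#' @export
setGeneric("trajectoryTimes", function(object) standardGeneric("trajectoryTimes"))

#' @rdname latchSim-generics
#' @export
setGeneric("fractionLR", function(traj, ...) standardGeneric("fractionLR"))

#' @rdname latchSim-generics
#' @export
setGeneric("counterBits", function(object) standardGeneric("counterBits"))

#' @rdname latchSim-generics
#' @export
setGeneric("counterValue", function(object) standardGeneric("counterValue"))

#' @rdname latchSim-generics
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname latchSim-generics
#' @export
setGeneric("populationCells", function(object) standardGeneric("populationCells"))
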