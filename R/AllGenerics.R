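#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objective", function(object) standardGeneric("objective"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objective<-", function(object, value) standardGeneric("objective<-"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("bounds", function(object, reaction) standardGeneric("bounds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("setBounds", function(object, reaction, lower = NULL, upper = NULL)
  standardGeneric("setBounds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("subsystems", function(object) standardGeneric("subsystems"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("isExchange", function(object) standardGeneric("isExchange"))

#' @rdname FluxSolution-accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxSolution-accessors
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname FluxSolution-accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname YieldTable-accessors
#' @export
setGeneric("yields", function(object) standardGeneric("yields"))

#' @rdname YieldTable-accessors
#' @export
setGeneric("cellStatus", function(object) standardGeneric("cellStatus"))
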