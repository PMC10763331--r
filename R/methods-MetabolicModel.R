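#' Accessors for MetabolicModel objects
#'
#' `metabolites()` and `reactions()` return the underlying tables;
#' `metaboliteIds()`/`reactionIds()` the id vectors; `objective()` the
#' objective (reaction id + direction); `bounds()` a named `c(lower, upper)`
#' pair for one reaction; `setBounds()` returns a modified copy;
#' `subsystems()` the subsystem of every reaction; `isExchange()` a logical
#' vector flagging exchange reactions (exactly one metabolite).
#'
#' @param object a [MetabolicModel-class]
#' @param reaction a reaction id
#' @param lower,upper new bounds (mmol/gDW/h); `NULL` leaves a bound unchanged
#' @param value for `objective<-`, a list with `reaction` and `direction`
#' @return see Description; `setBounds()` and `objective<-` return the
#'   modified model.
#' @name MetabolicModel-accessors
#' @aliases metabolites reactions metaboliteIds reactionIds objective
#'   objective<- bounds setBounds subsystems isExchange
#' @examples
#' mod <- buildCoreModel()
#' head(reactionIds(mod))
#' bounds(mod, "EX_meoh_e")
#' mod2 <- setBounds(mod, "EX_meoh_e", lower = -5)
NULL

#' @rdname MetabolicModel-accessors
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname MetabolicModel-accessors
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname MetabolicModel-accessors
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)

#' @rdname MetabolicModel-accessors
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)

#' @rdname MetabolicModel-accessors
setMethod("objective", "MetabolicModel", function(object) object@objective)

#' @rdname MetabolicModel-accessors
setMethod("objective<-", "MetabolicModel", function(object, value) {
  stopifnot(is.list(value), all(c("reaction", "direction") %in% names(value)))
  object@objective <- value[c("reaction", "direction")]
  validObject(object)
  object
})

.rxnIndex <- function(object, reaction) {
  i <- match(reaction, object@reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction, call. = FALSE)
  i
}

#' @rdname MetabolicModel-accessors
setMethod("bounds", "MetabolicModel", function(object, reaction) {
  i <- .rxnIndex(object, reaction)
  c(lower = object@reactions$lower_bound[i], upper = object@reactions$upper_bound[i])
})

#' @rdname MetabolicModel-accessors
setMethod("setBounds", "MetabolicModel", function(object, reaction, lower = NULL, upper = NULL) {
  i <- .rxnIndex(object, reaction)
  if (!is.null(lower)) object@reactions$lower_bound[i] <- lower
  if (!is.null(upper)) object@reactions$upper_bound[i] <- upper
  if (object@reactions$lower_bound[i] > object@reactions$upper_bound[i]) {
    stop("lower_bound > upper_bound for reaction ", reaction, call. = FALSE)
  }
  object
})

#' @rdname MetabolicModel-accessors
setMethod("subsystems", "MetabolicModel", function(object) {
  setNames(object@reactions$subsystem, object@reactions$id)
})

#' @rdname MetabolicModel-accessors
setMethod("isExchange", "MetabolicModel", function(object) {
  setNames(vapply(object@reactions$metabolites, length, integer(1)) == 1L &
    startsWith(object@reactions$id, "EX_"), object@reactions$id)
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel", sQuote(object@id), "\n")
  cat("  metabolites:", nrow(object@metabolites), "\n")
  cat("  reactions:  ", nrow(object@reactions),
    sprintf("(%d exchange)", sum(isExchange(object))), "\n")
  cat("  subsystems: ", length(unique(object@reactions$subsystem)), "\n")
  if (length(object@objective)) {
    cat("  objective:  ", object@objective$direction, object@objective$reaction, "\n")
  }
})

#' Accessors for FluxSolution objects
#'
#' @param object a [FluxSolution-class]
#' @return `fluxes()` the named flux vector; `solutionStatus()` the LP
#'   status; `objectiveValue()` the optimal objective value.
#' @name FluxSolution-accessors
#' @aliases fluxes solutionStatus objectiveValue
NULL

#' @rdname FluxSolution-accessors
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname FluxSolution-accessors
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

#' @rdname FluxSolution-accessors
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@status, ")\n", sep = "")
  if (object@status == "optimal") {
    cat("  objective value:", format(object@objectiveValue, digits = 6), "\n")
    nz <- sum(abs(object@fluxes) > 1e-9)
    cat("  fluxes:", length(object@fluxes), sprintf("(%d nonzero)", nz), "\n")
  }
})

#' Accessors for YieldTable objects
#'
#' @param object a [YieldTable-class]
#' @return `yields()` the product x scenario yield matrix (mol/mol);
#'   `cellStatus()` the matching matrix of LP statuses.
#' @name YieldTable-accessors
#' @aliases yields cellStatus
NULL

#' @rdname YieldTable-accessors
setMethod("yields", "YieldTable", function(object) object@yields)

#' @rdname YieldTable-accessors
setMethod("cellStatus", "YieldTable", function(object) object@status)

setMethod("show", "YieldTable", function(object) {
  cat("YieldTable (mol product / mol methanol)\n")
  print(round(object@yields, 4))
  if (any(object@status != "optimal")) {
    cat("non-optimal cells:",
      sum(object@status != "optimal"), "(see cellStatus())\n")
  }
})
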