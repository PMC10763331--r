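#' @import methods
#' @importFrom stats cov dist hclust prcomp setNames var
#' @importFrom utils read.delim write.csv head
NULL

VALID_COMPARTMENTS <- c("cytosol", "mitochondrion", "peroxisome", "extracellular")
TRACKED_ELEMENTS <- c("C", "H", "O", "N", "P", "S")

#' Stoichiometric metabolic network
#'
#' An S4 container for a compartmentalised stoichiometric model: metabolites
#' with elemental formulas, reactions with flux bounds (mmol/gDW/h) and
#' stoichiometries, and a single linear objective. This is the substrate for
#' flux balance analysis ([solveFBA()]) and all downstream analyses.
#'
#' @slot metabolites a `data.frame` with columns `id`, `name`, `compartment`
#'   (one of cytosol, mitochondrion, peroxisome, extracellular), `formula`
#'   (Hill-style elemental formula over C,H,O,N,P,S; may be `NA`), and
#'   `charge` (integer, may be `NA`).
#' @slot reactions a `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, and a list-column `metabolites` of named
#'   numeric vectors (metabolite id -> stoichiometric coefficient, negative
#'   = consumed).
#' @slot objective a list with elements `reaction` (a reaction id) and
#'   `direction` (`"max"` or `"min"`).
#' @slot id a model identifier string.
#'
#' @seealso [buildCoreModel()], [readMetabolicModel()], [solveFBA()]
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    objective = "list",
    id = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  need_met <- c("id", "name", "compartment", "formula", "charge")
  need_rxn <- c("id", "name", "lower_bound", "upper_bound", "subsystem", "metabolites")
  if (!all(need_met %in% names(met))) {
    msgs <- c(msgs, paste("metabolites must have columns:", paste(need_met, collapse = ", ")))
  }
  if (!all(need_rxn %in% names(rxn))) {
    msgs <- c(msgs, paste("reactions must have columns:", paste(need_rxn, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(met$id)) {
    msgs <- c(msgs, paste("duplicate metabolite id:", met$id[duplicated(met$id)][1]))
  }
  if (anyDuplicated(rxn$id)) {
    msgs <- c(msgs, paste("duplicate reaction id:", rxn$id[duplicated(rxn$id)][1]))
  }
  bad_comp <- setdiff(unique(met$compartment), VALID_COMPARTMENTS)
  if (length(bad_comp)) {
    msgs <- c(msgs, paste("unknown compartment:", paste(bad_comp, collapse = ", ")))
  }
  if (nrow(rxn)) {
    if (any(rxn$lower_bound > rxn$upper_bound)) {
      bad <- rxn$id[rxn$lower_bound > rxn$upper_bound][1]
      msgs <- c(msgs, paste("lower_bound > upper_bound for reaction", bad))
    }
    nstoich <- vapply(rxn$metabolites, length, integer(1))
    if (any(nstoich == 0L)) {
      msgs <- c(msgs, paste("empty stoichiometry for reaction", rxn$id[nstoich == 0L][1]))
    }
    unknown <- setdiff(unique(unlist(lapply(rxn$metabolites, names))), met$id)
    if (length(unknown)) {
      msgs <- c(msgs, paste("stoichiometry references unknown metabolite:", unknown[1]))
    }
  }
  if (length(object@objective)) {
    if (!all(c("reaction", "direction") %in% names(object@objective))) {
      msgs <- c(msgs, "objective must have elements 'reaction' and 'direction'")
    } else {
      if (!object@objective$reaction %in% rxn$id) {
        msgs <- c(msgs, paste("objective reaction not in model:", object@objective$reaction))
      }
      if (!object@objective$direction %in% c("max", "min")) {
        msgs <- c(msgs, "objective direction must be 'max' or 'min'")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Flux solution of a linear programme
#'
#' Result of one flux balance analysis solve: solver status, objective value,
#' and one flux per reaction (mmol/gDW/h). For `status == "optimal"` the flux
#' vector satisfies steady state (max |S v| < 1e-6) and all bounds.
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @slot objectiveValue the optimal objective value (`NA` unless optimal).
#' @slot fluxes named numeric vector of fluxes (empty unless optimal).
#'
#' @seealso [solveFBA()], [fluxes()], [computeYield()]
#' @export
setClass("FluxSolution",
  representation(status = "character", objectiveValue = "numeric", fluxes = "numeric")
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded")) {
    return("status must be optimal, infeasible or unbounded")
  }
  if (object@status == "optimal" && is.null(names(object@fluxes)) && length(object@fluxes)) {
    return("fluxes must be named by reaction id")
  }
  TRUE
})

#' Product x scenario yield grid
#'
#' Molar yields (mol product per mol methanol) of optimal target production
#' for each product under each pathway scenario, with per-cell LP status.
#'
#' @slot yields numeric matrix, products in rows, scenarios in columns.
#' @slot status character matrix of LP statuses, same shape as `yields`.
#'
#' @seealso [runScenarioMatrix()]
#' @export
setClass("YieldTable",
  representation(yields = "matrix", status = "matrix")
)

setValidity("YieldTable", function(object) {
  if (!identical(dim(object@yields), dim(object@status))) {
    return("yields and status must have identical dimensions")
  }
  ok <- object@yields[object@status == "optimal"]
  if (length(ok) && any(ok < -1e-9)) return("yields must be non-negative")
  TRUE
})
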