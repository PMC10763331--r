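# The five pathway scenarios (Ref, TCA-, TCA+, GlxStd, GlxVar) over the
# three products, including the feasibility-extreme bound calibration, and
# the product x scenario yield grid.

#' The five pathway scenarios
#'
#' Built-in scenario definitions as bound-edit lists over literature
#' reaction aliases (resolved by [referenceReactionAliases()]):
#' \describe{
#'   \item{Ref}{unconstrained reference: methanol uptake and product
#'     objective only}
#'   \item{TCA-}{blocked TCA: upper bound 0 for the PDH isoforms,
#'     ATP-citrate lyase, 2-oxoglutarate dehydrogenase, citrate
#'     transporters and citrate synthase}
#'   \item{TCA+}{forced TCA: 2-oxoglutarate dehydrogenase lower bound at
#'     the maximum flux that still supports a feasible solution}
#'   \item{GlxStd}{forced glyoxylate shunt: isocitrate lyase lower bound at
#'     its feasible maximum}
#'   \item{GlxVar}{forced, impaired glyoxylate shunt: GlxStd plus the
#'     mitochondrial malate dehydrogenase pinned to its feasible minimum}
#' }
#' Calibrated edits carry the directive `"calibrate:max"` or
#' `"calibrate:min"` and are resolved against the model with all previous
#' edits of the same scenario applied (so the GlxVar MDH calibration runs
#' on the GlxStd-forced model).
#'
#' @param uptake methanol uptake rate used in the GlxVar reverse-bound edit
#' @return a named list of scenario specifications, each a list with
#'   `name` and `edits` (list of `list(alias, bound, value)`)
#' @examples
#' names(scenarioSpecs())
#' @export
scenarioSpecs <- function(uptake = 10) {
  edit <- function(alias, bound, value) list(alias = alias, bound = bound, value = value)
  blocked <- c("PDHa1", "PDHcm", "ACLSm", "AKGDH1+2", "CITtam", "CITtap", "CSp+m")
  list(
    "Ref" = list(name = "Ref", edits = list()),
    "TCA-" = list(name = "TCA-",
      edits = lapply(blocked, edit, bound = "upper", value = 0)),
    "TCA+" = list(name = "TCA+",
      edits = list(edit("AKGDam", "lower", "calibrate:max"))),
    "GlxStd" = list(name = "GlxStd",
      edits = list(edit("ICL", "lower", "calibrate:max"))),
    "GlxVar" = list(name = "GlxVar",
      edits = list(
        edit("ICL", "lower", "calibrate:max"),
        edit("MDHm", "lower", -uptake),
        edit("MDHm", "upper", "calibrate:min")))
  )
}

#' Read scenario definitions from a YAML or JSON config
#'
#' Parses a scenario configuration file into the list structure of
#' [scenarioSpecs()]. The file holds a list of scenarios, each with a
#' `name` and an `edits` list of `{alias, bound, value}` entries; `value`
#' is a number or one of the directives `"calibrate:max"` /
#' `"calibrate:min"`. A bundled config mirroring the built-in five
#' scenarios ships as `system.file("extdata", "scenarios.yaml",
#' package = "methflux")`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a named list of scenario specifications
#' @export
readScenarioConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (!is.list(doc) || !length(doc)) {
    stop("scenario config ", path, " holds no scenarios", call. = FALSE)
  }
  out <- lapply(doc, function(sc) {
    if (is.null(sc$name)) stop("scenario without a name in ", path, call. = FALSE)
    edits <- lapply(sc$edits %||% list(), function(ed) {
      if (is.null(ed$alias) || is.null(ed$bound) || is.null(ed$value)) {
        stop("scenario '", sc$name, "': every edit needs alias, bound, value",
          call. = FALSE)
      }
      if (!ed$bound %in% c("lower", "upper", "both")) {
        stop("scenario '", sc$name, "': bound must be lower/upper/both",
          call. = FALSE)
      }
      list(alias = ed$alias, bound = ed$bound, value = ed$value)
    })
    list(name = sc$name, edits = edits)
  })
  setNames(out, vapply(out, `[[`, "", "name"))
}

#' Calibrate a forced flux bound
#'
#' Returns the extreme (`"max"` or `"min"`) feasible flux of a reaction,
#' found by flux variability with no objective fixing, pulled back by a
#' relative slack so that forcing a bound at the returned value leaves the
#' model feasible.
#'
#' @param model a feasible [MetabolicModel-class]
#' @param reaction reaction id
#' @param direction `"max"` or `"min"`
#' @param slack relative slack (default 1e-6)
#' @return the calibrated bound value (mmol/gDW/h)
#' @examples
#' mod <- buildCoreModel()
#' calibrateForcedBound(mod, "AKGDm", "max")
#' @export
calibrateForcedBound <- function(model, reaction, direction = c("max", "min"),
                                 slack = 1e-6) {
  direction <- match.arg(direction)
  fv <- fluxVariability(model, reaction)
  if (direction == "max") fv$max - abs(fv$max) * slack
  else fv$min + abs(fv$min) * slack
}

#' Apply a pathway scenario to a model
#'
#' Returns a copy of the model with the scenario's bound edits applied (the
#' input is untouched) and the shared setup in place: methanol uptake fixed
#' to `-uptake` (lower bound of the methanol exchange) and, if `product`
#' is given, the objective set to maximise that product's exchange.
#' Aliases are resolved case-insensitively; an unmapped alias is a
#' configuration error naming the alias. `"calibrate:max"`/`"calibrate:min"`
#' edit values are computed with [calibrateForcedBound()] on the model with
#' all preceding edits applied.
#'
#' @param model a [MetabolicModel-class]
#' @param spec one element of [scenarioSpecs()]
#' @param aliases alias map from [referenceReactionAliases()]; default is
#'   computed from the model
#' @param product optional product name or exchange id for the objective
#' @param uptake methanol uptake rate (default 10 mmol/gDW/h)
#' @return the edited model
#' @examples
#' mod <- buildCoreModel()
#' tcaMinus <- applyScenario(mod, scenarioSpecs()[["TCA-"]], product = "malate")
#' bounds(tcaMinus, "AKGDm")
#' @export
applyScenario <- function(model, spec, aliases = referenceReactionAliases(model),
                          product = NULL, uptake = 10) {
  stopifnot(is(model, "MetabolicModel"), is.list(spec), !is.null(spec$edits))
  out <- setBounds(model, "EX_meoh_e", lower = -uptake, upper = 0)
  for (ed in spec$edits) {
    i <- match(tolower(ed$alias), tolower(aliases$alias))
    if (is.na(i)) stop("unknown reaction alias: ", ed$alias, call. = FALSE)
    if (is.na(aliases$reaction[i])) {
      warning("skipping edit for unmapped alias '", ed$alias, "' (",
        aliases$note[i], ")")
      next
    }
    rid <- aliases$reaction[i]
    value <- ed$value
    if (is.character(value)) {
      dir <- switch(value,
        "calibrate:max" = "max",
        "calibrate:min" = "min",
        stop("unknown edit directive '", value, "' for alias ", ed$alias,
          call. = FALSE))
      value <- calibrateForcedBound(out, rid, dir)
    }
    out <- switch(ed$bound,
      lower = setBounds(out, rid, lower = value),
      upper = setBounds(out, rid, upper = value),
      both = setBounds(out, rid, lower = value, upper = value),
      stop("unknown bound selector '", ed$bound, "'", call. = FALSE))
  }
  if (!is.null(product)) {
    targets <- productTargets()
    ex <- if (product %in% targets$name) {
      targets$exchange_reaction[match(product, targets$name)]
    } else product
    objective(out) <- list(reaction = ex, direction = "max")
  }
  out
}

#' Run the product x scenario yield grid
#'
#' For every combination of product and scenario, applies the scenario,
#' maximises the product exchange, and records the mol/mol yield. With the
#' default three products and five scenarios this is the 15-cell simulation
#' grid. Infeasible cells are reported with status `"infeasible"`, yield 0,
#' and a warning - never silently dropped.
#'
#' @param model a model from [buildCoreModel()]
#' @param products a `data.frame` from [productTargets()]
#' @param scenarios a list from [scenarioSpecs()]
#' @param uptake methanol uptake rate (default 10 mmol/gDW/h)
#' @param keep_solutions store the 15 parsimonious flux solutions (for
#'   [assembleFluxMatrix()]) in the returned object
#' @return a [YieldTable-class]; if `keep_solutions`, the solutions are in
#'   `attr(, "solutions")`, named `"<product>|<scenario>"`
#' @examples
#' \donttest{
#' tab <- runScenarioMatrix(buildCoreModel())
#' yields(tab)
#' }
#' @export
runScenarioMatrix <- function(model, products = productTargets(),
                              scenarios = scenarioSpecs(uptake),
                              uptake = 10, keep_solutions = FALSE) {
  stopifnot(is(model, "MetabolicModel"), nrow(products) >= 1, length(scenarios) >= 1)
  aliases <- referenceReactionAliases(model)
  snames <- unname(vapply(scenarios, `[[`, "", "name"))
  ymat <- matrix(0, nrow(products), length(scenarios),
    dimnames = list(products$name, snames))
  smat <- matrix("optimal", nrow(products), length(scenarios),
    dimnames = dimnames(ymat))
  sols <- list()
  for (j in seq_along(scenarios)) {
    scen <- applyScenario(model, scenarios[[j]], aliases, uptake = uptake)
    for (i in seq_len(nrow(products))) {
      ex <- products$exchange_reaction[i]
      sol <- solveFBA(scen, ex, "max", parsimonious = TRUE)
      smat[i, j] <- solutionStatus(sol)
      if (solutionStatus(sol) == "optimal") {
        # a zero optimum can come with zero uptake under the parsimonious
        # refinement; the yield is 0 without dividing by the uptake
        ymat[i, j] <- if (objectiveValue(sol) < 1e-9) 0
          else computeYield(sol, ex, "EX_meoh_e")
        if (keep_solutions) {
          sols[[paste(products$name[i], snames[j], sep = "|")]] <- sol
        }
      } else {
        ymat[i, j] <- 0
        warning("scenario cell (", products$name[i], ", ", snames[j], ") is ",
          solutionStatus(sol), "; yield reported as 0")
      }
    }
  }
  out <- new("YieldTable", yields = ymat, status = smat)
  if (keep_solutions) attr(out, "solutions") <- sols
  out
}

#' Export a yield table
#'
#' Writes the yield grid as CSV and returns a Markdown rendering of the
#' table (products in rows, scenarios in columns).
#'
#' @param table a [YieldTable-class]
#' @param path optional CSV output path
#' @param digits rounding for display (default 2, matching the precision
#'   such tables are usually printed at)
#' @return invisibly, the Markdown lines (character vector)
#' @export
formatYieldTable <- function(table, path = NULL, digits = 2) {
  stopifnot(is(table, "YieldTable"))
  y <- yields(table)
  if (!is.null(path)) {
    df <- data.frame(product = rownames(y), round(y, 6), check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  header <- paste0("| product | ", paste(colnames(y), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(y) + 1), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(y)), function(i) {
    paste0("| ", rownames(y)[i], " | ",
      paste(format(round(y[i, ], digits), trim = TRUE), collapse = " | "), " |")
  }, "")
  invisible(c(header, sep, body))
}
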