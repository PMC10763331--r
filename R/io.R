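# Model I/O: COBRA-dialect JSON (canonical) and a TSV reaction-table dialect.

.COMP_CODE <- c(cytosol = "c", mitochondrion = "m", peroxisome = "x", extracellular = "e")
.COMP_NAME <- setNames(names(.COMP_CODE), .COMP_CODE)

#' Construct a MetabolicModel from component tables
#'
#' Low-level constructor used by the readers and by [buildCoreModel()].
#' Validates id uniqueness, bound ordering, and stoichiometry closure.
#'
#' @param metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`
#' @param reactions `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem` and a list-column `metabolites`
#' @param objective list with `reaction` and `direction` (`"max"`/`"min"`)
#' @param id model identifier
#' @return a validated [MetabolicModel-class]
#' @export
newMetabolicModel <- function(metabolites, reactions, objective = list(), id = "model") {
  new("MetabolicModel",
    metabolites = metabolites, reactions = reactions,
    objective = objective, id = id)
}

#' Read a metabolic model
#'
#' Reads the COBRA-dialect JSON (canonical, round-trip safe) or the TSV
#' reaction-table dialect (columns `id`, `equation`, `lower_bound`,
#' `upper_bound`, `subsystem`; metabolite compartments inferred from the
#' `_c`/`_m`/`_x`/`_e` id suffix, formulas unavailable). Unknown optional
#' JSON fields are ignored with a warning.
#'
#' @param path file path
#' @param format `"json"` or `"tsv"`; default guessed from the extension
#' @return a validated [MetabolicModel-class]
#' @seealso [writeMetabolicModel()]
#' @export
readMetabolicModel <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "json") .readModelJSON(path) else .readModelTSV(path)
}

.readModelJSON <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse error in ", path, ": ",
      conditionMessage(e), call. = FALSE))
  known_top <- c("id", "name", "compartments", "metabolites", "reactions",
    "genes", "objective_direction", "version")
  extra <- setdiff(names(doc), known_top)
  if (length(extra)) {
    warning("ignoring unknown model fields: ", paste(extra, collapse = ", "))
  }
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("JSON model in ", path, " lacks a 'metabolites' or 'reactions' key",
      call. = FALSE)
  }
  comp <- unlist(doc$compartments %||% list())

  g <- function(x, key, default = NA) if (is.null(x[[key]])) default else x[[key]]
  met <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(g(m, "id")), ""),
    name = vapply(doc$metabolites, function(m) as.character(g(m, "name", "")), ""),
    compartment = vapply(doc$metabolites, function(m) {
      code <- as.character(g(m, "compartment", ""))
      if (code %in% names(.COMP_NAME)) .COMP_NAME[[code]]
      else if (code %in% VALID_COMPARTMENTS) code
      else stop("unknown compartment code '", code, "' in ", path, call. = FALSE)
    }, ""),
    formula = vapply(doc$metabolites, function(m) as.character(g(m, "formula")), ""),
    charge = vapply(doc$metabolites, function(m) as.numeric(g(m, "charge")), 0),
    stringsAsFactors = FALSE)
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id in ", path, ": ",
      met$id[duplicated(met$id)][1], call. = FALSE)
  }

  stoich <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st)) {
      stop("reaction ", g(r, "id"), " has empty stoichiometry in ", path,
        call. = FALSE)
    }
    st
  })
  rxn <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(g(r, "id")), ""),
    name = vapply(doc$reactions, function(r) as.character(g(r, "name", "")), ""),
    lower_bound = vapply(doc$reactions, function(r) as.numeric(g(r, "lower_bound", -1000)), 0),
    upper_bound = vapply(doc$reactions, function(r) as.numeric(g(r, "upper_bound", 1000)), 0),
    subsystem = vapply(doc$reactions, function(r) as.character(g(r, "subsystem", "")), ""),
    stringsAsFactors = FALSE)
  rxn$metabolites <- stoich
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id in ", path, ": ",
      rxn$id[duplicated(rxn$id)][1], call. = FALSE)
  }

  objc <- vapply(doc$reactions, function(r) as.numeric(g(r, "objective_coefficient", 0)), 0)
  objective <- list()
  if (any(objc != 0)) {
    objective <- list(reaction = rxn$id[which(objc != 0)[1]],
      direction = as.character(g(doc, "objective_direction", "max")))
  }
  newMetabolicModel(met, rxn, objective, id = as.character(g(doc, "id", "model")))
}

.readModelTSV <- function(path) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("TSV parse error in ", path, ": ",
      conditionMessage(e), call. = FALSE))
  need <- c("id", "equation", "lower_bound", "upper_bound", "subsystem")
  if (!all(need %in% names(tab))) {
    stop("TSV model in ", path, " must have columns: ",
      paste(need, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), need)
  if (length(extra)) warning("ignoring unknown TSV columns: ", paste(extra, collapse = ", "))
  if (anyDuplicated(tab$id)) {
    stop("duplicate reaction id in ", path, ": ",
      tab$id[duplicated(tab$id)][1], call. = FALSE)
  }
  stoich <- lapply(seq_len(nrow(tab)), function(i) {
    .parseEquation(tab$equation[i], tab$id[i])
  })
  mids <- sort(unique(unlist(lapply(stoich, names))))
  suffix <- sub("^.*_([cmxe])$", "\\1", mids)
  comp <- ifelse(suffix %in% names(.COMP_NAME), .COMP_NAME[suffix], "cytosol")
  met <- data.frame(id = mids, name = mids, compartment = unname(comp),
    formula = NA_character_, charge = NA_real_, stringsAsFactors = FALSE)
  rxn <- data.frame(id = tab$id, name = tab$id,
    lower_bound = as.numeric(tab$lower_bound),
    upper_bound = as.numeric(tab$upper_bound),
    subsystem = tab$subsystem, stringsAsFactors = FALSE)
  rxn$metabolites <- stoich
  newMetabolicModel(met, rxn, id = sub("\\.[^.]*$", "", basename(path)))
}

.parseEquation <- function(eq, rxn_id) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L || !nzchar(trimws(eq))) {
    stop("malformed equation for reaction ", rxn_id, ": ", eq, call. = FALSE)
  }
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(); nm <- character()
    for (term in terms) {
      bits <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(bits) == 1L) { coef <- 1; mid <- bits }
      else if (length(bits) == 2L) { coef <- as.numeric(bits[1]); mid <- bits[2] }
      else stop("malformed term '", term, "' in reaction ", rxn_id, call. = FALSE)
      if (is.na(coef)) stop("malformed coefficient in term '", term,
        "' of reaction ", rxn_id, call. = FALSE)
      out <- c(out, sign * coef); nm <- c(nm, mid)
    }
    setNames(out, nm)
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- if (length(sides) == 2L) parseSide(sides[2], 1) else numeric()
  st <- c(lhs, rhs)
  # merge duplicates (metabolite on both sides)
  tapply_sum <- tapply(st, names(st), sum)
  st <- setNames(as.numeric(tapply_sum), names(tapply_sum))
  st[st != 0]
}

.formatEquation <- function(st) {
  fmt <- function(v, nm) {
    paste(vapply(seq_along(v), function(i) {
      if (v[i] == 1) nm[i] else paste(format(v[i], digits = 15, scientific = FALSE), nm[i])
    }, ""), collapse = " + ")
  }
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste(fmt(-unname(lhs), names(lhs)), "->", fmt(unname(rhs), names(rhs)))
}

#' Write a metabolic model
#'
#' Serialises a model to the COBRA-dialect JSON (full fidelity) or the TSV
#' reaction-table dialect (reaction structure only). Output is
#' deterministic: metabolites and reactions are sorted by id and floats are
#' written at full precision, so two writes of the same model are
#' byte-identical.
#'
#' @param model a [MetabolicModel-class]
#' @param path output file path
#' @param format `"json"` or `"tsv"`; default guessed from the extension
#' @return invisibly, `path`
#' @seealso [readMetabolicModel()]
#' @export
writeMetabolicModel <- function(model, path, format = c("auto", "json", "tsv")) {
  stopifnot(is(model, "MetabolicModel"))
  validObject(model)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "json") .writeModelJSON(model, path) else .writeModelTSV(model, path)
  invisible(path)
}

.writeModelJSON <- function(model, path) {
  met <- model@metabolites[order(model@metabolites$id), , drop = FALSE]
  rxn <- model@reactions[order(model@reactions$id), , drop = FALSE]
  obj_rxn <- if (length(model@objective)) model@objective$reaction else ""
  mets <- lapply(seq_len(nrow(met)), function(i) {
    m <- list(
      id = met$id[i],
      name = met$name[i],
      compartment = unname(.COMP_CODE[[met$compartment[i]]]))
    if (!is.na(met$formula[i])) m$formula <- met$formula[i]
    if (!is.na(met$charge[i])) m$charge <- as.integer(met$charge[i])
    m
  })
  rxns <- lapply(seq_len(nrow(rxn)), function(i) {
    st <- rxn$metabolites[[i]]
    st <- st[order(names(st))]
    list(
      id = rxn$id[i],
      name = rxn$name[i],
      metabolites = as.list(st),
      lower_bound = rxn$lower_bound[i],
      upper_bound = rxn$upper_bound[i],
      subsystem = rxn$subsystem[i],
      gene_reaction_rule = "",
      objective_coefficient = if (identical(rxn$id[i], obj_rxn)) 1 else 0)
  })
  comps <- sort(unique(met$compartment))
  doc <- list(
    id = model@id,
    compartments = setNames(as.list(comps), unname(.COMP_CODE[comps])),
    metabolites = mets,
    reactions = rxns,
    genes = list())
  if (length(model@objective)) doc$objective_direction <- model@objective$direction
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2)
  con <- tryCatch(file(path, "wb"),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
      call. = FALSE))
  on.exit(close(con))
  writeLines(json, con)
}

.writeModelTSV <- function(model, path) {
  rxn <- model@reactions[order(model@reactions$id), , drop = FALSE]
  lines <- c("id\tequation\tlower_bound\tupper_bound\tsubsystem",
    vapply(seq_len(nrow(rxn)), function(i) {
      paste(rxn$id[i], .formatEquation(rxn$metabolites[[i]]),
        format(rxn$lower_bound[i], digits = 15, scientific = FALSE),
        format(rxn$upper_bound[i], digits = 15, scientific = FALSE),
        rxn$subsystem[i], sep = "\t")
    }, ""))
  con <- tryCatch(file(path, "wb"),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
      call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
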