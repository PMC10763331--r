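# Elemental bookkeeping: formula parsing and per-reaction balance residuals.

#' Parse a Hill-style elemental formula
#'
#' Converts a formula string such as `"C4H6O5"` or `"CH4O"` into a named
#' count vector over the tracked elements C, H, O, N, P, S. Fractional
#' counts are not supported; element symbols outside the tracked set raise
#' an error.
#'
#' @param formula a single formula string
#' @return named numeric vector over `c("C","H","O","N","P","S")`
#' @examples
#' parseFormula("C4H6O5") # L-malate
#' @export
parseFormula <- function(formula) {
  out <- setNames(numeric(length(TRACKED_ELEMENTS)), TRACKED_ELEMENTS)
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty formula", call. = FALSE)
  }
  rest <- formula
  while (nzchar(rest)) {
    m <- regexpr("^([A-Z][a-z]?)([0-9]*)", rest)
    if (m == -1L) stop("malformed formula: ", formula, call. = FALSE)
    tok <- regmatches(rest, m)
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% TRACKED_ELEMENTS) {
      stop("unsupported element '", sym, "' in formula ", formula, call. = FALSE)
    }
    out[sym] <- out[sym] + if (nzchar(num)) as.numeric(num) else 1
    rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
  }
  out
}

#' Format an element-count vector as a formula string
#'
#' Inverse of [parseFormula()] for non-negative integer counts, in Hill-like
#' C,H,O,N,P,S order. Zero counts are dropped.
#'
#' @param counts named numeric vector over the tracked elements
#' @return a formula string
#' @export
formatFormula <- function(counts) {
  counts <- counts[TRACKED_ELEMENTS]
  counts[is.na(counts)] <- 0
  parts <- character()
  for (el in TRACKED_ELEMENTS) {
    n <- counts[[el]]
    if (n == 0) next
    parts <- c(parts, if (n == 1) el else paste0(el, format(n, scientific = FALSE)))
  }
  if (!length(parts)) "" else paste(parts, collapse = "")
}

#' Check elemental balance of every internal reaction
#'
#' For each non-exchange reaction, sums coefficient-weighted element counts
#' of all participants and reports any nonzero residual for C, H, O, N, P or
#' S. Exchange reactions (single-metabolite system boundaries) are exempt:
#' they are net sources/sinks by design. A missing formula on a metabolite
#' used by an internal reaction is an error.
#'
#' @param model a [MetabolicModel-class]
#' @param tol residuals with absolute value below `tol` count as zero
#' @return a `data.frame` with one row per unbalanced internal reaction:
#'   `reaction`, one column per element with the residual (products minus
#'   substrates), zero rows if the model is fully balanced.
#' @examples
#' mod <- buildCoreModel()
#' validateMassBalance(mod) # zero rows: the core network is balanced
#' @export
validateMassBalance <- function(model, tol = 1e-9) {
  stopifnot(is(model, "MetabolicModel"))
  met <- model@metabolites
  rxn <- model@reactions
  exch <- isExchange(model)
  fmap <- setNames(met$formula, met$id)

  internal <- rxn[!exch, , drop = FALSE]
  residuals <- matrix(0, nrow(internal), length(TRACKED_ELEMENTS),
    dimnames = list(internal$id, TRACKED_ELEMENTS))
  for (i in seq_len(nrow(internal))) {
    st <- internal$metabolites[[i]]
    for (mid in names(st)) {
      f <- fmap[[mid]]
      if (is.na(f) || !nzchar(f)) {
        stop("metabolite ", mid, " used by internal reaction ", internal$id[i],
          " has no formula", call. = FALSE)
      }
      residuals[i, ] <- residuals[i, ] + st[[mid]] * parseFormula(f)
    }
  }
  bad <- apply(abs(residuals) > tol, 1, any)
  out <- data.frame(reaction = internal$id[bad], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(residuals[bad, , drop = FALSE], row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Assemble the stoichiometric matrix
#'
#' Builds the sparse metabolite x reaction matrix S with `S[i, j]` equal to
#' the stoichiometric coefficient of metabolite i in reaction j. Row order
#' follows `metaboliteIds(model)`, column order `reactionIds(model)`.
#'
#' @param model a [MetabolicModel-class]
#' @return a `Matrix::dgCMatrix` with dimnames (metabolite ids, reaction ids)
#' @examples
#' S <- stoichiometricMatrix(buildCoreModel())
#' dim(S)
#' @export
stoichiometricMatrix <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  mids <- model@metabolites$id
  rids <- model@reactions$id
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(rids)) {
    st <- model@reactions$metabolites[[j]]
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
    dims = c(length(mids), length(rids)),
    dimnames = list(mids, rids))
}
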