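# Flux balance analysis on MetabolicModel objects: FBA with a parsimonious
# secondary objective, flux variability, production envelopes, molar yields.

.modelLP <- function(model) {
  S <- as.matrix(stoichiometricMatrix(model))
  list(S = S,
    lb = model@reactions$lower_bound,
    ub = model@reactions$upper_bound,
    rids = model@reactions$id)
}

#' Solve flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction subject to steady state
#' (`S v = 0`) and the model's flux bounds. Because the optimal vertex of an
#' FBA problem is generally degenerate, the returned flux vector is, by
#' default, the one minimising the total absolute flux among all optima
#' (a second LP with the objective pinned at its optimum, parsimonious
#' FBA). This affects only the representative flux distribution, never the
#' objective value or yields.
#'
#' @param model a [MetabolicModel-class]
#' @param objective reaction id to optimise; default the model objective
#' @param direction `"max"` or `"min"`; default the model objective direction
#' @param parsimonious return the total-flux-minimising optimal flux vector
#'   (default `TRUE`)
#' @return a [FluxSolution-class]; status `"infeasible"` or `"unbounded"`
#'   carries no flux vector
#' @examples
#' mod <- buildCoreModel()
#' sol <- solveFBA(mod, objective = "EX_mal_e", direction = "max")
#' objectiveValue(sol)
#' @export
solveFBA <- function(model, objective = NULL, direction = NULL,
                     parsimonious = TRUE) {
  stopifnot(is(model, "MetabolicModel"))
  if (is.null(objective)) {
    if (!length(model@objective)) stop("model has no objective", call. = FALSE)
    objective <- model@objective$reaction
    if (is.null(direction)) direction <- model@objective$direction
  }
  if (is.null(direction)) direction <- "max"
  direction <- match.arg(direction, c("max", "min"))
  lp <- .modelLP(model)
  j <- match(objective, lp$rids)
  if (is.na(j)) stop("objective reaction not in model: ", objective, call. = FALSE)
  n <- length(lp$rids); m <- nrow(lp$S)
  cc <- numeric(n); cc[j] <- 1

  res <- .simplexSolve(cc, lp$S, rep(0, m), lp$lb, lp$ub,
    maximize = direction == "max")
  if (res$status != "optimal") {
    return(new("FluxSolution", status = res$status,
      objectiveValue = NA_real_, fluxes = numeric()))
  }
  v <- res$x
  if (parsimonious) {
    v <- .pfbaVector(lp, cc, res$objective)
  }
  new("FluxSolution", status = "optimal", objectiveValue = res$objective,
    fluxes = setNames(v, lp$rids))
}

# Among all flux vectors attaining objective value z, return the one with
# minimal sum of absolute fluxes: v = p - q with p, q >= 0, plus the
# objective pinned by an equality row.
.pfbaVector <- function(lp, cc, z) {
  n <- ncol(lp$S); m <- nrow(lp$S)
  A <- rbind(cbind(lp$S, -lp$S), c(cc, -cc))
  b <- c(rep(0, m), z)
  lbp <- pmax(lp$lb, 0); ubp <- pmax(lp$ub, 0)
  lbq <- pmax(-lp$ub, 0); ubq <- pmax(-lp$lb, 0)
  res <- .simplexSolve(rep(1, 2 * n), A, b, c(lbp, lbq), c(ubp, ubq),
    maximize = FALSE)
  if (res$status != "optimal") {
    stop("parsimonious refinement unexpectedly ", res$status, call. = FALSE)
  }
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

#' Molar yield of an optimal solution
#'
#' Yield is the product formation rate divided by the absolute substrate
#' uptake rate, both in mmol/gDW/h, hence dimensionless (mol/mol).
#'
#' @param solution an optimal [FluxSolution-class]
#' @param product_exchange,substrate_exchange exchange reaction ids
#' @return the mol/mol yield (non-negative)
#' @examples
#' mod <- buildCoreModel()
#' sol <- solveFBA(mod, "EX_mal_e", "max")
#' computeYield(sol, "EX_mal_e", "EX_meoh_e") # 0.25
#' @export
computeYield <- function(solution, product_exchange, substrate_exchange = "EX_meoh_e") {
  stopifnot(is(solution, "FluxSolution"))
  if (solutionStatus(solution) != "optimal") {
    stop("yield requires an optimal solution (status: ",
      solutionStatus(solution), ")", call. = FALSE)
  }
  v <- fluxes(solution)
  for (rid in c(product_exchange, substrate_exchange)) {
    if (!rid %in% names(v)) stop("reaction not in solution: ", rid, call. = FALSE)
  }
  up <- abs(v[[substrate_exchange]])
  if (up < 1e-12) stop("undefined yield: zero substrate uptake", call. = FALSE)
  max(v[[product_exchange]] / up, 0)
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux of each queried reaction, via two LP
#' solves per reaction. Optionally the model objective is first optimised
#' and held at a fraction of its optimum.
#'
#' @param model a [MetabolicModel-class]
#' @param reaction one or more reaction ids (default: all)
#' @param fix_objective_fraction if non-`NULL`, constrain the model
#'   objective reaction to at least (max) / at most (min) this fraction of
#'   its optimal value before scanning
#' @return a `data.frame` with columns `reaction`, `min`, `max`
#' @examples
#' mod <- buildCoreModel()
#' fluxVariability(mod, "ICL")
#' @export
fluxVariability <- function(model, reaction = reactionIds(model),
                            fix_objective_fraction = NULL) {
  stopifnot(is(model, "MetabolicModel"))
  if (!is.null(fix_objective_fraction)) {
    base <- solveFBA(model, parsimonious = FALSE)
    if (solutionStatus(base) != "optimal") {
      stop("base model is ", solutionStatus(base), call. = FALSE)
    }
    z <- objectiveValue(base) * fix_objective_fraction
    obj <- model@objective
    model <- if (obj$direction == "max") {
      setBounds(model, obj$reaction, lower = z)
    } else {
      setBounds(model, obj$reaction, upper = z)
    }
  }
  lp <- .modelLP(model)
  m <- nrow(lp$S)
  out <- data.frame(reaction = reaction, min = NA_real_, max = NA_real_,
    stringsAsFactors = FALSE)
  for (k in seq_along(reaction)) {
    j <- match(reaction[k], lp$rids)
    if (is.na(j)) stop("unknown reaction id: ", reaction[k], call. = FALSE)
    cc <- numeric(length(lp$rids)); cc[j] <- 1
    lo <- .simplexSolve(cc, lp$S, rep(0, m), lp$lb, lp$ub, maximize = FALSE)
    hi <- .simplexSolve(cc, lp$S, rep(0, m), lp$lb, lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux variability: base model ", lo$status, call. = FALSE)
    }
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}

#' Production envelope
#'
#' Maximum attainable product yield as a function of imposed growth. For
#' each of `n_points` growth fractions f in [0, 1], the biomass flux is
#' fixed at f times the maximal growth rate and the product exchange is
#' maximised; the yield is the product flux over the realised methanol
#' uptake.
#'
#' @param model a [MetabolicModel-class] containing a biomass reaction and
#'   the product exchange
#' @param product a product name from [productTargets()] or an exchange
#'   reaction id
#' @param n_points number of growth fractions (default 21)
#' @param biomass_reaction id of the growth reaction (default `"BIOMASS"`)
#' @param substrate_exchange substrate exchange id (default `"EX_meoh_e"`)
#' @return a `data.frame` with columns `growth_fraction`, `growth_rate`
#'   (1/h), and `max_yield` (mol/mol)
#' @examples
#' mod <- buildCoreModel()
#' env <- productionEnvelope(mod, "malate", n_points = 5)
#' env$max_yield[1] # zero-growth maximum, 0.25
#' @export
productionEnvelope <- function(model, product, n_points = 21,
                               biomass_reaction = "BIOMASS",
                               substrate_exchange = "EX_meoh_e") {
  stopifnot(is(model, "MetabolicModel"), n_points >= 2)
  targets <- productTargets()
  ex <- if (product %in% targets$name) {
    targets$exchange_reaction[match(product, targets$name)]
  } else product
  if (!ex %in% reactionIds(model)) {
    stop("product exchange not in model: ", ex, call. = FALSE)
  }
  mu_sol <- solveFBA(model, biomass_reaction, "max", parsimonious = FALSE)
  if (solutionStatus(mu_sol) != "optimal") {
    stop("growth maximisation is ", solutionStatus(mu_sol), call. = FALSE)
  }
  mu_max <- objectiveValue(mu_sol)
  if (mu_max <= 1e-9) stop("maximal growth rate is zero; envelope undefined", call. = FALSE)

  fr <- seq(0, 1, length.out = n_points)
  out <- data.frame(growth_fraction = fr, growth_rate = fr * mu_max,
    max_yield = NA_real_)
  for (i in seq_along(fr)) {
    mu <- fr[i] * mu_max
    fixed <- setBounds(model, biomass_reaction,
      lower = mu * (1 - 1e-9), upper = mu)
    sol <- solveFBA(fixed, ex, "max", parsimonious = FALSE)
    if (solutionStatus(sol) != "optimal") {
      stop("envelope point f=", fr[i], " is ", solutionStatus(sol), call. = FALSE)
    }
    out$max_yield[i] <- computeYield(sol, ex, substrate_exchange)
  }
  out
}
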