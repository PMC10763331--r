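# Shared fixtures, built in code.

# Minimal two-reaction model around peroxisomal methanol oxidation.
toyOxidaseModel <- function(drop_water = FALSE) {
  met <- data.frame(
    id = c("meoh_x", "o2_x", "fald_x", "h2o2_x", "h2o_x"),
    name = c("methanol", "oxygen", "formaldehyde", "hydrogen peroxide", "water"),
    compartment = "peroxisome",
    formula = c("CH4O", "O2", "CH2O", "H2O2", "H2O"),
    charge = NA_real_,
    stringsAsFactors = FALSE)
  cat_st <- c(h2o2_x = -2, o2_x = 1, h2o_x = 2)
  if (drop_water) cat_st <- c(h2o2_x = -2, o2_x = 1, h2o_x = 1)
  rxn <- data.frame(
    id = c("MOX", "CATx", "EX_meoh_x", "EX_o2_x", "EX_fald_x", "EX_h2o_x"),
    name = c("methanol oxidase", "catalase", "exchange", "exchange",
      "exchange", "exchange"),
    lower_bound = c(0, 0, -10, -1000, 0, -1000),
    upper_bound = c(1000, 1000, 0, 1000, 1000, 1000),
    subsystem = c("oxidation", "oxidation", rep("exchange", 4)),
    stringsAsFactors = FALSE)
  rxn$metabolites <- list(
    c(meoh_x = -1, o2_x = -1, fald_x = 1, h2o2_x = 1),
    cat_st,
    c(meoh_x = -1), c(o2_x = -1), c(fald_x = -1), c(h2o_x = -1))
  newMetabolicModel(met, rxn,
    objective = list(reaction = "EX_fald_x", direction = "max"),
    id = "toy_oxidase")
}

# Build the shared core model once per test run.
coreModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildCoreModel()
    cache
  }
})

# The 15-cell grid with solutions is expensive; compute once and reuse.
coreGrid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        runScenarioMatrix(coreModel(), keep_solutions = TRUE))
    }
    cache
  }
})

makeSolution <- function(fluxes, objective = NA_real_) {
  new("FluxSolution", status = "optimal",
    objectiveValue = if (is.na(objective)) max(fluxes) else objective,
    fluxes = fluxes)
}
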