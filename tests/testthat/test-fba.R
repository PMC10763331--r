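# FBA engine: optima, yields, variability, envelopes, and an independent
# cross-check against a reference constraint-based implementation.

test_that("maximum malate flux on methanol reaches the theoretical optimum", {
  sol <- solveFBA(coreModel(), "EX_mal_e", "max")
  expect_equal(solutionStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 2.5, tolerance = 1e-6)
  expect_equal(computeYield(sol, "EX_mal_e", "EX_meoh_e"), 0.25, tolerance = 1e-4)
  # steady state and bounds hold on the returned vector
  S <- as.matrix(stoichiometricMatrix(coreModel()))
  v <- fluxes(sol)
  expect_lt(max(abs(S %*% v)), 1e-6)
  r <- reactions(coreModel())
  expect_true(all(v >= r$lower_bound - 1e-9 & v <= r$upper_bound + 1e-9))
})

test_that("closing all exchanges leaves only the zero steady state", {
  mod <- coreModel()
  for (rid in reactionIds(mod)[isExchange(mod)]) {
    mod <- setBounds(mod, rid, lower = 0, upper = 0)
  }
  sol <- solveFBA(mod, "EX_mal_e", "max")
  expect_equal(solutionStatus(sol), "optimal")
  expect_lt(max(abs(fluxes(sol))), 1e-9)
})

test_that("an unattainable forced lower bound yields infeasibility", {
  mod <- setBounds(coreModel(), "EX_mal_e", lower = 5, upper = 5) # above 2.5
  sol <- solveFBA(mod, "EX_mal_e", "max")
  expect_equal(solutionStatus(sol), "infeasible")
  expect_length(fluxes(sol), 0L)
})

test_that("yield arithmetic follows the production-over-uptake definition", {
  s <- makeSolution(c(EX_p = 2.5, EX_s = -10))
  expect_equal(computeYield(s, "EX_p", "EX_s"), 0.25)
  expect_equal(computeYield(makeSolution(c(EX_p = 1, EX_s = -8)), "EX_p", "EX_s"),
    0.125)
  expect_equal(computeYield(makeSolution(c(EX_p = 0, EX_s = -10)), "EX_p", "EX_s"), 0)
  expect_error(computeYield(makeSolution(c(EX_p = 1, EX_s = 0)), "EX_p", "EX_s"),
    "zero substrate")
})

test_that("yields are invariant under common rescaling of all bounds", {
  mod <- coreModel()
  scaled <- mod
  scaled@reactions$lower_bound <- mod@reactions$lower_bound * 2
  scaled@reactions$upper_bound <- mod@reactions$upper_bound * 2
  y1 <- computeYield(solveFBA(mod, "EX_mal_e", "max", parsimonious = FALSE),
    "EX_mal_e", "EX_meoh_e")
  y2 <- computeYield(solveFBA(scaled, "EX_mal_e", "max", parsimonious = FALSE),
    "EX_mal_e", "EX_meoh_e")
  expect_equal(y1, y2, tolerance = 1e-9)
})

test_that("flux variability agrees with two independent single-objective solves", {
  mod <- coreModel()
  for (rid in c("ICL", "AKGDm", "MDHm", "EX_mal_e")) {
    fv <- fluxVariability(mod, rid)
    lo <- objectiveValue(solveFBA(mod, rid, "min", parsimonious = FALSE))
    hi <- objectiveValue(solveFBA(mod, rid, "max", parsimonious = FALSE))
    expect_equal(fv$min, lo, tolerance = 1e-8, info = rid)
    expect_equal(fv$max, hi, tolerance = 1e-8, info = rid)
    expect_lte(fv$min, fv$max + 1e-12)
  }
})

test_that("variability of a sink without producers is (0, 0)", {
  # block formaldehyde supply: the whole assimilation tree dries up
  mod <- setBounds(coreModel(), "MOX", upper = 0)
  fv <- fluxVariability(mod, "EX_mal_e")
  expect_equal(fv$min, 0)
  expect_equal(fv$max, 0)
})

test_that("objective fixing restricts the variability range", {
  mod <- coreModel()
  objective(mod) <- list(reaction = "EX_mal_e", direction = "max")
  free <- fluxVariability(mod, "ICL")
  fixed <- fluxVariability(mod, "ICL", fix_objective_fraction = 1)
  expect_gte(fixed$min, free$min - 1e-9)
  expect_lte(fixed$max, free$max + 1e-9)
})

test_that("re-solving with the objective pinned at its optimum stays feasible", {
  mod <- coreModel()
  z <- objectiveValue(solveFBA(mod, "EX_mal_e", "max", parsimonious = FALSE))
  pinned <- setBounds(mod, "EX_mal_e", lower = z * (1 - 1e-9), upper = z)
  sol <- solveFBA(pinned, "BIOMASS", "max", parsimonious = FALSE)
  expect_equal(solutionStatus(sol), "optimal")
})

test_that("production envelopes are monotone, anchored, and steepest for malate", {
  mod <- coreModel()
  envs <- lapply(c("malate", "acetone", "isoprene"), function(p) {
    productionEnvelope(mod, p, n_points = 9)
  })
  names(envs) <- c("malate", "acetone", "isoprene")
  for (p in names(envs)) {
    env <- envs[[p]]
    expect_equal(env$growth_fraction[1], 0)
    expect_equal(env$growth_fraction[nrow(env)], 1)
    # yields non-increasing along the growth axis
    expect_true(all(diff(env$max_yield) <= 1e-6), info = p)
    # at maximal growth nothing is left for the product
    expect_lt(env$max_yield[nrow(env)], 1e-6)
  }
  expect_equal(envs$malate$max_yield[1], 0.25, tolerance = 1e-4)
  # absolute slope in yield per unit growth rate is steepest for malate
  slope <- vapply(envs, function(env) {
    (env$max_yield[1] - env$max_yield[nrow(env)]) / env$growth_rate[nrow(env)]
  }, 0)
  expect_gt(slope[["malate"]], slope[["acetone"]])
  expect_gt(slope[["malate"]], slope[["isoprene"]])
  # drop normalised by the zero-growth yield is never larger elsewhere
  ndrop <- vapply(envs, function(env) {
    (env$max_yield[1] - env$max_yield[nrow(env)]) / env$max_yield[1]
  }, 0)
  expect_gte(ndrop[["malate"]], ndrop[["acetone"]] - 1e-9)
  expect_gte(ndrop[["malate"]], ndrop[["isoprene"]] - 1e-9)
})

test_that("a zero-growth model has no envelope", {
  mod <- setBounds(coreModel(), "BIOMASS", upper = 0)
  expect_error(productionEnvelope(mod, "malate", n_points = 3), "zero")
})

test_that("the reference constraint-based implementation reproduces the optimum", {
  # cross-check through the COBRA-dialect JSON written by this package
  path <- withr::local_tempfile(fileext = ".json")
  writeMetabolicModel(coreModel(), path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra",
    "m = cobra.io.load_json_model(sys.argv[1])",
    "m.objective = 'EX_mal_e'",
    "print(repr(m.optimize().objective_value))"), script)
  out <- tryCatch(
    system2("python", c(script, path), stdout = TRUE, stderr = FALSE),
    warning = function(w) character())
  expect_gt(length(out), 0)
  expect_equal(as.numeric(out[length(out)]), 2.5, tolerance = 1e-6)
})
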