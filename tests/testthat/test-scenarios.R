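# Scenario engine: bound edits, calibration, and the product x scenario
# yield grid with its qualitative structure.

test_that("blocked-TCA edits zero the expected core reactions", {
  mod <- coreModel()
  tca <- suppressWarnings(
    applyScenario(mod, scenarioSpecs()[["TCA-"]], product = "malate"))
  for (rid in c("PDHm", "AKGDm", "CITtc", "CSm")) {
    expect_equal(unname(bounds(tca, rid)["upper"]), 0, info = rid)
  }
  expect_equal(objective(tca), list(reaction = "EX_mal_e", direction = "max"))
  # the input model is untouched
  expect_equal(unname(bounds(mod, "PDHm")["upper"]), 1000)
})

test_that("the reference scenario only sets uptake and objective", {
  mod <- coreModel()
  ref <- applyScenario(mod, scenarioSpecs()[["Ref"]], product = "acetone")
  expect_equal(unname(bounds(ref, "EX_meoh_e")), c(-10, 0))
  expect_equal(objective(ref)$reaction, "EX_acetone_e")
  same <- setdiff(reactionIds(mod), "EX_meoh_e")
  expect_equal(reactions(ref)[match(same, reactionIds(ref)), c("lower_bound", "upper_bound")],
    reactions(mod)[match(same, reactionIds(mod)), c("lower_bound", "upper_bound")])
})

test_that("the impaired-glyoxylate scenario extends the forced one", {
  mod <- coreModel()
  std <- applyScenario(mod, scenarioSpecs()[["GlxStd"]])
  var <- applyScenario(mod, scenarioSpecs()[["GlxVar"]])
  # ICL forcing shared
  expect_equal(bounds(var, "ICL")["lower"], bounds(std, "ICL")["lower"])
  expect_gt(unname(bounds(std, "ICL")["lower"]), 0)
  # the mitochondrial MDH is additionally pinned down
  expect_lt(unname(bounds(var, "MDHm")["upper"]),
    unname(bounds(std, "MDHm")["upper"]))
  expect_equal(unname(bounds(var, "MDHm")["lower"]), -10)
})

test_that("calibrated bounds sit at the feasibility extremes", {
  mod <- coreModel()
  cal <- calibrateForcedBound(mod, "AKGDm", "max")
  expect_gt(cal, 0)
  fv <- fluxVariability(mod, "AKGDm")
  expect_equal(cal, fv$max * (1 - 1e-6), tolerance = 1e-9)
  # independent bisection oracle: largest feasible forced lower bound
  feasible <- function(b) {
    m <- setBounds(mod, "AKGDm", lower = b)
    solutionStatus(solveFBA(m, "EX_mal_e", "max", parsimonious = FALSE)) == "optimal"
  }
  lo <- 0; hi <- 10
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  expect_equal(cal, lo, tolerance = 1e-5)
  # forcing at the calibrated bound stays feasible
  expect_true(feasible(cal))

  # a reaction with zero attainable flux calibrates to zero
  blocked <- setBounds(mod, "ICL", upper = 0)
  expect_equal(calibrateForcedBound(blocked, "ICL", "max"), 0)
})

test_that("the grid covers 15 cells with non-negative yields and statuses", {
  tab <- coreGrid()
  y <- yields(tab)
  expect_equal(dim(y), c(3L, 5L))
  expect_equal(rownames(y), c("malate", "acetone", "isoprene"))
  expect_equal(colnames(y), c("Ref", "TCA-", "TCA+", "GlxStd", "GlxVar"))
  expect_true(all(y >= 0))
  expect_true(all(cellStatus(tab) %in% c("optimal", "infeasible")))
})

test_that("the yield grid reproduces the qualitative scenario structure", {
  y <- yields(coreGrid())
  expect_equal(y["malate", "Ref"], 0.25, tolerance = 1e-4)
  expect_equal(y["malate", "TCA-"], 0.25, tolerance = 1e-4)
  for (p in rownames(y)) {
    # blocked TCA barely moves the optimum (within 10 % relative)
    expect_lte(y[p, "TCA-"], y[p, "Ref"] + 1e-9)
    expect_gte(y[p, "TCA-"], y[p, "Ref"] * 0.9 - 1e-9)
    # forcing the glyoxylate shunt costs yield, strictly
    expect_lt(y[p, "GlxStd"], y[p, "Ref"] - 1e-6)
    # forced TCA at the calibrated maximum commits all carbon
    expect_lt(y[p, "TCA+"], 1e-4)
  }
  expect_lte(y["malate", "GlxVar"], y["malate", "GlxStd"] + 1e-9)
})

test_that("the bundled scenario config mirrors the built-in definitions", {
  path <- system.file("extdata", "scenarios.yaml", package = "methflux")
  cfg <- readScenarioConfig(path)
  builtin <- scenarioSpecs()
  expect_equal(names(cfg), names(builtin))
  for (nm in names(cfg)) {
    expect_equal(length(cfg[[nm]]$edits), length(builtin[[nm]]$edits), info = nm)
    for (k in seq_along(cfg[[nm]]$edits)) {
      expect_equal(cfg[[nm]]$edits[[k]]$alias, builtin[[nm]]$edits[[k]]$alias)
      expect_equal(cfg[[nm]]$edits[[k]]$bound, builtin[[nm]]$edits[[k]]$bound)
      expect_equal(cfg[[nm]]$edits[[k]]$value, builtin[[nm]]$edits[[k]]$value)
    }
  }
  # a grid run from the file-based config matches the built-in grid
  tab <- suppressWarnings(runScenarioMatrix(coreModel(),
    productTargets("malate"), scenarios = cfg["GlxStd"]))
  expect_equal(unname(yields(tab)[1, 1]),
    unname(yields(coreGrid())["malate", "GlxStd"]), tolerance = 1e-8)
})

test_that("alias handling: unmapped aliases warn, unknown aliases error", {
  mod <- coreModel()
  expect_warning(
    applyScenario(mod, scenarioSpecs()[["TCA-"]]),
    "ACLSm")
  bogus <- list(name = "x", edits = list(list(alias = "NOPE", bound = "upper", value = 0)))
  expect_error(applyScenario(mod, bogus), "NOPE")
})

test_that("malformed scenario configs are rejected", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("- edits: []", p)
  expect_error(readScenarioConfig(p), "name")
  writeLines(c("- name: a", "  edits:", "    - {alias: ICL, bound: sideways, value: 1}"), p)
  expect_error(readScenarioConfig(p), "lower/upper/both")
})
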