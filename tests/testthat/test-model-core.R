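# Model container, formula arithmetic, elemental balance, stoichiometric
# matrix, and the JSON/TSV readers and writers.

test_that("formula parsing matches independent elemental counting", {
  # oracle: count element occurrences by regex over the formula string
  countEl <- function(f, el) {
    m <- regmatches(f, gregexpr(paste0(el, "(?![a-z])[0-9]*"), f, perl = TRUE))[[1]]
    if (!length(m)) return(0)
    sum(vapply(m, function(t) {
      n <- sub(paste0("^", el), "", t)
      if (nzchar(n)) as.numeric(n) else 1
    }, 0))
  }
  for (f in c("CH4O", "C4H6O5", "C21H26N7O14P2", "H", "O2", "C23H34N7O17P3S")) {
    parsed <- parseFormula(f)
    for (el in c("C", "H", "O", "N", "P", "S")) {
      expect_equal(parsed[[el]], countEl(f, el), info = paste(f, el))
    }
  }
  expect_equal(formatFormula(parseFormula("C4H6O5")), "C4H6O5")
  expect_error(parseFormula("C4X2"), "unsupported element")
})

test_that("elemental balance flags exactly the corrupted reactions", {
  expect_equal(nrow(validateMassBalance(toyOxidaseModel())), 0L)

  bad <- validateMassBalance(toyOxidaseModel(drop_water = TRUE))
  expect_equal(bad$reaction, "CATx")
  expect_equal(bad$H, -2)
  expect_equal(bad$O, -1)
})

test_that("exchange-only models give an empty report, missing formulas error", {
  mod <- toyOxidaseModel()
  only_ex <- newMetabolicModel(metabolites(mod),
    reactions(mod)[isExchange(mod), ], id = "ex_only")
  expect_equal(nrow(validateMassBalance(only_ex)), 0L)

  noform <- mod
  noform@metabolites$formula[1] <- NA_character_
  expect_error(validateMassBalance(noform), "meoh_x")
})

test_that("stoichiometric matrix reproduces the per-reaction coefficients", {
  mod <- coreModel()
  S <- stoichiometricMatrix(mod)
  expect_equal(dim(S), c(nrow(metabolites(mod)), nrow(reactions(mod))))
  # random spot checks against the stoichiometry lists
  set.seed(3)
  for (j in sample(ncol(S), 10)) {
    st <- reactions(mod)$metabolites[[j]]
    expect_equal(as.numeric(S[names(st), j]), unname(st))
    others <- setdiff(rownames(S), names(st))
    expect_true(all(S[others, j] == 0))
  }
  # exchange columns carry exactly one nonzero entry
  for (j in which(isExchange(mod))) {
    expect_equal(sum(S[, j] != 0), 1)
  }
})

test_that("model validity catches duplicate ids, bad bounds, dangling stoich", {
  mod <- toyOxidaseModel()
  dup <- mod@metabolites; dup$id[2] <- dup$id[1]
  expect_error(newMetabolicModel(dup, reactions(mod)), "duplicate")
  badb <- reactions(mod); badb$lower_bound[1] <- 5; badb$upper_bound[1] <- 1
  expect_error(newMetabolicModel(metabolites(mod), badb), "lower_bound")
  dang <- reactions(mod); dang$metabolites[[1]] <- c(ghost_c = -1)
  expect_error(newMetabolicModel(metabolites(mod), dang), "unknown metabolite")
})

test_that("JSON round-trip is the identity on models", {
  mod <- coreModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeMetabolicModel(mod, path)
  back <- readMetabolicModel(path)

  expect_equal(sort(metaboliteIds(back)), sort(metaboliteIds(mod)))
  expect_equal(sort(reactionIds(back)), sort(reactionIds(mod)))
  expect_equal(objective(back), objective(mod))
  for (rid in reactionIds(mod)) {
    i <- match(rid, reactionIds(mod)); j <- match(rid, reactionIds(back))
    a <- reactions(mod)[i, ]; b <- reactions(back)[j, ]
    expect_equal(b$lower_bound, a$lower_bound, info = rid)
    expect_equal(b$upper_bound, a$upper_bound, info = rid)
    expect_equal(b$subsystem, a$subsystem, info = rid)
    sa <- a$metabolites[[1]]; sb <- b$metabolites[[1]]
    expect_equal(sb[sort(names(sb))], sa[sort(names(sa))], info = rid)
  }
  for (mid in metaboliteIds(mod)) {
    i <- match(mid, metaboliteIds(mod)); j <- match(mid, metaboliteIds(back))
    expect_equal(metabolites(back)$formula[j], metabolites(mod)$formula[i])
    expect_equal(metabolites(back)$compartment[j], metabolites(mod)$compartment[i])
  }
})

test_that("two writes of the same model are byte-identical", {
  mod <- coreModel()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeMetabolicModel(mod, p1); writeMetabolicModel(mod, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  writeMetabolicModel(mod, t1); writeMetabolicModel(mod, t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("TSV dialect round-trips reaction structure", {
  mod <- toyOxidaseModel()
  one <- newMetabolicModel(metabolites(mod), reactions(mod)[1, ],
    id = "one_rxn")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMetabolicModel(one, path)
  expect_length(readLines(path), 2L)  # header + one data row

  back <- readMetabolicModel(path)
  expect_equal(reactionIds(back), "MOX")
  st <- reactions(back)$metabolites[[1]]
  expect_equal(st[sort(names(st))],
    reactions(one)$metabolites[[1]][sort(names(reactions(one)$metabolites[[1]]))])
  expect_equal(reactions(back)$lower_bound, 0)
  expect_equal(reactions(back)$upper_bound, 1000)
})

test_that("reader errors name the offence and warns on unknown fields", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  expect_error(readMetabolicModel(empty), "parse error")

  expect_error(readMetabolicModel(tempfile()), "not found")

  path <- withr::local_tempfile(fileext = ".json")
  writeMetabolicModel(toyOxidaseModel(), path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$notes <- "extra"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  expect_warning(readMetabolicModel(path), "unknown model fields")

  doc$metabolites[[2]]$id <- doc$metabolites[[1]]$id
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  expect_error(suppressWarnings(readMetabolicModel(path)), "duplicate")
})
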