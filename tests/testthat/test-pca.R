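# Flux matrix assembly, PCA against a brute-force eigen oracle, and the
# score-space geometry of the scenario solutions.

test_that("flux matrix assembly zero-fills and keeps labels unique", {
  s1 <- makeSolution(c(A = 1, B = 2))
  s2 <- makeSolution(c(B = 3, C = -1))
  fm <- assembleFluxMatrix(list(x = s1, y = s2))
  expect_equal(dim(fm), c(2L, 3L))
  expect_equal(colnames(fm), c("A", "B", "C"))
  expect_equal(unname(fm["y", "A"]), 0)   # absent reaction -> 0
  expect_equal(unname(fm["x", "C"]), 0)

  fm2 <- assembleFluxMatrix(list(a = s1, b = s1))
  expect_equal(fm2["a", ], fm2["b", ])    # identical solutions, identical rows

  expect_error(assembleFluxMatrix(stats::setNames(list(s1, s1), c("a", "a"))),
    "duplicate")
  expect_error(assembleFluxMatrix(list(a = s1)), "at least two")
  bad <- new("FluxSolution", status = "infeasible",
    objectiveValue = NA_real_, fluxes = numeric())
  expect_error(assembleFluxMatrix(list(a = s1, b = bad)), "non-optimal")
})

test_that("PCA agrees with a brute-force covariance eigen-decomposition", {
  set.seed(19)
  x <- matrix(rnorm(24), 6, 4,
    dimnames = list(paste0("r", 1:6), paste0("c", 1:4)))
  p <- runFluxPCA(x, center = TRUE, scale = FALSE)

  # oracle: eigenvectors of the covariance matrix of the centred data
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  or_scores <- xc %*% ev$vectors
  for (k in seq_len(ncol(p$scores))) {
    expect_lt(min(
      max(abs(p$scores[, k] - or_scores[, k])),
      max(abs(p$scores[, k] + or_scores[, k]))), 1e-8)
    expect_lt(min(
      max(abs(p$loadings[, k] - ev$vectors[, k])),
      max(abs(p$loadings[, k] + ev$vectors[, k]))), 1e-8)
  }
  expect_equal(p$explained_variance_ratio,
    (ev$values / sum(ev$values))[seq_len(ncol(p$scores))], tolerance = 1e-10)

  # variance ratios: in [0,1], non-increasing, summing to at most 1
  evr <- p$explained_variance_ratio
  expect_true(all(evr >= 0 & evr <= 1))
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-9)

  # scores reproduce the centred data times the loadings
  expect_equal(p$scores, unclass(xc %*% p$loadings),
    ignore_attr = TRUE, tolerance = 1e-10)
  # the sign convention makes the result deterministic
  p2 <- runFluxPCA(x)
  expect_identical(p$scores, p2$scores)
})

test_that("degenerate inputs: identical rows score zero, scaling drops flats", {
  x <- matrix(1, 4, 3)
  p <- runFluxPCA(x)
  expect_lt(max(abs(p$scores)), 1e-12)
  expect_error(runFluxPCA(x[1, , drop = FALSE]), "two rows")

  y <- cbind(rnorm(5), 7)
  expect_warning(runFluxPCA(y, scale = TRUE), "zero-variance")
})

test_that("score-space distances and the largest-gap cluster cut behave", {
  m <- rbind(a = c(0, 0, 0), b = c(0.1, 0, 0),
    c = c(10, 10, 0), d = c(10.1, 10, 0))
  sd <- scenarioDistances(runFluxPCA(m), k = 2)
  expect_equal(sd$n_clusters, 2L)
  expect_equal(unname(sd$clusters["a"]), unname(sd$clusters["b"]))
  expect_equal(unname(sd$clusters["c"]), unname(sd$clusters["d"]))
  expect_equal(sd$distances["a", "a"], 0)
  expect_error(scenarioDistances(runFluxPCA(m), k = 5), "exceeds")

  same <- matrix(3, 4, 2)
  sd2 <- scenarioDistances(runFluxPCA(same), k = 1)
  expect_equal(sd2$n_clusters, 1L)
  expect_true(all(sd2$distances == 0))
})

test_that("scenario solutions separate into the three pathway modes", {
  fm <- assembleFluxMatrix(attr(coreGrid(), "solutions"))
  expect_equal(nrow(fm), 15L)
  p <- runFluxPCA(fm)
  dm <- scenarioDistances(p, k = 2)$distances

  scen <- c("Ref", "TCA-", "TCA+", "GlxStd", "GlxVar")
  mode <- c(Ref = 1, `TCA-` = 1, `TCA+` = 2, GlxStd = 3, GlxVar = 3)
  for (prod in c("malate", "acetone", "isoprene")) {
    lab <- paste(prod, scen, sep = "|")
    d <- dm[lab, lab]
    within <- d[outer(mode, mode, "==") & upper.tri(d)]
    across <- d[outer(mode, mode, "!=") & upper.tri(d)]
    # within-mode spread strictly below any cross-mode distance
    expect_lt(max(within), min(across), label = paste(prod, "within-mode max"))
    # the reference clusters with the blocked-TCA solution, not with the
    # glyoxylate ones
    expect_lt(d[paste0(prod, "|Ref"), paste0(prod, "|TCA-")],
      d[paste0(prod, "|Ref"), paste0(prod, "|GlxStd")])
  }

  # acetone and isoprene share routes: nearest cross-product neighbours
  for (sc in scen) {
    a <- paste0("acetone|", sc); i <- paste0("isoprene|", sc)
    m <- paste0("malate|", sc)
    expect_lte(dm[a, i], min(dm[a, m], dm[i, m]) + 1e-9,
      label = paste(sc, "acetone-isoprene distance"))
  }
})
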