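test_that("index kernels reproduce hand-computed values", {
  expect_equal(contaminationFactor(553.68, 100), 5.5368)
  expect_equal(contaminationFactor(173.71, 50), 3.4742)
  expect_equal(contaminationFactor(80, 80), 1)
  expect_error(contaminationFactor(10, 0), "reference error")

  expect_equal(ecologicalRisk(10, 2), 20)
  expect_equal(ecologicalRisk(5, 0), 0)
  expect_equal(ecologicalRisk(2, 5.5368), 11.0736)

  expect_equal(nemerowSingle(120, 120), 1)
  expect_equal(nemerowSingle(0, 120), 0)
  expect_equal(nemerowSingle(240, 120), 2)
  ## homogeneity of degree 1
  expect_equal(contaminationFactor(3 * 70, 50), 3 * contaminationFactor(70, 50))
  expect_equal(nemerowSingle(3 * 70, 120), 3 * nemerowSingle(70, 120))
})

test_that("Nemerow combinations follow their closed forms", {
  expect_equal(nemerowIntegrated(c(2, 2, 2)), 2)
  expect_equal(nemerowIntegrated(c(1, 1, 3)),
               sqrt((mean(c(1, 1, 3))^2 + 9) / 2))
  expect_equal(nemerowIntegrated(c(1, 1, 3)), 2.4267, tolerance = 1e-4)
  expect_equal(nemerowIntegrated(2), 2)
  expect_error(nemerowIntegrated(numeric(0)), "no index values")
  expect_equal(nemerowLow(c(1, 1, 3)), sqrt((mean(c(1, 1, 3))^2 + 1) / 2))
})

test_that("capacity index honours its algebra", {
  ## Pi = 1 at background, 0 at screening, negative beyond
  expect_equal(capacityPi(50, 120, 50)$pi, 1)
  expect_equal(capacityPi(120, 120, 50)$pi, 0)
  expect_lt(capacityPi(150, 120, 50)$pi, 0)
  ## invariant to soil mass M, strictly decreasing in Ci
  ci <- seq(10, 300, by = 10)
  p1 <- capacityPi(ci, 120, 50, M = 2.25e6)$pi
  p2 <- capacityPi(ci, 120, 50, M = 1e4)$pi
  expect_equal(p1, p2)
  expect_true(all(diff(p1) < 0))
  ## Qi/Qib scale with M even though Pi does not
  expect_equal(capacityPi(60, 120, 50, M = 2e6)$qib, 2 * 70 * 1e-6 * 1e6)
  expect_error(capacityPi(10, 50, 50), "reference error")
})

test_that("contamination under the default rule is background exceedance", {
  sv <- generateSurvey(seed = 2)
  idx <- pollutionIndices(sv)
  refs <- idx@references
  X <- concMatrix(sv)
  for (mt in colnames(X)) {
    flagged <- applyRule(idx@pi[, mt], list(op = "<", threshold = 1))
    expect_equal(flagged, X[, mt] > refs[refs$metal == mt, "background"],
                 ignore_attr = TRUE)
  }
})

test_that("integrated Pi follows the two-step definition", {
  ## constant table: every metal normalises to the 0.5 convention
  pim <- matrix(0.3, 4, 3)
  expect_equal(integratePi(pim), rep(0.5, 4))
  ## a site strictly worst in every metal integrates to 0
  pim <- rbind(c(0.1, 0.2), c(0.5, 0.9), c(0.8, 0.4))
  expect_equal(integratePi(pim)[1], 0)
  ## brute-force evaluation on a 3-site, 2-metal toy table
  norm1 <- (pim[, 1] - 0.1) / 0.7
  norm2 <- (pim[, 2] - 0.2) / 0.7
  manual <- sapply(1:3, function(i) {
    v <- c(norm1[i], norm2[i])
    sqrt((mean(v)^2 + min(v)^2) / 2)
  })
  expect_equal(integratePi(pim), manual)
  expect_equal(integratePi(pim, method = "mean"),
               rowMeans(cbind(norm1, norm2)))
})

test_that("risk classes use lower-closed bins", {
  expect_equal(as.character(classifyRisk(c(0.84, -0.2, 0.7, 0.4, 0, 0.39))),
               c("safe", "overloaded", "safe", "precautionary", "loaded",
                 "loaded"))
})

test_that("full index table matches a spreadsheet-style recomputation", {
  sv <- toySurvey()
  refs <- metalReferences()
  idx <- pollutionIndices(sv, refs)
  X <- concMatrix(sv)
  ## independent recomputation, cell by cell
  for (i in seq_len(nrow(X))) for (mt in colnames(X)) {
    r <- refs[refs$metal == mt, ]
    expect_equal(idx@cf[i, mt], X[i, mt] / r$background)
    expect_equal(idx@er[i, mt], r$toxic_response * X[i, mt] / r$background)
    expect_equal(idx@npi[i, mt], X[i, mt] / r$standard_limit)
    expect_equal(idx@pi[i, mt],
                 (r$screening - X[i, mt]) / (r$screening - r$background))
  }
  ## site S1 sits exactly at background for every metal: Pi = 1 across
  expect_equal(unname(idx@pi[1, ]), rep(1, 8))
  ## ER = Tr x CF exactly, as matrices
  expect_equal(idx@er, sweep(idx@cf, 2, refs[colnames(X), "toxic_response"],
                             "*"))
  ## wide and long exports conserve rows
  expect_equal(nrow(indexTable(idx)), 5)
  expect_equal(nrow(indexTableLong(idx)), 5 * 8 * 4)
})
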