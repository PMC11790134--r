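test_that("uncertainty matrix implements the two-branch convention", {
  conc <- matrix(10, 8, 3, dimnames = list(c("Pb", "Cr", "Mn", "Cu", "Zn",
                                             "Co", "Ni", "As"), NULL))
  conc["Pb", 1] <- 0.1      # below the 0.25 mg/kg Pb detection limit
  conc["Cu", 2] <- 100
  sv <- SoilSurvey(conc, x = 1:3, y = 3:1,
                   land_use = rep("residential", 3))
  refs <- metalReferences(data.frame(metal = "Cu", sigma = 0.1, mdl = 0.25))
  u <- buildUncertainty(sv, refs)
  ## below-MDL branch: u = (5/6) MDL, concentration replaced by MDL/2
  expect_equal(u$U[1, "Pb"], 5 / 6 * 0.25, tolerance = 1e-12)
  expect_equal(u$X[1, "Pb"], 0.125)
  expect_true(u$substituted[1, "Pb"])
  ## above-MDL branch: u = sqrt((sigma x)^2 + (MDL/2)^2)
  expect_equal(u$U[2, "Cu"], sqrt(100 + 0.015625), tolerance = 1e-12)
  expect_equal(u$U[2, "Cu"], 10.0008, tolerance = 1e-4)
  expect_false(u$substituted[2, "Cu"])
  ## sigma = 0 limit: u = MDL/2
  refs0 <- metalReferences(data.frame(metal = "Zn", sigma = 0))
  u0 <- buildUncertainty(sv, refs0)
  expect_equal(u0$U[1, "Zn"], 0.21 / 2, tolerance = 1e-12)
  expect_true(all(u$U > 0))
})

test_that("noiseless low-rank matrices are factorized to numerical zero", {
  d <- generatePMFDataset(n = 25, m = 8, p = 3, noise_level = 0, seed = 2)
  X <- concMatrix(d$survey)
  U <- matrix(1, nrow(X), ncol(X))
  fit <- pmfFit(X, U, p = 3, n_runs = 5, seed = 1, max_iter = 10000)
  Xhat <- fit@G %*% fit@F
  expect_lt(max(abs(X - Xhat)) / max(X), 1e-4)
  expect_lt(fit@Q / sum((X / U)^2), 1e-8)
  expect_equal(unname(fit@r2), rep(1, 8), tolerance = 1e-6)
  expect_equal(mean(abs(fit@scaledResiduals) <= 3), 1)
  ## rank-1 data with p = 1
  d1 <- generatePMFDataset(n = 15, m = 6, p = 1, noise_level = 0, seed = 3)
  X1 <- concMatrix(d1$survey)
  f1 <- pmfFit(X1, matrix(1, 15, 6), p = 1, n_runs = 3, seed = 1)
  expect_lt(f1@Q / sum(X1^2), 1e-8)
  expect_equal(unname(pmfContributions(f1)$factor_contribution_pct), 100)
})

test_that("Q never increases along multiplicative updates", {
  d <- generatePMFDataset(n = 20, m = 8, p = 3, noise_level = 0.1, seed = 5)
  X <- concMatrix(d$survey)
  U <- 0.1 * X + 0.01
  set.seed(2)
  run <- soilcap:::.pmfRun(X, 1 / U^2, p = 3, max_iter = 300, tol = 0,
                           init_scale = sqrt(mean(X) / 3))
  expect_gte(length(run$qTrace), 100)
  expect_true(all(diff(run$qTrace) <= 1e-8 * run$qTrace[-length(run$qTrace)]))
})

test_that("planted factors are recovered at realistic noise", {
  d <- generatePMFDataset(n = 30, m = 8, p = 3, noise_level = 0.05, seed = 1,
                          shares = c(0.2, 0.3, 0.5))
  X <- concMatrix(d$survey)
  U <- 0.05 * pmax(X, 1e-6) + 1e-6
  fit <- pmfFit(X, U, p = 3, n_runs = 20, seed = 1)
  mt <- matchFactors(d$F_true, fit@F)
  expect_gt(mt$mean_cosine, 0.95)
  shares_hat <- fit@factorContributionPct[mt$perm]
  expect_lt(max(abs(shares_hat - c(20, 30, 50))), 5)
  ## every metal well explained
  expect_gt(min(fit@r2), 0.8)
})

test_that("solutions are seed-deterministic and scale-consistent", {
  d <- generatePMFDataset(n = 20, m = 8, p = 3, noise_level = 0.05, seed = 6)
  X <- concMatrix(d$survey)
  U <- 0.05 * X + 0.01
  f1 <- pmfFit(X, U, p = 3, n_runs = 5, seed = 9)
  f2 <- pmfFit(X, U, p = 3, n_runs = 5, seed = 9)
  expect_identical(f1@G, f2@G)
  expect_identical(f1@Q, f2@Q)
  ## multistart spread is small on well-posed data
  expect_lt(diff(range(f1@qPerRun)) / min(f1@qPerRun), 0.01)
  ## after rescaling, G columns average 1 so F rows are mean apportioned
  ## mass, and the mass shares coincide with row sums of F
  expect_equal(unname(colMeans(f1@G)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(f1@factorContributionPct),
               unname(100 * rowSums(f1@F) / sum(f1@F)), tolerance = 1e-9)
  ## contributions sum to 100 in both conventions
  ct <- pmfContributions(f1)
  expect_equal(sum(ct$factor_contribution_pct), 100, tolerance = 1e-9)
  expect_equal(sum(ct$factor_contribution_pct_normalized), 100,
               tolerance = 1e-9)
  expect_equal(unname(colSums(ct$species_share_pct)), rep(100, 8),
               tolerance = 1e-9)
})

test_that("factor-count diagnostics expose the true rank as an elbow", {
  d <- generatePMFDataset(n = 30, m = 8, p = 3, noise_level = 0.05, seed = 7)
  X <- concMatrix(d$survey)
  U <- 0.05 * pmax(X, 1e-6) + 1e-6
  dg <- pmfDiagnostics(X, U, p_values = 2:5, n_runs = 8, seed = 1)
  expect_equal(dg$table$Q_expected, 30 * 8 - (2:5) * (30 + 8))
  q <- dg$table$Q
  ## sharp drop up to p = 3, flat afterwards
  expect_gt((q[1] - q[2]) / q[1], 0.5)
  expect_lt((q[2] - q[3]) / q[2], 0.5)
  expect_error(pmfDiagnostics(X, U, p_values = 3), "at least two")
})

test_that("degenerate inputs are rejected", {
  X <- matrix(1:12, 4, 3)
  expect_error(pmfFit(X, abs(X) + 1, p = 3, seed = 1), "rank error")
  expect_error(pmfFit(-X, abs(X) + 1, p = 2, seed = 1), "nonnegative")
  expect_error(pmfFit(X, X * 0, p = 2, seed = 1), "positive")
})
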