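test_that("descriptives match hand computation and degenerate cases", {
  conc <- matrix(10, 8, 4, dimnames = list(c("Pb", "Cr", "Mn", "Cu", "Zn",
                                             "Co", "Ni", "As"), NULL))
  conc["Pb", ] <- c(1, 3, 5, 5)   # residential pair {1,3}; commercial {5,5}
  sv <- SoilSurvey(conc, x = 1:4, y = 4:1,
                   land_use = c("residential", "residential", "commercial",
                                "commercial"))
  d <- describeByLandUse(sv)
  res <- d[d$land_use == "residential" & d$metal == "Pb", ]
  expect_equal(res$mean, 2)
  expect_equal(res$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(res$cv_percent, 100 * sqrt(2) / 2, tolerance = 1e-10)
  com <- d[d$land_use == "commercial" & d$metal == "Pb", ]
  expect_equal(com$sd, 0)
  expect_equal(com$cv_percent, 0)
  ## a singleton stratum is refused
  sv1 <- SoilSurvey(conc[, 1:3], x = 1:3, y = 3:1,
                    land_use = c("residential", "residential", "commercial"))
  expect_error(describeByLandUse(sv1), "fewer than 2")
})

test_that("normality workflow transforms only non-normal samples", {
  ## exact normal quantiles: no rejection, no transform
  q <- qnorm(ppoints(60))
  nt <- normalityTransform(q)
  expect_gt(nt$ks_p, 0.05)
  expect_false(nt$applied)
  expect_identical(nt$transformed, q)
  ## a lognormal sample is rejected and improves after Box-Cox
  set.seed(8)
  x <- rlnorm(200, 0, 0.9)
  nt <- normalityTransform(x)
  expect_lt(nt$ks_p, 0.05)
  expect_true(nt$applied)
  expect_lt(abs(nt$lambda), 0.35)   # ML lambda near log for lognormal data
  expect_gt(nortest::lillie.test(nt$transformed)$p.value, nt$ks_p)
  ## degenerate inputs
  expect_error(normalityTransform(rep(1, 10)), "constant")
  expect_error(normalityTransform(1:4), "at least 5")
})

test_that("one-way F equals brute-force sums of squares", {
  conc <- matrix(5, 8, 9, dimnames = list(c("Pb", "Cr", "Mn", "Cu", "Zn",
                                            "Co", "Ni", "As"), NULL))
  vals <- c(3.1, 4.2, 2.8, 6.5, 7.1, 6.0, 9.3, 8.8, 10.1)
  conc["Pb", ] <- vals
  groups <- rep(c("residential", "commercial", "floodplain"), each = 3)
  sv <- SoilSurvey(conc, x = 1:9, y = 9:1, land_use = groups)
  av <- onewayAnova(sv, "Pb")
  ## independent oracle: explicit between/within mean squares
  g <- factor(groups)
  gm <- tapply(vals, g, mean)
  ssb <- sum(table(g) * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[g])^2)
  Fman <- (ssb / (nlevels(g) - 1)) / (ssw / (length(vals) - nlevels(g)))
  expect_equal(av$F, Fman, tolerance = 1e-12)
  expect_equal(av$p, pf(Fman, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(nrow(av$posthoc), 3)   # all pairs reported

  ## identical group means: F ~ 0, p ~ 1
  conc["Pb", ] <- rep(c(1, 2, 3), times = 3)
  sv0 <- SoilSurvey(conc, x = 1:9, y = 9:1, land_use = groups)
  av0 <- onewayAnova(sv0, "Pb")
  expect_lt(av0$F, 1e-20)
  expect_gt(av0$p, 0.999)

  ## shift invariance and correct scaling
  conc["Pb", ] <- vals + 100
  avs <- onewayAnova(SoilSurvey(conc, x = 1:9, y = 9:1, land_use = groups),
                     "Pb")
  expect_equal(avs$F, av$F, tolerance = 1e-9)
  conc["Pb", ] <- vals * 7
  avm <- onewayAnova(SoilSurvey(conc, x = 1:9, y = 9:1, land_use = groups),
                     "Pb")
  expect_equal(avm$F, av$F, tolerance = 1e-9)
})

test_that("heterogeneous variances switch the post hoc to Games-Howell", {
  set.seed(21)
  conc <- matrix(5, 8, 30, dimnames = list(c("Pb", "Cr", "Mn", "Cu", "Zn",
                                             "Co", "Ni", "As"), NULL))
  groups <- rep(c("residential", "commercial", "floodplain"), each = 10)
  conc["Pb", ] <- c(rnorm(10, 10, 0.1), rnorm(10, 12, 0.1), rnorm(10, 30, 15))
  sv <- SoilSurvey(conc, x = 1:30, y = 30:1, land_use = groups)
  av <- onewayAnova(sv, "Pb")
  expect_lt(av$levene_p, 0.05)
  expect_equal(av$posthoc_method, "games-howell")
  expect_true(all(av$posthoc$p_adj >= 0 & av$posthoc$p_adj <= 1))
  ## the clearly different tight pair is detected
  rc <- av$posthoc[grepl("residential", av$posthoc$pair) &
                   grepl("commercial", av$posthoc$pair), ]
  expect_lt(rc$p_adj, 0.01)
})

test_that("correlation matrices behave as Pearson theory dictates", {
  set.seed(5)
  conc <- matrix(rlnorm(8 * 10, 2, 0.3), 8, 10,
                 dimnames = list(c("Pb", "Cr", "Mn", "Cu", "Zn", "Co", "Ni",
                                   "As"), NULL))
  conc["Zn", ] <- conc["Pb", ]          # duplicate -> r = 1
  conc["Cu", ] <- -conc["Cr", ] + 100   # affine anti-correlation -> r = -1
  sv <- SoilSurvey(conc, x = 1:10, y = 10:1, land_use = rep("commercial", 10))
  ct <- metalCorrelations(sv, "commercial")
  expect_equal(ct$r["Pb", "Zn"], 1, tolerance = 1e-12)
  expect_equal(ct$r["Cr", "Cu"], -1, tolerance = 1e-12)
  expect_equal(ct$r, t(ct$r))
  expect_equal(unname(diag(ct$r)), rep(1, 8))
  ## positive semidefinite on complete data
  expect_gte(min(eigen(ct$r, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  ## independent large samples: mean |r| near 0
  set.seed(6)
  conc2 <- matrix(rnorm(8 * 500, 100, 10), 8, 500,
                  dimnames = list(rownames(conc), NULL))
  sv2 <- SoilSurvey(conc2, x = 1:500, y = 500:1,
                    land_use = rep("commercial", 500))
  r2 <- metalCorrelations(sv2)$r
  expect_lt(mean(abs(r2[upper.tri(r2)])), 0.1)
  ## zero-variance metal reported as missing
  conc["As", ] <- 4
  sv3 <- SoilSurvey(conc, x = 1:10, y = 10:1,
                    land_use = rep("commercial", 10))
  r3 <- metalCorrelations(sv3)$r
  expect_true(all(is.na(r3["As", setdiff(rownames(r3), "As")])))
})
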