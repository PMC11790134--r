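test_that("IDW is exact at sites, bounded, and matches brute force", {
  xy <- rbind(c(0, 0), c(100, 0), c(50, 80))
  v <- c(1, 5, 9)
  grid <- makeStudyGrid(xy, grid_dim = 15)
  surf <- idw(xy, v, grid)
  ## bounded by the data range
  expect_true(all(surf@values >= min(v) & surf@values <= max(v)))
  ## brute-force check at a handful of cells
  P <- cbind(rep(grid$cx, each = grid$ny), rep(grid$cy, times = grid$nx))
  for (i in c(1, 57, 120)) {
    d <- sqrt(rowSums(sweep(xy, 2, P[i, ])^2))
    expect_equal(as.vector(surf@values)[i], sum(v / d^2) / sum(1 / d^2),
                 tolerance = 1e-10)
  }
  ## exact at a site when a cell centre coincides
  g1 <- pointGrid(50, 80)
  expect_equal(as.vector(idw(xy, v, g1)@values), 9)
  ## constant field -> constant surface
  expect_equal(range(idw(xy, c(4, 4, 4), grid)@values), c(4, 4))
  expect_error(idw(xy[0, , drop = FALSE], numeric(0), grid), "at least one")
  expect_error(idw(xy, v, grid, power = 0), "power")
})

test_that("variogram fitting recovers structure and degenerates sanely", {
  set.seed(31)
  xy <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  ## constant field: zero sill
  vm0 <- fitVariogram(xy, rep(3, 200))
  expect_equal(vm0@psill, 0)
  expect_equal(vm0@nugget, 0)
  ## range recovery, judged in the median over independent fields
  ratios <- sapply(1:5, function(s) {
    set.seed(s)
    z <- soilcap:::simulateGRF(xy, 150)
    fitVariogram(xy, z)@range / 150
  })
  expect_lt(abs(median(ratios) - 1), 0.5)
  ## pure-nugget data: spatially shuffled field loses its range
  set.seed(32)
  z <- soilcap:::simulateGRF(xy, 150)
  zs <- sample(z)
  vms <- fitVariogram(xy, zs)
  expect_true(vms@range < 75 || vms@psill < 0.25 * var(zs))
  ## collinear geometry warns but proceeds
  xyl <- cbind(seq(0, 1000, length.out = 30), rep(5, 30))
  expect_warning(fitVariogram(xyl, rnorm(30)), "collinear")
})

test_that("ordinary kriging solves the BLUP system", {
  vm <- new("VariogramModel", model = "exponential", nugget = 0, psill = 2,
            range = 120)
  xy <- rbind(c(0, 0), c(200, 0), c(0, 200), c(150, 150))
  v <- c(3, 7, 5, 10)
  ## hand-assembled kriging system at one prediction point
  p0 <- c(60, 40)
  C <- function(h) (0 + 2) - (0 + 2 * (1 - exp(-h / 120)))
  K <- matrix(1, 5, 5); K[5, 5] <- 0
  D <- as.matrix(dist(xy))
  K[1:4, 1:4] <- C(D)
  rhs <- c(C(sqrt(colSums((t(xy) - p0)^2))), 1)
  w <- solve(K, rhs)
  expected <- sum(w[1:4] * v)
  got <- ordinaryKriging(xy, v, pointGrid(p0[1], p0[2]), vm)
  expect_equal(as.vector(got@values), expected, tolerance = 1e-10)
  ## exactness at a site with zero nugget
  at <- ordinaryKriging(xy, v, pointGrid(150, 150), vm)
  expect_equal(as.vector(at@values), 10, tolerance = 1e-8)
  ## constant field -> constant surface
  grid <- makeStudyGrid(xy, grid_dim = 8)
  cf <- ordinaryKriging(xy, rep(6, 4), grid, vm)
  expect_equal(range(cf@values), c(6, 6))
  ## pure nugget: prediction tends to the global mean away from sites
  vmn <- new("VariogramModel", model = "exponential", nugget = 2,
             psill = 1e-11, range = 120)
  far <- ordinaryKriging(xy, v, pointGrid(5000, 5000), vmn)
  expect_equal(as.vector(far@values), mean(v), tolerance = 1e-6)
  ## duplicated sites are averaged with a warning
  expect_warning(
    dup <- ordinaryKriging(rbind(xy, xy[1, ]), c(v, 9),
                           pointGrid(0, 0), vm),
    "averaged")
  expect_equal(as.vector(dup@values), 6, tolerance = 1e-8)  # mean(3, 9)
})

test_that("variogram-resampling ensemble behaves like kriging done carefully", {
  sv <- generateSurvey(seed = 4)
  xy <- siteCoords(sv)
  z <- log(concMatrix(sv)[, "Pb"])
  grid <- makeStudyGrid(xy, grid_dim = 20)
  ## ensemble of one is ordinary kriging under the fitted model
  e1 <- ebkKriging(xy, z, grid, K = 1, seed = 1)
  ok <- ordinaryKriging(xy, z, grid, fitVariogram(xy, z))
  expect_equal(e1$surface@values, ok@values, tolerance = 1e-12)
  ## fixed seed reproduces bit-identically
  ea <- ebkKriging(xy, z, grid, K = 10, seed = 7)
  eb <- ebkKriging(xy, z, grid, K = 10, seed = 7)
  expect_identical(ea$surface@values, eb$surface@values)
  expect_equal(sum(ea$weights), 1, tolerance = 1e-12)
  ## held-out prediction error no worse than 1.1x ordinary kriging
  set.seed(9)
  hold <- sample(nSites(sv), 8)
  errK <- errE <- numeric(0)
  for (i in hold) {
    gi <- pointGrid(xy[i, 1], xy[i, 2])
    vmf <- fitVariogram(xy[-i, ], z[-i])
    pk <- as.vector(ordinaryKriging(xy[-i, ], z[-i], gi, vmf)@values)
    pe <- as.vector(ebkKriging(xy[-i, ], z[-i], gi, K = 15,
                               seed = i)$surface@values)
    errK <- c(errK, (pk - z[i])^2)
    errE <- c(errE, (pe - z[i])^2)
  }
  expect_lte(sqrt(mean(errE)), 1.1 * sqrt(mean(errK)))
})

test_that("pollution-area detection counts sites and cells consistently", {
  ## three sites, one exceedance: site fraction 33.33 (too few pairs for a
  ## variogram, so the IDW surface carries the area fraction)
  xy <- rbind(c(0, 0), c(100, 0), c(50, 90))
  det <- detectPollutedArea(xy, c(1.2, 1.4, 0.5), grid_dim = 12,
                            method = "idw")
  expect_equal(det$site_fraction, 100 / 3, tolerance = 1e-10)
  ## all contaminated / none contaminated
  sv <- generateSurvey(seed = 6)
  xy <- siteCoords(sv)
  all1 <- detectPollutedArea(xy, rep(0.2, 30), grid_dim = 15)
  expect_equal(c(all1$site_fraction, all1$area_fraction), c(100, 100))
  none <- detectPollutedArea(xy, rep(1.8, 30), grid_dim = 15)
  expect_equal(c(none$site_fraction, none$area_fraction), c(0, 0))
})

test_that("area fractions are stable across grid resolutions", {
  sv <- generateSurvey(seed = 8)
  xy <- siteCoords(sv)
  ## a smooth spatial index: kriging-friendly GRF plus mild trend
  set.seed(8)
  z <- soilcap:::simulateGRF(xy, 500) + xy[, 1] / 1000
  rule <- list(op = "<", threshold = median(z))
  d1 <- detectPollutedArea(xy, z, rule = rule, grid_dim = 50)
  d2 <- detectPollutedArea(xy, z, rule = rule, grid_dim = 100)
  expect_equal(d1$site_fraction, d2$site_fraction)  # grid-independent
  expect_lt(abs(d1$area_fraction - d2$area_fraction), 2)
})
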