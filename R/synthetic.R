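#' Default stratum specifications for the synthetic survey
#'
#' Five land-use strata (residential n=5, commercial n=7, educational n=6,
#' floodplain n=7, agricultural n=5; 30 sites in all) with per-metal means
#' and standard deviations (mg/kg) calibrated to the descriptive statistics
#' of the river-port study the pipeline targets. Each stratum occupies a
#' rectangular block of a 2 km x 2 km study area (an arbitrary local planar
#' origin; no CRS is implied).
#'
#' @return a list of stratum specs: `land_use`, `n_sites`, `mean` and `sd`
#'   (named per metal), `extent` = c(xmin, xmax, ymin, ymax).
#' @export
defaultStrata <- function() {
  mk <- function(land_use, n, mean, sd, extent)
    list(land_use = land_use, n_sites = n,
         mean = stats::setNames(mean, SOIL_METALS),
         sd = stats::setNames(sd, SOIL_METALS), extent = extent)
  list(
    mk("residential", 5L,
       c(115.28, 67.74, 320.69, 17.09, 98.54, 13.97, 22.56, 25.23),
       c(38.96, 72.04, 42.16, 4.17, 36.10, 3.58, 4.42, 6.00),
       c(0, 1000, 1000, 2000)),
    mk("commercial", 7L,
       c(105.33, 72.19, 316.79, 22.51, 61.22, 17.05, 26.51, 32.82),
       c(28.30, 16.60, 42.51, 6.68, 45.70, 2.06, 5.34, 16.77),
       c(1000, 2000, 1000, 2000)),
    mk("educational", 6L,
       c(155.77, 141.68, 300.58, 19.97, 92.80, 11.30, 24.35, 27.89),
       c(42.19, 63.21, 48.46, 4.40, 71.61, 5.11, 3.78, 9.37),
       c(0, 666, 0, 1000)),
    mk("floodplain", 7L,
       c(120.96, 553.68, 280.77, 21.54, 15.21, 5.17, 22.49, 16.88),
       c(16.52, 825.53, 207.95, 26.17, 3.44, 1.20, 13.01, 4.68),
       c(666, 1333, 0, 1000)),
    mk("agricultural", 5L,
       c(173.71, 280.02, 286.70, 21.50, 64.68, 10.92, 23.57, 28.33),
       c(23.19, 492.62, 129.95, 14.93, 54.52, 5.62, 9.36, 16.94),
       c(1333, 2000, 0, 1000)))
}

## Unit-variance Gaussian random field with exponential correlation
## exp(-h/range), simulated exactly at the given coordinates (Cholesky).
simulateGRF <- function(coords, range) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  C <- exp(-d / range)
  L <- chol(C + diag(1e-10, n))
  as.vector(t(L) %*% stats::rnorm(n))
}

#' Generate a synthetic stratified soil survey
#'
#' Concentrations are drawn per metal and stratum from a lognormal whose two
#' moments match the stratum's (mean, sd) exactly. The lognormal latent is a
#' mixture of a smooth Gaussian random field over the study area
#' (exponential correlation, range = 1/4 of the study extent) and
#' independent noise, so empirical variograms are non-degenerate; the two
#' components are weighted `spatial_weight` / `1 - spatial_weight` on the
#' variance scale and the latent stays exactly standard normal. Values are
#' clamped at half the detection limit and flagged below-MDL where at or
#' under it.
#'
#' @param strata list of stratum specs (see [defaultStrata()]).
#' @param seed integer seed; regeneration with the same seed is identical.
#' @param references reference table supplying MDLs.
#' @param spatial_weight share of latent variance carried by the spatial
#'   field, in [0, 1].
#' @return a [SoilSurvey-class] with sites ordered by stratum.
#' @examples
#' sv <- generateSurvey(seed = 1)
#' table(landUse(sv))
#' @export
generateSurvey <- function(strata = defaultStrata(), seed = 1L,
                           references = metalReferences(),
                           spatial_weight = 0.5) {
  if (!length(strata)) stop("at least one stratum spec is required")
  for (s in strata) {
    if (any(s$mean <= 0)) stop("stratum means must be > 0")
    if (any(s$sd < 0)) stop("stratum sds must be >= 0")
    if (s$n_sites < 1) stop("each stratum needs n_sites >= 1")
  }
  if (spatial_weight < 0 || spatial_weight > 1)
    stop("spatial_weight must lie in [0, 1]")
  metals <- names(strata[[1]]$mean)
  set.seed(as.integer(seed))

  xy <- do.call(rbind, lapply(strata, function(s) {
    cbind(x = stats::runif(s$n_sites, s$extent[1], s$extent[2]),
          y = stats::runif(s$n_sites, s$extent[3], s$extent[4]))
  }))
  n <- nrow(xy)
  land_use <- rep(vapply(strata, `[[`, "", "land_use"),
                  vapply(strata, `[[`, 0L, "n_sites"))
  bbox <- c(range(vapply(strata, function(s) s$extent[1:2], numeric(2))),
            range(vapply(strata, function(s) s$extent[3:4], numeric(2))))
  grfRange <- max(bbox[2] - bbox[1], bbox[4] - bbox[3]) / 4

  conc <- matrix(NA_real_, n, length(metals),
                 dimnames = list(NULL, metals))
  strat_idx <- rep(seq_along(strata), vapply(strata, `[[`, 0L, "n_sites"))
  for (j in seq_along(metals)) {
    s_field <- if (spatial_weight > 0) simulateGRF(xy, grfRange)
               else numeric(n)
    z <- sqrt(spatial_weight) * s_field +
      sqrt(1 - spatial_weight) * stats::rnorm(n)
    for (k in seq_along(strata)) {
      idx <- which(strat_idx == k)
      m <- strata[[k]]$mean[j]; s <- strata[[k]]$sd[j]
      sdlog2 <- log(1 + (s / m)^2)
      mulog <- log(m) - sdlog2 / 2
      conc[idx, j] <- exp(mulog + sqrt(sdlog2) * z[idx])
    }
  }
  mdl <- stats::setNames(references$mdl, references$metal)
  mdl <- ifelse(metals %in% names(mdl), mdl[metals], min(references$mdl))
  conc <- pmax(conc, rep(0.5 * mdl, each = n))
  below <- sweep(conc, 2, mdl, "<=")
  SoilSurvey(conc = t(conc), x = xy[, 1], y = xy[, 2], land_use = land_use,
             below_mdl = t(below))
}

#' Generate a receptor-model test set with known factorization
#'
#' Builds nonnegative ground-truth contributions G (n x p) and profiles F
#' (p x m, rows summing to 1), forms X = G F and adds Gaussian noise with
#' sd = `noise_level` x |X_ij|, truncated at 0. Each factor's profile
#' concentrates on its own block of metals (plus a small baseline), making
#' the planted factors well separated; column scales of G are set so factor
#' k carries the fraction `shares[k]` of the total mass.
#'
#' @param n,m,p sites, metals, factors; `p < min(n, m)` is required.
#' @param noise_level relative noise sd (0 for an exact rank-p matrix).
#' @param seed integer seed.
#' @param shares length-p positive mass shares (normalised internally);
#'   default equal shares.
#' @return list with `survey` (a [SoilSurvey-class]), `G_true`, `F_true`,
#'   `noise_sd`, `shares`.
#' @export
generatePMFDataset <- function(n = 30L, m = 8L, p = 3L, noise_level = 0.05,
                               seed = 1L, shares = NULL) {
  if (p >= min(n, m))
    stop("rank error: p must be smaller than min(n, m)")
  if (is.null(shares)) shares <- rep(1 / p, p)
  if (length(shares) != p || any(shares <= 0))
    stop("shares must be length p and positive")
  shares <- shares / sum(shares)
  set.seed(as.integer(seed))
  metals <- if (m == 8) SOIL_METALS else paste0("M", seq_len(m))

  block <- if (p == 1) list(seq_len(m))
           else split(seq_len(m), cut(seq_len(m), p, labels = FALSE))
  Ftrue <- matrix(0.05 + stats::runif(p * m, 0, 0.1), p, m,
                  dimnames = list(paste0("F", seq_len(p)), metals))
  for (k in seq_len(p)) Ftrue[k, block[[k]]] <- Ftrue[k, block[[k]]] + 1
  Ftrue <- Ftrue / rowSums(Ftrue)

  ## gamma draws give realistic site-to-site contribution variability
  ## (CV ~ 0.9); near-constant columns would leave the split of the mean
  ## concentration across factors unidentifiable
  G <- matrix(stats::rgamma(n * p, shape = 1.2, scale = 1), n, p)
  total <- 100 * n                       # arbitrary overall mass scale
  G <- sweep(G, 2, shares * total / colSums(G), "*")
  X <- G %*% Ftrue
  noise_sd <- noise_level * abs(X)
  Xn <- pmax(X + stats::rnorm(n * m, 0, as.vector(noise_sd)), 0)

  survey <- SoilSurvey(conc = t(Xn),
                       x = stats::runif(n, 0, 1000),
                       y = stats::runif(n, 0, 1000),
                       land_use = rep(LAND_USES, length.out = n))
  list(survey = survey, G_true = G, F_true = Ftrue, noise_sd = noise_sd,
       shares = shares)
}
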