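## ---- grid and study-polygon helpers -------------------------------------

## Convex hull of the sites, closed, in counter-clockwise order.
.siteHull <- function(coords) {
  idx <- grDevices::chull(coords)
  hull <- coords[idx, , drop = FALSE]
  ## enforce CCW orientation (chull returns clockwise)
  a <- sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
           c(hull[-1, 1], hull[1, 1]) * hull[, 2])
  if (a < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  hull
}

.pointsInConvex <- function(px, py, hull) {
  inside <- rep(TRUE, length(px))
  nv <- nrow(hull)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (hull[j, 1] - hull[i, 1]) * (py - hull[i, 2]) -
             (hull[j, 2] - hull[i, 2]) * (px - hull[i, 1])
    inside <- inside & cross >= 0
  }
  inside
}

.distToHull <- function(px, py, hull) {
  dmin <- rep(Inf, length(px))
  nv <- nrow(hull)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ax <- hull[i, 1]; ay <- hull[i, 2]
    bx <- hull[j, 1]; by <- hull[j, 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (len2 == 0) 0 else
      pmin(1, pmax(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2))
    dmin <- pmin(dmin, sqrt((px - (ax + t * (bx - ax)))^2 +
                            (py - (ay + t * (by - ay)))^2))
  }
  dmin
}

#' Build the interpolation grid and study-polygon mask
#'
#' A regular grid of cell centres over the bounding box of the sites,
#' expanded by the buffer distance. The mask keeps cells inside the convex
#' hull of the sites buffered by the median nearest-neighbour distance (the
#' study polygon used for all area fractions).
#'
#' @param coords two-column site coordinate matrix.
#' @param grid_dim cells along the longer axis (ignored when `cell_size`
#'   is given).
#' @param cell_size cell size in metres, or NA.
#' @param buffer buffer distance; default the median nearest-neighbour
#'   distance.
#' @return list with `origin`, `cellSize`, `nx`, `ny`, `cx`, `cy` (cell
#'   centre coordinate vectors) and logical `mask` (ny x nx matrix, row 1
#'   southernmost).
#' @export
makeStudyGrid <- function(coords, grid_dim = 100L, cell_size = NA_real_,
                          buffer = NULL) {
  coords <- as.matrix(coords)
  if (is.null(buffer)) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    buffer <- stats::median(apply(d, 1, min))
  }
  xr <- range(coords[, 1]) + c(-buffer, buffer)
  yr <- range(coords[, 2]) + c(-buffer, buffer)
  if (is.na(cell_size))
    cell_size <- max(diff(xr), diff(yr)) / grid_dim
  cx <- seq(xr[1] + cell_size / 2, xr[2], by = cell_size)
  cy <- seq(yr[1] + cell_size / 2, yr[2], by = cell_size)
  hull <- .siteHull(coords)
  px <- rep(cx, each = length(cy))
  py <- rep(cy, times = length(cx))
  ok <- .pointsInConvex(px, py, hull) |
    (.distToHull(px, py, hull) <= buffer)
  mask <- matrix(ok, nrow = length(cy), ncol = length(cx))
  list(origin = c(xr[1] + cell_size / 2, yr[1] + cell_size / 2),
       cellSize = cell_size, nx = length(cx), ny = length(cy),
       cx = cx, cy = cy, mask = mask)
}

.gridCentres <- function(grid)
  cbind(rep(grid$cx, each = grid$ny), rep(grid$cy, times = grid$nx))

.asSurface <- function(grid, vals)
  new("RasterSurface", origin = grid$origin, cellSize = grid$cellSize,
      values = matrix(vals, nrow = grid$ny, ncol = grid$nx),
      mask = grid$mask)

## ---- interpolators -------------------------------------------------------

#' Inverse-distance-weighted interpolation
#'
#' Weights proportional to distance^-power; a cell whose centre coincides
#' with a site takes that site's value exactly. Predictions are convex
#' combinations of the data, hence bounded by its range.
#'
#' @param coords two-column site coordinates.
#' @param values numeric site values.
#' @param grid a grid from [makeStudyGrid()].
#' @param power positive IDW exponent (default 2).
#' @return a [RasterSurface-class].
#' @export
idw <- function(coords, values, grid, power = 2) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("idw needs at least one site")
  if (power <= 0) stop("power must be > 0")
  P <- .gridCentres(grid)
  D <- outer(rowSums(P^2), rowSums(coords^2), "+") -
    2 * P %*% t(coords)
  D <- sqrt(pmax(D, 0))
  pred <- numeric(nrow(P))
  hit <- D < 1e-9
  atSite <- rowSums(hit) > 0
  if (any(atSite))
    pred[atSite] <- values[apply(hit[atSite, , drop = FALSE], 1, which.max)]
  W <- 1 / pmax(D[!atSite, , drop = FALSE], 1e-12)^power
  pred[!atSite] <- (W %*% values) / rowSums(W)
  .asSurface(grid, pred)
}

## Average duplicated site locations, warning once.
.dedupeSites <- function(coords, values) {
  key <- paste(signif(coords[, 1], 12), signif(coords[, 2], 12))
  if (!anyDuplicated(key)) return(list(coords = coords, values = values))
  warning("duplicate site locations averaged before kriging")
  agg <- lapply(split(seq_along(key), key), function(i)
    c(coords[i[1], 1], coords[i[1], 2], mean(values[i])))
  m <- do.call(rbind, agg)
  list(coords = m[, 1:2, drop = FALSE], values = m[, 3])
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction under the supplied semivariogram model,
#' with the usual unbiasedness (unit-sum weight) constraint. With zero
#' nugget the predictor honours the data exactly; under a pure-nugget model
#' it tends to the global mean. Duplicate site locations are averaged with
#' a warning.
#'
#' @param coords,values sites and their values.
#' @param grid a grid from [makeStudyGrid()].
#' @param vm a [VariogramModel-class], e.g. from [fitVariogram()].
#' @return a [RasterSurface-class].
#' @export
ordinaryKriging <- function(coords, values, grid, vm) {
  dd <- .dedupeSites(as.matrix(coords), values)
  coords <- dd$coords; values <- dd$values
  n <- length(values)
  if (vm@psill <= 1e-12 || stats::var(values) == 0)
    return(.asSurface(grid, rep(mean(values), grid$nx * grid$ny)))
  K <- matrix(0, n + 1, n + 1)
  K[1:n, 1:n] <- covarianceValue(vm, as.matrix(stats::dist(coords)))
  K[n + 1, 1:n] <- K[1:n, n + 1] <- 1
  P <- .gridCentres(grid)
  D0 <- sqrt(pmax(outer(rowSums(P^2), rowSums(coords^2), "+") -
                  2 * P %*% t(coords), 0))
  rhs <- rbind(t(covarianceValue(vm, D0)), 1)
  w <- tryCatch(solve(K, rhs), error = function(e) {
    K[1:n, 1:n] <- K[1:n, 1:n] + diag(1e-8 * (vm@nugget + vm@psill), n)
    solve(K, rhs)
  })
  pred <- as.vector(crossprod(w[1:n, , drop = FALSE], values))
  .asSurface(grid, pred)
}

## Gaussian log-likelihood of the data under a variogram model, with the
## mean profiled out by GLS. Used to weight ensemble members.
.variogramLoglik <- function(vm, coords, values) {
  n <- length(values)
  S <- covarianceValue(vm, as.matrix(stats::dist(coords))) + diag(1e-10, n)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Si1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Siz <- backsolve(ch, forwardsolve(t(ch), values))
  mu <- sum(Si1 * values) / sum(Si1)
  r <- values - mu
  Sir <- backsolve(ch, forwardsolve(t(ch), r))
  -sum(log(diag(ch))) - 0.5 * sum(r * Sir)
}

#' Variogram-resampling ensemble predictor
#'
#' Kriging that propagates semivariogram-estimation error, in the spirit of
#' empirical Bayesian kriging: a model is fitted to the data, new values are
#' simulated at the data locations from it, a new semivariogram is refitted
#' to each simulated set, each member model is weighted by the (Bayes-rule)
#' Gaussian likelihood of the observed data under its covariance, and the
#' prediction is the weight-averaged ordinary-kriging surface. With
#' `K = 1` the result is exactly ordinary kriging under the fitted model.
#'
#' @param coords,values sites and their values.
#' @param grid a grid from [makeStudyGrid()].
#' @param K ensemble size (>= 1).
#' @param seed integer seed for the simulation draws.
#' @param model variogram family passed to [fitVariogram()].
#' @return list: `surface` (a [RasterSurface-class]), `models` (list of
#'   member [VariogramModel-class]), `weights`.
#' @export
ebkKriging <- function(coords, values, grid, K = 100L, seed = 1L,
                       model = "exponential") {
  coords <- as.matrix(coords)
  vm0 <- fitVariogram(coords, values, model = model)
  if (K < 1) stop("ensemble size K must be >= 1")
  models <- list(vm0)
  if (K > 1) {
    set.seed(as.integer(seed))
    n <- length(values)
    S <- covarianceValue(vm0, as.matrix(stats::dist(coords))) +
      diag(1e-10, n)
    L <- t(chol(S))
    for (k in 2:K) {
      z <- mean(values) + as.vector(L %*% stats::rnorm(n))
      vmk <- try(fitVariogram(coords, z, model = model), silent = TRUE)
      if (!inherits(vmk, "try-error")) models <- c(models, list(vmk))
    }
  }
  ll <- vapply(models, .variogramLoglik, 0, coords = coords,
               values = values)
  w <- exp(ll - max(ll[is.finite(ll)]))
  w[!is.finite(w)] <- 0
  if (sum(w) == 0) {
    warning("all ensemble weights vanished; falling back to the fitted model")
    models <- list(vm0); w <- 1
  }
  w <- w / sum(w)
  acc <- 0
  for (k in seq_along(models))
    if (w[k] > 0)
      acc <- acc + w[k] * ordinaryKriging(coords, values, grid,
                                          models[[k]])@values
  surf <- new("RasterSurface", origin = c(grid$origin[1], grid$origin[2]),
              cellSize = grid$cellSize, values = acc, mask = grid$mask)
  list(surface = surf, models = models, weights = w)
}

## ---- pollution-area detection -------------------------------------------

#' Detect polluted area from site values and interpolated surfaces
#'
#' Compares the statistical site fraction (percent of sites violating the
#' contamination rule) with the interpolated area fraction (percent of
#' study-polygon cells violating it) on the combined surface — the cellwise
#' mean of the ordinary-kriging and IDW surfaces (`method` switches to
#' either alone).
#'
#' @param coords,values sites and their per-site index values (e.g. a Pi
#'   column or the integrated Pi).
#' @param rule contamination predicate, see [applyRule()]; default Pi < 1.
#' @param grid optional grid from [makeStudyGrid()]; built at `grid_dim`
#'   resolution otherwise.
#' @param grid_dim grid resolution when `grid` is NULL.
#' @param method `"combined"`, `"kriging"` or `"idw"`.
#' @param model variogram family for the kriging component.
#' @return list: `site_fraction`, `area_fraction` (percent), `surface`
#'   (the combined [RasterSurface-class]), `vm` (fitted variogram).
#' @export
detectPollutedArea <- function(coords, values,
                               rule = list(index = "pi", op = "<",
                                           threshold = 1),
                               grid = NULL, grid_dim = 100L,
                               method = c("combined", "kriging", "idw"),
                               model = "exponential") {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (is.null(grid)) grid <- makeStudyGrid(coords, grid_dim = grid_dim)
  if (!any(grid$mask)) stop("study-polygon mask is empty")
  site_fraction <- 100 * mean(applyRule(values, rule))
  surfK <- surfI <- vm <- NULL
  if (method != "idw") {
    vm <- tryCatch(fitVariogram(coords, values, model = model),
                   error = function(e) NULL)
    if (is.null(vm)) {
      warning("variogram fit failed (too few sites?); using IDW only")
      method <- "idw"
    } else surfK <- ordinaryKriging(coords, values, grid, vm)
  }
  if (method != "kriging") surfI <- idw(coords, values, grid)
  vals <- if (method == "combined") (surfK@values + surfI@values) / 2
          else if (method == "kriging") surfK@values else surfI@values
  surface <- new("RasterSurface", origin = grid$origin,
                 cellSize = grid$cellSize, values = vals, mask = grid$mask)
  area_fraction <- 100 * mean(applyRule(vals[grid$mask], rule))
  list(site_fraction = site_fraction, area_fraction = area_fraction,
       surface = surface, vm = vm)
}
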