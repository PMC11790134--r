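## Semivariogram evaluation for the supported models. For the exponential
## model `range` is the e-folding distance of the correlation (practical
## range ~ 3x); for the spherical model the sill is reached exactly at
## `range`.
variogramValue <- function(vm, h) {
  g <- switch(vm@model,
    exponential = vm@psill * (1 - exp(-h / vm@range)),
    spherical = ifelse(h >= vm@range, vm@psill,
                       vm@psill * (1.5 * h / vm@range -
                                   0.5 * (h / vm@range)^3)))
  out <- vm@nugget + g
  out[h == 0] <- 0
  out
}

## Covariance implied by the variogram: C(h) = sill_total - gamma(h),
## with C(0) = nugget + psill.
covarianceValue <- function(vm, h) {
  (vm@nugget + vm@psill) - variogramValue(vm, h)
}

#' Empirical semivariogram
#'
#' Bins site pairs by separation distance and averages
#' \eqn{\frac{1}{2}(z_i - z_j)^2} per bin.
#'
#' @param coords two-column coordinate matrix.
#' @param values numeric vector, one per site.
#' @param n_bins number of distance bins.
#' @param max_dist pair cutoff; default half the maximum pair distance.
#' @return data.frame with `dist` (bin mean distance), `gamma`, `n_pairs`.
#' @export
empiricalVariogram <- function(coords, values, n_bins = 12,
                               max_dist = NULL) {
  d <- stats::dist(coords)
  g <- stats::dist(values)^2 / 2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d > 0 & d <= max_dist
  d <- as.vector(d)[keep]; g <- as.vector(g)[keep]
  if (length(d) < 10) stop("need at least 10 site pairs within max_dist")
  bins <- cut(d, breaks = seq(0, max_dist, length.out = n_bins + 1),
              include.lowest = TRUE)
  out <- data.frame(dist = as.vector(tapply(d, bins, mean)),
                    gamma = as.vector(tapply(g, bins, mean)),
                    n_pairs = as.vector(table(bins)))
  out[!is.na(out$dist), ]
}

#' Fit a semivariogram model
#'
#' Weighted least-squares fit of an exponential or spherical model to the
#' empirical semivariogram, with Cressie weights
#' \eqn{N_h / \gamma_{model}(h)^2}. A constant field yields a degenerate
#' model with zero sill; near-collinear site geometry produces a warning
#' but the fit proceeds.
#'
#' @param coords two-column coordinate matrix.
#' @param values numeric vector of site values.
#' @param model `"exponential"` or `"spherical"`.
#' @param n_bins,max_dist passed to [empiricalVariogram()].
#' @return a [VariogramModel-class].
#' @export
fitVariogram <- function(coords, values,
                         model = c("exponential", "spherical"),
                         n_bins = 12, max_dist = NULL) {
  model <- match.arg(model)
  coords <- as.matrix(coords)
  ## collinearity check: spread orthogonal to the principal axis
  sv <- svd(scale(coords, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    warning("sites are (near-)collinear; variogram fit may be unstable")
  v <- stats::var(values)
  if (v == 0)
    return(new("VariogramModel", model = model, nugget = 0, psill = 0,
               range = max(stats::dist(coords)) / 4))
  ev <- empiricalVariogram(coords, values, n_bins = n_bins,
                           max_dist = max_dist)
  dmax <- max(ev$dist)
  obj <- function(par) {
    vm <- new("VariogramModel", model = model, nugget = par[1],
              psill = max(par[2], 1e-12), range = par[3])
    gm <- variogramValue(vm, ev$dist)
    sum(ev$n_pairs * (ev$gamma - gm)^2 / pmax(gm, 1e-12)^2)
  }
  starts <- expand.grid(nugget = c(0, 0.5 * v),
                        psill = c(0.5 * v, v),
                        range = dmax * c(0.1, 0.3, 0.6))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj,
                            method = "L-BFGS-B",
                            lower = c(0, 1e-12, dmax * 1e-3),
                            upper = c(2 * v, 5 * v, dmax * 5)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed from every start")
  new("VariogramModel", model = model, nugget = best$par[1],
      psill = best$par[2], range = best$par[3])
}
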