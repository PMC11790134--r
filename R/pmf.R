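#' Build the measurement-uncertainty matrix for receptor modelling
#'
#' EPA-convention per-cell uncertainties: for a value at or below the
#' detection limit, u = (5/6) MDL and the concentration is replaced by
#' MDL/2; above it, u = sqrt((sigma_j x)^2 + (0.5 MDL)^2), with sigma_j the
#' metal's relative error fraction.
#'
#' @param survey a [SoilSurvey-class].
#' @param references reference table supplying `mdl` and `sigma` per metal.
#' @return list: `X` (sites x metals, below-MDL values substituted), `U`
#'   (positive uncertainties, same shape), `substituted` (logical matrix).
#' @examples
#' u <- buildUncertainty(generateSurvey(seed = 1))
#' range(u$U)
#' @export
buildUncertainty <- function(survey, references = metalReferences()) {
  X <- concMatrix(survey)
  metals <- colnames(X)
  i <- match(metals, references$metal)
  if (anyNA(i))
    stop("missing sigma/MDL for metal(s): ",
         paste(metals[is.na(i)], collapse = ", "))
  mdl <- references$mdl[i]
  sigma <- references$sigma[i]
  MDL <- matrix(mdl, nrow(X), ncol(X), byrow = TRUE)
  SIG <- matrix(sigma, nrow(X), ncol(X), byrow = TRUE)
  below <- X <= MDL
  U <- ifelse(below, (5 / 6) * MDL,
              sqrt((SIG * X)^2 + (0.5 * MDL)^2))
  Xs <- ifelse(below, MDL / 2, X)
  if (any(U <= 0)) stop("uncertainty matrix must be strictly positive")
  list(X = Xs, U = U, substituted = below)
}

#' PMF solution
#'
#' Weighted nonnegative factorization X ~ G F minimising
#' Q = sum(((X - GF)/U)^2). After fitting, factors are rescaled (leaving
#' G F unchanged) so each row of F sums to the factor's mean apportioned
#' concentration mass.
#'
#' @slot G n x p nonnegative contributions.
#' @slot F p x m nonnegative profiles (concentration units).
#' @slot Q best objective value; `qPerRun` holds all multistart results.
#' @slot r2 per-metal coefficient of determination between X and GF.
#' @slot factorContributionPct length-p mass shares (percent, sum 100).
#' @slot speciesSharePct p x m percent of each metal apportioned to each
#'   factor (columns sum to 100).
#' @slot scaledResiduals (X - GF)/U.
#' @slot converged logical: did the best run meet the tolerance.
#' @export
setClass("PMFSolution",
  representation(G = "matrix", F = "matrix", Q = "numeric",
                 qPerRun = "numeric", r2 = "numeric",
                 factorContributionPct = "numeric",
                 speciesSharePct = "matrix", scaledResiduals = "matrix",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(object@G < 0) || any(object@F < 0))
      msg <- c(msg, "G and F must be nonnegative")
    if (length(object@factorContributionPct) &&
        abs(sum(object@factorContributionPct) - 100) > 1e-6)
      msg <- c(msg, "factor contributions must sum to 100")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PMFSolution", function(object) {
  cat(sprintf("PMFSolution: %d factors, Q = %.4g (%s)\n",
              ncol(object@G), object@Q,
              if (object@converged) "converged" else "not converged"))
  cat("  factor mass shares (%):",
      paste(sprintf("%.1f", object@factorContributionPct), collapse = ", "),
      "\n")
  cat("  per-metal R2:\n")
  print(round(object@r2, 3))
  invisible(NULL)
})

## One multiplicative-update run of weighted NMF. W = 1/U^2. The updates
## keep G, F nonnegative and never increase Q.
.pmfRun <- function(X, W, p, max_iter, tol, init_scale) {
  n <- nrow(X); m <- ncol(X)
  eps <- 1e-12
  G <- matrix(stats::runif(n * p, 0.1, 1), n, p) * init_scale
  F <- matrix(stats::runif(p * m, 0.1, 1), p, m)
  WX <- W * X
  Qold <- Inf
  qTrace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    GF <- G %*% F
    G <- G * ((WX %*% t(F)) / pmax((W * GF) %*% t(F), eps))
    GF <- G %*% F
    F <- F * ((t(G) %*% WX) / pmax(t(G) %*% (W * GF), eps))
    Q <- sum(W * (X - G %*% F)^2)
    qTrace <- c(qTrace, Q)
    if (is.finite(Qold) && (Qold - Q) <= tol * max(Qold, eps)) {
      converged <- TRUE
      break
    }
    Qold <- Q
  }
  list(G = G, F = F, Q = Q, qTrace = qTrace, converged = converged)
}

#' Fit the PMF receptor model
#'
#' Uncertainty-weighted nonnegative factorization by multiplicative updates
#' (weights 1/U^2), restarted from `n_runs` seeded random initialisations;
#' the run with the lowest Q wins. Iteration stops when the relative Q
#' decrease falls below `tol` or at `max_iter`.
#'
#' @param X sites x metals concentration matrix (below-MDL substituted, see
#'   [buildUncertainty()]).
#' @param U positive uncertainty matrix, same shape.
#' @param p number of factors, `p < min(n, m)`.
#' @param n_runs multistart runs (default 20).
#' @param seed integer seed.
#' @param max_iter,tol iteration cap and relative convergence tolerance.
#' @return a [PMFSolution-class].
#' @examples
#' d <- generatePMFDataset(n = 20, m = 6, p = 2, noise_level = 0, seed = 1)
#' X <- concMatrix(d$survey)
#' fit <- pmfFit(X, U = 0.05 * X + 0.01, p = 2, n_runs = 3, seed = 1)
#' fit@Q
#' @export
pmfFit <- function(X, U, p, n_runs = 20L, seed = 1L, max_iter = 5000L,
                   tol = 1e-6) {
  X <- as.matrix(X); U <- as.matrix(U)
  n <- nrow(X); m <- ncol(X)
  if (p >= min(n, m)) stop("rank error: p must be smaller than min(n, m)")
  if (any(X < 0)) stop("X must be nonnegative (apply below-MDL substitution)")
  if (any(U <= 0)) stop("U must be strictly positive")
  W <- 1 / U^2
  init_scale <- sqrt(mean(X) / max(p, 1))
  set.seed(as.integer(seed))
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs))
    runs[[r]] <- .pmfRun(X, W, p, max_iter, tol, init_scale)
  qs <- vapply(runs, `[[`, 0, "Q")
  best <- runs[[which.min(qs)]]
  if (!best$converged)
    warning("best run hit max_iter before meeting the tolerance")

  ## rescale: row k of F sums to factor k's mean apportioned mass; GF fixed
  G <- best$G; F <- best$F
  s <- colMeans(G)
  live <- s > 0
  G[, live] <- sweep(G[, live, drop = FALSE], 2, s[live], "/")
  F[live, ] <- sweep(F[live, , drop = FALSE], 1, s[live], "*")
  GF <- G %*% F
  dimnames(F) <- list(paste0("F", seq_len(p)), colnames(X))
  dimnames(G) <- list(rownames(X), paste0("F", seq_len(p)))

  r2 <- vapply(seq_len(m), function(j) {
    if (stats::sd(X[, j]) == 0 || stats::sd(GF[, j]) == 0) return(NA_real_)
    stats::cor(X[, j], GF[, j])^2
  }, 0)
  names(r2) <- colnames(X)
  contrib <- pmfShares(G, F)
  new("PMFSolution", G = G, F = F, Q = best$Q, qPerRun = qs, r2 = r2,
      factorContributionPct = contrib$factor_pct,
      speciesSharePct = contrib$species_pct,
      scaledResiduals = (X - GF) / U, converged = best$converged)
}

## Mass-based shares. species_pct[k, j]: percent of metal j's modelled mass
## apportioned to factor k; factor_pct[k]: percent of total modelled mass.
pmfShares <- function(G, F) {
  p <- ncol(G)
  M <- t(vapply(seq_len(p), function(k) colMeans(outer(G[, k], F[k, ])),
                numeric(ncol(F))))   # p x m mean apportioned mass
  if (any(rowSums(M) == 0)) warning("factor with zero mass")
  colTot <- colSums(M)
  species_pct <- 100 * sweep(M, 2, ifelse(colTot > 0, colTot, 1), "/")
  factor_pct <- 100 * rowSums(M) / sum(M)
  dimnames(species_pct) <- dimnames(M) <- list(rownames(F), colnames(F))
  list(factor_pct = factor_pct, species_pct = species_pct)
}

#' Factor contributions and species shares
#'
#' Mass-based apportionment of a fitted solution: the percent of the total
#' modelled concentration mass carried by each factor, and per metal the
#' percent split across factors (columns sum to 100). The alternative
#' normalised-contribution convention (factors weighted by mean normalised
#' G) is reported alongside.
#'
#' @param solution a [PMFSolution-class].
#' @return list: `factor_contribution_pct`, `species_share_pct`,
#'   `factor_contribution_pct_normalized`.
#' @export
pmfContributions <- function(solution) {
  sh <- pmfShares(solution@G, solution@F)
  gn <- colMeans(solution@G)
  list(factor_contribution_pct = sh$factor_pct,
       species_share_pct = sh$species_pct,
       factor_contribution_pct_normalized = 100 * gn / sum(gn))
}

#' Factor-count diagnostics
#'
#' Fits the model for each candidate factor count and tabulates the best Q,
#' Q divided by its expected value (nm - p(n+m)), the percentage of scaled
#' residuals outside [-3, 3] and the worst per-metal R2 — the quantities
#' used to choose p.
#'
#' @param X,U as in [pmfFit()].
#' @param p_values candidate factor counts (>= 2 of them).
#' @param ... passed to [pmfFit()] (`n_runs`, `seed`, ...).
#' @return list: `table` (data.frame, one row per p), `solutions` (named
#'   list of [PMFSolution-class]).
#' @export
pmfDiagnostics <- function(X, U, p_values = 3:5, ...) {
  if (length(p_values) < 2) stop("need at least two candidate factor counts")
  n <- nrow(X); m <- ncol(X)
  sols <- lapply(p_values, function(p) pmfFit(X, U, p, ...))
  names(sols) <- paste0("p", p_values)
  tab <- data.frame(
    p = p_values,
    Q = vapply(sols, function(s) s@Q, 0),
    Q_expected = n * m - p_values * (n + m),
    pct_resid_outside_3 = vapply(sols, function(s)
      100 * mean(abs(s@scaledResiduals) > 3), 0),
    min_r2 = vapply(sols, function(s) min(s@r2, na.rm = TRUE), 0),
    row.names = NULL)
  tab$Q_over_Qexp <- tab$Q / pmax(tab$Q_expected, 1)
  list(table = tab, solutions = sols)
}
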