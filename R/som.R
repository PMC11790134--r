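#' Self-organizing-map fit
#'
#' Result of training a rectangular batch SOM on standardised metal
#' concentrations and clustering its codebook vectors.
#'
#' @slot codebook units x variables matrix of codebook vectors.
#' @slot gridRows,gridCols map dimensions; unit u sits at row
#'   `(u-1) %% gridRows + 1`, column `(u-1) %/% gridRows + 1`.
#' @slot bmu best-matching unit index per sample.
#' @slot quantError mean distance of samples to their BMU.
#' @slot dbiByK Davies-Bouldin index per candidate cluster count.
#' @slot bestK cluster count minimising the DBI.
#' @slot unitCluster cluster label per codebook unit (for `bestK`).
#' @slot sampleCluster cluster label per sample (its BMU's cluster).
#' @export
setClass("SOMFit",
  representation(codebook = "matrix", gridRows = "integer",
                 gridCols = "integer", bmu = "integer",
                 quantError = "numeric", dbiByK = "numeric",
                 bestK = "integer", unitCluster = "integer",
                 sampleCluster = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@codebook) != object@gridRows * object@gridCols)
      msg <- c(msg, "codebook must have gridRows*gridCols units")
    if (length(object@bestK) == 1 && length(object@dbiByK) &&
        !is.na(object@bestK)) {
      kmin <- as.integer(names(which.min(object@dbiByK)))
      if (object@bestK != kmin)
        msg <- c(msg, "bestK must minimise dbiByK")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SOMFit", function(object) {
  cat(sprintf("SOMFit: %d x %d map, %d samples, quantisation error %.4g\n",
              object@gridRows, object@gridCols, length(object@bmu),
              object@quantError))
  if (length(object@dbiByK))
    cat(sprintf("  best k = %d (DBI %.3f)\n", object@bestK,
                min(object@dbiByK)))
  invisible(NULL)
})

.somUnitCoords <- function(rows, cols)
  cbind(rep(seq_len(rows), times = cols), rep(seq_len(cols), each = rows))

.bmuOf <- function(X, codebook) {
  D <- outer(rowSums(X^2), rowSums(codebook^2), "+") - 2 * X %*% t(codebook)
  max.col(-D, ties.method = "first")
}

#' Default SOM grid size
#'
#' The usual 5*sqrt(n)-unit heuristic, split into an aspect-balanced
#' rectangle (about 6 x 5 for n = 30).
#'
#' @param n number of samples.
#' @return c(rows, cols).
#' @export
somGridSize <- function(n) {
  units <- max(4, ceiling(5 * sqrt(n)))
  rows <- ceiling(sqrt(units))
  cols <- ceiling(units / rows)
  c(rows = rows, cols = cols)
}

#' Train a batch self-organizing map
#'
#' Rectangular-topology batch SOM with a Gaussian neighbourhood whose
#' radius shrinks linearly from `max(rows, cols)/2` to 1 over the epochs.
#' Codebook vectors are initialised from seeded draws of the data (with
#' small jitter), so training is deterministic given the seed. Input is
#' expected column-standardised (zero mean, unit sd); [prepareSOMInput()]
#' does this.
#'
#' @param X numeric n x m matrix, standardised per column.
#' @param rows,cols map dimensions (rows*cols >= 4); defaults from
#'   [somGridSize()].
#' @param epochs training epochs.
#' @param seed integer seed.
#' @return a [SOMFit-class] (clustering slots empty until
#'   [clusterCodebook()]).
#' @export
trainSOM <- function(X, rows = NULL, cols = NULL, epochs = 50L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(rows) || is.null(cols) || is.na(rows) || is.na(cols)) {
    g <- somGridSize(n); rows <- g[1]; cols <- g[2]
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  U <- rows * cols
  if (U < 4) stop("map needs at least 4 units")
  if (n < U / 4) warning("sparse map: fewer samples than units/4")
  set.seed(as.integer(seed))
  init_idx <- sample.int(n, U, replace = TRUE)
  codebook <- X[init_idx, , drop = FALSE] +
    matrix(stats::rnorm(U * ncol(X), 0, 0.05), U)
  uc <- .somUnitCoords(rows, cols)
  G2 <- as.matrix(stats::dist(uc))^2   # squared grid distances
  r0 <- max(rows, cols) / 2
  for (e in seq_len(epochs)) {
    radius <- r0 + (1 - r0) * (e - 1) / max(epochs - 1, 1)
    bmu <- .bmuOf(X, codebook)
    H <- exp(-G2[, bmu, drop = FALSE] / (2 * radius^2))  # units x samples
    denom <- rowSums(H)
    upd <- denom > 1e-12
    codebook[upd, ] <- (H[upd, , drop = FALSE] %*% X) / denom[upd]
  }
  bmu <- .bmuOf(X, codebook)
  qe <- mean(sqrt(rowSums((X - codebook[bmu, , drop = FALSE])^2)))
  rownames(codebook) <- paste0("u", seq_len(U))
  colnames(codebook) <- colnames(X)
  new("SOMFit", codebook = codebook, gridRows = rows, gridCols = cols,
      bmu = as.integer(bmu), quantError = qe, dbiByK = numeric(0),
      bestK = NA_integer_, unitCluster = integer(0),
      sampleCluster = integer(0))
}

#' Standardise survey concentrations for the SOM
#'
#' @param survey a [SoilSurvey-class].
#' @return z-scored sites x metals matrix.
#' @export
prepareSOMInput <- function(survey) scale(concMatrix(survey))

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst pairwise \eqn{(\sigma_i + \sigma_j) /
#' d_{ij}}, with \eqn{\sigma} the mean distance of members to their
#' centroid and \eqn{d} the centroid separation. Lower is better.
#'
#' @param X data matrix.
#' @param labels integer cluster labels.
#' @return scalar DBI.
#' @export
daviesBouldin <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  sig <- vapply(seq_along(ks), function(i) {
    M <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2, cent[i, ])^2)))
  }, 0)
  Dc <- as.matrix(stats::dist(cent))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) (sig[i] + sig[j]) / Dc[i, j],
               0))
  }, 0))
}

#' Cluster SOM codebook vectors with DBI-selected k
#'
#' Runs k-means (10 restarts) on the codebook vectors of the BMU-occupied
#' units for each candidate k, scores each clustering with the
#' Davies-Bouldin index and keeps the minimiser. Unoccupied units — the
#' interpolating units a small map places between data regions — carry no
#' samples and would otherwise dominate the validity index; they are
#' assigned afterwards to the nearest cluster centroid. Samples inherit
#' the cluster of their best-matching unit. Candidate counts outside
#' `[2, occupied units - 1]` are dropped; a k for which every restart
#' produces an empty or singleton cluster is skipped with a warning — a
#' singleton has zero dispersion, which drives the DBI toward zero as k
#' approaches the number of units and would make the index select
#' degenerate partitions.
#'
#' @param som a [SOMFit-class] from [trainSOM()].
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed integer seed for the k-means restarts.
#' @return the [SOMFit-class] with `dbiByK`, `bestK`, `unitCluster`,
#'   `sampleCluster` filled.
#' @export
clusterCodebook <- function(som, k_range = 2:10, seed = 1L) {
  occ <- sort(unique(som@bmu))
  cb <- som@codebook[occ, , drop = FALSE]
  k_range <- k_range[k_range >= 2 & k_range <= nrow(cb) - 1]
  if (!length(k_range)) stop("no admissible k in k_range")
  set.seed(as.integer(seed))
  dbi <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    best_km <- NULL
    for (rs in seq_len(10)) {
      km <- tryCatch(stats::kmeans(cb, centers = k_range[i], nstart = 1,
                                   iter.max = 100),
                     error = function(e) NULL)
      if (is.null(km) || min(table(km$cluster)) < 2) next
      if (is.null(best_km) || km$tot.withinss < best_km$tot.withinss)
        best_km <- km
    }
    if (is.null(best_km)) {
      warning("k = ", k_range[i],
              " skipped (no partition without empty/singleton clusters)")
      next
    }
    labs[[i]] <- best_km$cluster
    dbi[i] <- daviesBouldin(cb, best_km$cluster)
  }
  ok <- !is.na(dbi)
  if (!any(ok)) stop("clustering failed for every k")
  best <- which.min(ifelse(ok, dbi, Inf))
  occLab <- labs[[best]]
  ## extend occupied-unit clusters to the full map via nearest centroid
  cent <- t(vapply(sort(unique(occLab)), function(k)
    colMeans(cb[occLab == k, , drop = FALSE]), numeric(ncol(cb))))
  allLab <- integer(nrow(som@codebook))
  allLab[occ] <- occLab
  unocc <- setdiff(seq_len(nrow(som@codebook)), occ)
  if (length(unocc)) {
    D <- outer(rowSums(som@codebook[unocc, , drop = FALSE]^2),
               rowSums(cent^2), "+") -
      2 * som@codebook[unocc, , drop = FALSE] %*% t(cent)
    allLab[unocc] <- max.col(-D, ties.method = "first")
  }
  som@dbiByK <- dbi[ok]
  som@bestK <- as.integer(k_range[best])
  som@unitCluster <- allLab
  som@sampleCluster <- allLab[som@bmu]
  validObject(som)
  som
}

#' Component planes of a trained SOM
#'
#' One grid per variable: the codebook values of that variable arranged on
#' the map. Correlated variables show spatially correlated planes; the
#' Pearson correlation between two planes (over units) summarises their
#' association.
#'
#' @param som a [SOMFit-class].
#' @return named list of gridRows x gridCols matrices.
#' @export
componentPlanes <- function(som) {
  lapply(stats::setNames(colnames(som@codebook), colnames(som@codebook)),
         function(v) matrix(som@codebook[, v], som@gridRows, som@gridCols))
}

#' @describeIn componentPlanes correlation matrix between component planes.
#' @export
planeCorrelations <- function(som) stats::cor(som@codebook)
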