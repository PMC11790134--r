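## Shared fixture builders and independent oracles.

## Tiny hand-sized survey: explicit concentrations, 5 sites, all 8 metals.
toySurvey <- function() {
  conc <- rbind(
    Pb = c(50, 100, 120, 200, 64.1),
    Cr = c(100, 50, 553.68, 2416.24, 13.02),
    Mn = c(2000, 320, 280, 746.36, 42.16),
    Cu = c(100, 17, 21.5, 80.62, 4.17),
    Zn = c(300, 98, 15.2, 236.5, 3.44),
    Co = c(50, 14, 5.2, 20.22, 1.2),
    Ni = c(100, 22.6, 22.5, 51.83, 3.78),
    As = c(20, 25.2, 16.9, 69.43, 4.68))
  SoilSurvey(conc = conc, x = c(0, 100, 200, 150, 50),
             y = c(0, 50, 100, 200, 150),
             land_use = c("residential", "commercial", "educational",
                          "floodplain", "agricultural"))
}

## Three well-separated 8-dimensional blobs, 10 samples each (standardised).
plantedBlobs <- function(seed = 1, within_sd = 1) {
  centers <- rbind(c( 3, 3, 0, 0, -3, -3, 0, 0),
                   c(-3, 0, 3, 3, 0, 0, -3, 0),
                   c( 0, -3, -3, 0, 3, 0, 3, 3))
  set.seed(seed)
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(10 * 8, 0, within_sd), 10, 8), 2, centers[k, ], "+")))
  colnames(X) <- paste0("V", 1:8)
  scale(X)
}

## Match estimated factor profiles to truth (rows of both matrices) by
## maximising total cosine similarity: Hungarian assignment when clue is
## available, exhaustive permutation search otherwise. Returns the
## permutation `perm` (truth row i matches estimate row perm[i]) and the
## mean matched cosine.
matchFactors <- function(F_true, F_hat) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  p <- nrow(F_true)
  S <- outer(seq_len(p), seq_len(p),
             Vectorize(function(i, j) cosine(F_true[i, ], F_hat[j, ])))
  if (requireNamespace("clue", quietly = TRUE)) {
    perm <- as.integer(clue::solve_LSAP(S, maximum = TRUE))
  } else {
    perms <- as.matrix(expand.grid(rep(list(seq_len(p)), p)))
    perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
    sc <- apply(perms, 1, function(pm) mean(S[cbind(seq_len(p), pm)]))
    perm <- as.integer(perms[which.max(sc), ])
  }
  list(perm = perm, mean_cosine = mean(S[cbind(seq_len(p), perm)]))
}

## Brute-force Davies-Bouldin, written independently of the package version.
dbiBruteForce <- function(X, labels) {
  ks <- sort(unique(labels))
  K <- length(ks)
  cen <- lapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]))
  sig <- numeric(K)
  for (i in 1:K) {
    M <- X[labels == ks[i], , drop = FALSE]
    sig[i] <- mean(apply(M, 1, function(r) sqrt(sum((r - cen[[i]])^2))))
  }
  total <- 0
  for (i in 1:K) {
    worst <- -Inf
    for (j in 1:K) {
      if (i == j) next
      d <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      worst <- max(worst, (sig[i] + sig[j]) / d)
    }
    total <- total + worst
  }
  total / K
}

## Minimal one-cell grid centred at a point (for cross-validation kriging).
pointGrid <- function(x, y) {
  list(origin = c(x, y), cellSize = 1, nx = 1L, ny = 1L, cx = x, cy = y,
       mask = matrix(TRUE, 1, 1))
}
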