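#' Descriptive statistics by land-use stratum
#'
#' Mean, unbiased (n-1) standard deviation and coefficient of variation
#' (CV% = 100 sd / mean) of every metal within every land-use stratum.
#'
#' @param survey a [SoilSurvey-class]; every represented stratum needs
#'   n >= 2.
#' @return data.frame with columns `land_use`, `metal`, `n`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
describeByLandUse <- function(survey) {
  X <- concMatrix(survey)
  lu <- droplevels(landUse(survey))
  cnt <- table(lu)
  if (any(cnt < 2))
    stop("sd undefined: stratum with fewer than 2 sites: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  out <- do.call(rbind, lapply(levels(lu), function(g) {
    sub <- X[lu == g, , drop = FALSE]
    data.frame(land_use = g, metal = colnames(X), n = nrow(sub),
               mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
               row.names = NULL)
  }))
  out$cv_percent <- ifelse(out$mean == 0, 0, 100 * out$sd / out$mean)
  out
}

#' Normality check and Box-Cox transformation
#'
#' Tests normality with the Lilliefors-corrected Kolmogorov-Smirnov test
#' (parameters estimated from the sample), estimates the Box-Cox
#' \eqn{\lambda} by profile maximum likelihood, and applies the
#' transformation only when the test rejects normality at
#' `alpha` — the pre-processing step the index and variance analyses assume.
#' Non-positive inputs are shifted by `-min + eps` first (the shift is
#' reported).
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @param alpha rejection level for the normality test (default 0.05).
#' @return list: `ks_p`, `lambda`, `transformed` (the working vector:
#'   transformed when normality was rejected, otherwise the input),
#'   `applied` (logical), `shift`.
#' @export
normalityTransform <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 5)
    stop("need at least 5 values for a normality assessment")
  if (stats::sd(values) == 0)
    stop("values are constant; normality test undefined")
  ks_p <- nortest::lillie.test(values)$p.value
  shift <- 0
  if (min(values) <= 0) {
    shift <- -min(values) + 1e-6 * diff(range(values))
    values_pos <- values + shift
  } else values_pos <- values
  bc <- MASS::boxcox(values_pos ~ 1, lambda = seq(-3, 3, 0.01),
                     plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  applied <- ks_p < alpha
  transformed <- if (!applied) values
  else if (abs(lambda) < 1e-8) log(values_pos)
  else (values_pos^lambda - 1) / lambda
  list(ks_p = ks_p, lambda = lambda, transformed = transformed,
       applied = applied, shift = shift)
}

## Games-Howell pairwise comparisons: Welch t statistics referred to the
## studentized-range distribution; used when variances are heterogeneous.
gamesHowell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  st <- data.frame(n = tapply(values, groups, length),
                   m = tapply(values, groups, mean),
                   v = tapply(values, groups, stats::var))
  pairs <- utils::combn(levels(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    a <- st[pr[1], ]; b <- st[pr[2], ]
    se2 <- a$v / a$n + b$v / b$n
    t <- (a$m - b$m) / sqrt(se2)
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(diff = a$m - b$m, t = t, df = df, p_adj = p)
  })
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
             t(out), row.names = NULL)
}

#' One-way ANOVA across land-use strata with post-hoc comparisons
#'
#' Classical one-way F test of a metal's concentrations across land-use
#' strata. A Levene pre-test (Brown-Forsythe median centring) decides the
#' post-hoc family: Tukey HSD when variances are homogeneous, Games-Howell
#' when they are not. Optionally the Box-Cox-normalised values from
#' [normalityTransform()] are analysed instead of the raw ones.
#'
#' @param survey a [SoilSurvey-class].
#' @param metal metal name.
#' @param transform analyse Box-Cox-normalised values when the raw values
#'   fail the normality test (default FALSE: raw concentrations).
#' @return list: `F`, `p`, `df`, `levene_p`, `posthoc_method`, `posthoc`
#'   (data.frame with pair, diff, adjusted p).
#' @export
onewayAnova <- function(survey, metal, transform = FALSE) {
  X <- concMatrix(survey)
  if (!metal %in% colnames(X)) stop("unknown metal: ", metal)
  values <- X[, metal]
  groups <- droplevels(landUse(survey))
  if (nlevels(groups) < 2) stop("need at least 2 land-use strata")
  if (any(table(groups) < 2)) stop("every stratum needs n >= 2")
  if (transform) values <- normalityTransform(values)$transformed

  fit <- stats::aov(values ~ groups)
  atab <- summary(fit)[[1]]
  lev <- car::leveneTest(values ~ groups)
  levene_p <- lev[["Pr(>F)"]][1]
  if (levene_p >= 0.05) {
    tk <- stats::TukeyHSD(fit)$groups
    posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
    method <- "tukey"
  } else {
    gh <- gamesHowell(values, groups)
    posthoc <- gh[c("pair", "diff", "p_adj")]
    method <- "games-howell"
  }
  list(F = atab[["F value"]][1], p = atab[["Pr(>F)"]][1],
       df = atab[["Df"]], levene_p = levene_p, posthoc_method = method,
       posthoc = posthoc)
}

#' Pearson correlations between metals within a stratum
#'
#' Pairwise Pearson r with two-tailed t-test p-values for the sites of one
#' land-use stratum (or the whole survey). Zero-variance metals are
#' reported as NA.
#'
#' @param survey a [SoilSurvey-class].
#' @param stratum a land-use level, or NULL for all sites.
#' @return list of two matrices, `r` and `p` (symmetric, unit/zero
#'   diagonal).
#' @export
metalCorrelations <- function(survey, stratum = NULL) {
  X <- concMatrix(survey)
  if (!is.null(stratum)) {
    keep <- landUse(survey) == stratum
    if (sum(keep) < 3) stop("stratum needs n >= 3 for correlation")
    X <- X[keep, , drop = FALSE]
  }
  m <- ncol(X)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(colnames(X), colnames(X)))
  diag(r) <- 1; diag(p) <- 0
  sds <- apply(X, 2, stats::sd)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (sds[i] == 0 || sds[j] == 0) next
    ct <- stats::cor.test(X[, i], X[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Full land-use statistics report
#'
#' Bundles the descriptive table, per-metal normality/ANOVA results and
#' per-stratum correlation matrices.
#'
#' @inheritParams onewayAnova
#' @return list: `descriptives`, `tests` (per-metal data.frame with ks_p,
#'   boxcox lambda, F, p, levene p, post-hoc method), `posthoc` (named list),
#'   `correlations` (named list of r/p matrices per stratum).
#' @export
landUseStats <- function(survey, transform = FALSE) {
  metals <- metalNames(survey)
  tests <- lapply(metals, function(mt) {
    nt <- normalityTransform(concMatrix(survey)[, mt])
    av <- onewayAnova(survey, mt, transform = transform)
    list(row = data.frame(metal = mt, ks_p = nt$ks_p, lambda = nt$lambda,
                          transformed = nt$applied, levene_p = av$levene_p,
                          F = av$F, p = av$p,
                          posthoc_method = av$posthoc_method),
         posthoc = av$posthoc)
  })
  strata <- levels(droplevels(landUse(survey)))
  cors <- lapply(stats::setNames(strata, strata), function(g)
    if (sum(landUse(survey) == g) >= 3) metalCorrelations(survey, g) else NULL)
  list(descriptives = describeByLandUse(survey),
       tests = do.call(rbind, lapply(tests, `[[`, "row")),
       posthoc = stats::setNames(lapply(tests, `[[`, "posthoc"), metals),
       correlations = cors)
}
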