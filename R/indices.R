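#' Single-metal pollution indices
#'
#' Elementary index kernels, vectorised over concentrations.
#'
#' `contaminationFactor()` is the ratio of measured concentration to the
#' geochemical background, CF = Ci / Cb. `ecologicalRisk()` is Hakanson's
#' toxicity-weighted factor ER = Tr x CF. `nemerowSingle()` is the
#' single-metal Nemerow index NPI = Ci / Sj against the standard limit.
#'
#' @param Ci measured concentration (mg/kg).
#' @param Cb geochemical background (mg/kg), > 0.
#' @param Tr toxic-response factor, > 0.
#' @param cf contamination factor.
#' @param Sj standard limit (mg/kg), > 0.
#' @return numeric vector of index values.
#' @examples
#' contaminationFactor(553.68, 100)  # 5.5368: five-fold background exceedance
#' ecologicalRisk(10, 2)             # 20
#' @export
contaminationFactor <- function(Ci, Cb) {
  if (any(Cb <= 0)) stop("reference error: background Cb must be > 0")
  Ci / Cb
}

#' @rdname contaminationFactor
#' @export
ecologicalRisk <- function(Tr, cf) {
  if (any(Tr <= 0)) stop("reference error: toxic-response factor must be > 0")
  Tr * cf
}

#' @rdname contaminationFactor
#' @export
nemerowSingle <- function(Ci, Sj) {
  if (any(Sj <= 0)) stop("reference error: standard limit Sj must be > 0")
  Ci / Sj
}

#' Integrated Nemerow combinations
#'
#' `nemerowIntegrated()` combines single-metal NPI values at one site with
#' the classical high-end-emphasising form
#' \eqn{\sqrt{(\overline{NPI}^2 + \max(NPI)^2)/2}}. `nemerowLow()` is the
#' mirrored low-end-emphasising form \eqn{\sqrt{(\bar{v}^2 + \min(v)^2)/2}}
#' used when integrating residual-capacity values, where the worst condition
#' is the smallest value.
#'
#' @param values per-metal index values at one site (non-empty).
#' @return scalar combined index.
#' @export
nemerowIntegrated <- function(values) {
  if (!length(values)) stop("no index values to integrate")
  sqrt((mean(values)^2 + max(values)^2) / 2)
}

#' @rdname nemerowIntegrated
#' @export
nemerowLow <- function(values) {
  if (!length(values)) stop("no index values to integrate")
  sqrt((mean(values)^2 + min(values)^2) / 2)
}

#' Environmental pollution capacity index
#'
#' The existing capacity per hectare is Qi = 1e-6 x M x (Cs - Ci), the total
#' capacity Qib = 1e-6 x M x (Cs - Cb), and the capacity index their ratio
#' Pi = Qi / Qib = (Cs - Ci) / (Cs - Cb). Pi equals 1 on background soil,
#' 0 when the concentration reaches the screening value, and is negative
#' beyond it (capacity overdrawn); it does not depend on M.
#'
#' @param Ci measured concentration (mg/kg).
#' @param Cs risk-screening value (mg/kg), must exceed `Cb`.
#' @param Cb geochemical background (mg/kg).
#' @param M soil mass per hectare (kg/ha).
#' @return list with vectors `qi`, `qib`, `pi`.
#' @examples
#' capacityPi(50, 120, 50)$pi   # 1: background soil, full residual capacity
#' capacityPi(120, 120, 50)$pi  # 0: capacity exhausted at the screening value
#' @export
capacityPi <- function(Ci, Cs, Cb, M = 2.25e6) {
  if (any(Cs <= Cb)) stop("reference error: screening Cs must exceed background Cb")
  if (M <= 0) stop("soil mass M must be > 0")
  qi <- 1e-6 * M * (Cs - Ci)
  qib <- 1e-6 * M * (Cs - Cb)
  list(qi = qi, qib = qib, pi = qi / qib)
}

#' Integrate per-metal capacity indices across a survey
#'
#' Each metal's Pi values are first range-normalised over the survey to
#' [0, 1] (a metal with constant Pi across all sites maps to 0.5 by
#' convention), then combined per site. The default low-end-emphasising
#' Nemerow combination \eqn{\sqrt{(\bar v^2 + \min(v)^2)/2}} stresses the
#' metal with the least residual capacity; `method = "mean"` averages
#' instead.
#'
#' @param pi_matrix numeric matrix of Pi values, sites in rows, metals in
#'   columns.
#' @param method `"nemerow_min"` or `"mean"`.
#' @return numeric vector of integrated Pi per site, in [0, 1].
#' @export
integratePi <- function(pi_matrix, method = c("nemerow_min", "mean")) {
  method <- match.arg(method)
  pi_matrix <- as.matrix(pi_matrix)
  if (!ncol(pi_matrix)) stop("pi_matrix has no metals")
  norm <- apply(pi_matrix, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  })
  norm <- matrix(norm, nrow = nrow(pi_matrix))
  if (method == "mean") return(rowMeans(norm))
  apply(norm, 1, nemerowLow)
}

#' Classify capacity-index values into risk classes
#'
#' Bins are closed on their lower bound: a value exactly on a break takes
#' the better (higher-capacity) class, so Pi = 0.7 is `safe` under the
#' default bins (safe >= 0.7 > precautionary >= 0.4 > loaded >= 0 >
#' overloaded).
#'
#' @param pi numeric vector of (integrated) capacity-index values.
#' @param bins list with `breaks` (increasing internal cut points) and
#'   `labels` (worst class first, one more than breaks).
#' @return factor of class labels, levels ordered worst to best.
#' @export
classifyRisk <- function(pi, bins = soilcapConfig()$pi_bins) {
  cut(pi, breaks = c(-Inf, bins$breaks, Inf), labels = bins$labels,
      right = FALSE)
}

#' Pollution indices: the result container
#'
#' Per-site x metal matrices of CF, ER, NPI, capacity terms Qi/Qib and Pi,
#' plus the per-site integrated Pi and its risk class.
#'
#' @slot cf,er,npi,qi,qib,pi numeric matrices, sites x metals.
#' @slot integratedPi numeric per site.
#' @slot riskClass factor per site.
#' @slot references the reference table used.
#' @seealso [pollutionIndices()]
#' @export
setClass("PollutionIndices",
  representation(cf = "matrix", er = "matrix", npi = "matrix", qi = "matrix",
                 qib = "matrix", pi = "matrix", integratedPi = "numeric",
                 riskClass = "factor", references = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (any(object@cf < 0)) msg <- c(msg, "cf must be >= 0")
    if (any(object@qib <= 0)) msg <- c(msg, "qib must be > 0")
    if (length(object@integratedPi) != nrow(object@cf))
      msg <- c(msg, "integratedPi must have one value per site")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PollutionIndices", function(object) {
  cat("PollutionIndices:", nrow(object@cf), "sites x", ncol(object@cf),
      "metals\n")
  cat("  mean Pi per metal:\n")
  print(round(colMeans(object@pi), 3))
  cat("  risk classes:",
      paste(levels(object@riskClass), table(object@riskClass),
            sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

#' Compute all pollution indices for a survey
#'
#' Runs the full per-site index battery — CF, ER, NPI, capacity Qi/Qib/Pi —
#' against the reference constants, integrates Pi across metals and assigns
#' risk classes.
#'
#' @param survey a [SoilSurvey-class].
#' @param references reference table (see [metalReferences()]).
#' @param config a [soilcapConfig()] list (soil mass M, bins, integration
#'   method).
#' @return a [PollutionIndices-class].
#' @examples
#' idx <- pollutionIndices(generateSurvey(seed = 1))
#' head(indexTable(idx))
#' @export
pollutionIndices <- function(survey, references = metalReferences(),
                             config = soilcapConfig()) {
  validateReferences(references)
  X <- concMatrix(survey)
  metals <- colnames(X)
  refs <- references[match(metals, references$metal), ]
  if (anyNA(refs$metal))
    stop("no reference constants for metal(s): ",
         paste(metals[is.na(refs$metal)], collapse = ", "))
  cf <- sweep(X, 2, refs$background, "/")
  er <- sweep(cf, 2, refs$toxic_response, "*")
  npi <- sweep(X, 2, refs$standard_limit, "/")
  cap <- capacityPi(X, Cs = rep(refs$screening, each = nrow(X)),
                    Cb = rep(refs$background, each = nrow(X)),
                    M = config$soil_mass_M)
  pim <- matrix(cap$pi, nrow(X), dimnames = dimnames(X))
  qi <- matrix(cap$qi, nrow(X), dimnames = dimnames(X))
  qib <- matrix(cap$qib, nrow(X), dimnames = dimnames(X))
  intPi <- integratePi(pim, method = if (config$integration == "mean")
    "mean" else "nemerow_min")
  new("PollutionIndices", cf = cf, er = er, npi = npi, qi = qi, qib = qib,
      pi = pim, integratedPi = stats::setNames(intPi, rownames(X)),
      riskClass = classifyRisk(intPi, config$pi_bins), references = refs)
}

#' @describeIn pollutionIndices wide per-site table of all indices
#'   (columns `<index>_<metal>`, `integrated_pi`, `risk_class`).
#' @param indices a [PollutionIndices-class].
#' @export
indexTable <- function(indices) {
  wide <- function(m, nm) {
    colnames(m) <- paste0(nm, "_", colnames(m))
    as.data.frame(m)
  }
  cbind(data.frame(site = rownames(indices@cf)),
        wide(indices@cf, "cf"), wide(indices@er, "er"),
        wide(indices@npi, "npi"), wide(indices@pi, "pi"),
        data.frame(integrated_pi = indices@integratedPi,
                   risk_class = as.character(indices@riskClass)))
}

#' @describeIn pollutionIndices long format (site, metal, index, value),
#'   heat-map ready.
#' @export
indexTableLong <- function(indices) {
  stack1 <- function(m, nm)
    data.frame(site = rep(rownames(m), ncol(m)),
               metal = rep(colnames(m), each = nrow(m)),
               index = nm, value = as.vector(m))
  rbind(stack1(indices@cf, "cf"), stack1(indices@er, "er"),
        stack1(indices@npi, "npi"), stack1(indices@pi, "pi"))
}

#' Flag contaminated sites
#'
#' Applies the configured contamination predicate to per-site values. Under
#' the default rule (Pi < 1) a site is contaminated exactly when its
#' concentration exceeds the background.
#'
#' @param values numeric vector (e.g. a column of the Pi matrix).
#' @param rule list with `op` (one of `<`, `<=`, `>`, `>=`) and `threshold`.
#' @return logical vector.
#' @export
applyRule <- function(values, rule = soilcapConfig()$contamination_rule) {
  f <- match.fun(rule$op)
  f(values, rule$threshold)
}
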