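#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

SOIL_METALS <- c("Pb", "Cr", "Mn", "Cu", "Zn", "Co", "Ni", "As")

LAND_USES <- c("residential", "commercial", "educational", "floodplain",
               "agricultural")

#' SoilSurvey: a stratified soil heavy-metal survey
#'
#' Container for a soil survey: one column per sampling site, one row per
#' metal(loid). The `"conc"` assay holds concentrations in mg/kg; the optional
#' `"belowMDL"` assay flags values at or below the method detection limit.
#' Site metadata (`x`, `y` planar coordinates in metres and the `land_use`
#' stratum) live in `colData`.
#'
#' @slot .  Extends \linkS4class{SummarizedExperiment}; no extra slots.
#' @seealso [SoilSurvey()], [readSurvey()], [generateSurvey()]
#' @export
setClass("SoilSurvey", contains = "SummarizedExperiment")

.validSoilSurvey <- function(object) {
  msg <- character()
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'conc' is required")
  cd <- colData(object)
  need <- c("x", "y", "land_use")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "site ids (colnames) must be unique")
  if (length(msg)) return(msg)
  conc <- assay(object, "conc")
  if (any(!is.finite(conc)))
    msg <- c(msg, "concentrations must be finite")
  else if (any(conc < 0))
    msg <- c(msg, "concentrations must be >= 0")
  lu <- as.character(cd$land_use)
  bad <- setdiff(unique(lu), LAND_USES)
  if (length(bad))
    msg <- c(msg, paste0("unknown land_use value(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("SoilSurvey", .validSoilSurvey)

#' Construct a SoilSurvey
#'
#' @param conc numeric matrix of concentrations (mg/kg), metals in rows and
#'   sites in columns (a sites-by-metals matrix is transposed automatically
#'   when its colnames are metal names).
#' @param x,y numeric planar site coordinates (metres, projected).
#' @param land_use character/factor of land-use strata, one of
#'   `r paste(LAND_USES, collapse = ", ")`.
#' @param site_id site identifiers; defaults to `S1, S2, ...`.
#' @param below_mdl optional logical matrix, same shape as `conc`, flagging
#'   below-detection values.
#' @return A [SoilSurvey-class] object.
#' @examples
#' sv <- generateSurvey(seed = 1)
#' sv
#' @export
SoilSurvey <- function(conc, x, y, land_use, site_id = NULL, below_mdl = NULL) {
  conc <- as.matrix(conc)
  if (!is.null(colnames(conc)) && all(colnames(conc) %in% SOIL_METALS) &&
      !all(rownames(conc) %in% SOIL_METALS))
    conc <- t(conc)
  n <- ncol(conc)
  if (is.null(site_id)) site_id <- paste0("S", seq_len(n))
  if (length(x) != n || length(y) != n || length(land_use) != n)
    stop("x, y and land_use must have one entry per site")
  colnames(conc) <- as.character(site_id)
  cd <- DataFrame(x = as.numeric(x), y = as.numeric(y),
                  land_use = factor(as.character(land_use), levels = LAND_USES),
                  row.names = as.character(site_id))
  assays <- list(conc = conc)
  if (!is.null(below_mdl)) {
    below_mdl <- as.matrix(below_mdl)
    dimnames(below_mdl) <- dimnames(conc)
    assays$belowMDL <- below_mdl
  }
  se <- SummarizedExperiment(assays = assays, colData = cd)
  new("SoilSurvey", se)
}

#' @describeIn SoilSurvey Concentration matrix, sites in rows, metals in
#'   columns (the receptor-model X matrix).
#' @param object,survey a `SoilSurvey`.
#' @export
concMatrix <- function(survey) t(assay(survey, "conc"))

#' @describeIn SoilSurvey Two-column matrix of site coordinates (metres).
#' @export
siteCoords <- function(survey) {
  cd <- colData(survey)
  cbind(x = cd$x, y = cd$y)
}

#' @describeIn SoilSurvey Land-use stratum of each site.
#' @export
landUse <- function(survey) colData(survey)$land_use

#' @describeIn SoilSurvey Metal names, in fixed row order.
#' @export
metalNames <- function(survey) rownames(survey)

#' @describeIn SoilSurvey Number of sampling sites.
#' @export
nSites <- function(survey) ncol(survey)

setMethod("show", "SoilSurvey", function(object) {
  cat("SoilSurvey:", ncol(object), "sites x", nrow(object), "metal(loid)s\n")
  cat("  metals:", paste(rownames(object), collapse = ", "), "\n")
  tab <- table(landUse(object))
  tab <- tab[tab > 0]
  cat("  strata:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if ("belowMDL" %in% SummarizedExperiment::assayNames(object))
    cat("  below-MDL flags:", sum(assay(object, "belowMDL")), "value(s)\n")
  invisible(NULL)
})

#' Semivariogram model
#'
#' Parametric isotropic semivariogram \eqn{\gamma(h)}. For the exponential
#' model \eqn{\gamma(h) = nugget + psill\,(1 - e^{-h/range})}; for the
#' spherical model the standard bounded form with `range` the distance at
#' which the sill is reached.
#'
#' @slot model `"exponential"` or `"spherical"`.
#' @slot nugget,psill,range nonnegative parameters; the total sill is
#'   `nugget + psill`.
#' @export
setClass("VariogramModel",
  representation(model = "character", nugget = "numeric", psill = "numeric",
                 range = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@model %in% c("exponential", "spherical"))
      msg <- c(msg, "model must be 'exponential' or 'spherical'")
    if (object@nugget < 0 || object@psill < 0)
      msg <- c(msg, "nugget and partial sill must be >= 0")
    if (object@range <= 0) msg <- c(msg, "range must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf("VariogramModel: %s | nugget %.4g, partial sill %.4g, range %.4g\n",
              object@model, object@nugget, object@psill, object@range))
  invisible(NULL)
})

#' Interpolated raster surface
#'
#' A regular grid of interpolated values over the bounding box of the sites,
#' with a logical mask restricting summaries to the study polygon (convex
#' hull of the sites buffered by the median nearest-neighbour distance).
#'
#' @slot origin x/y of the lower-left cell centre.
#' @slot cellSize cell size in metres.
#' @slot values numeric matrix, `nrows x ncols`, row 1 = southernmost row.
#' @slot mask logical matrix, same shape; `TRUE` inside the study polygon.
#' @export
setClass("RasterSurface",
  representation(origin = "numeric", cellSize = "numeric", values = "matrix",
                 mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 2) msg <- c(msg, "origin must be length 2")
    if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
    if (!identical(dim(object@values), dim(object@mask)))
      msg <- c(msg, "values and mask must share dimensions")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "RasterSurface", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("RasterSurface: %d x %d cells (%.4g m), %d masked-in\n",
              nrow(object@values), ncol(object@values), object@cellSize,
              sum(object@mask)))
  if (length(v))
    cat(sprintf("  values in study polygon: [%.4g, %.4g]\n",
                min(v), max(v)))
  invisible(NULL)
})

#' @describeIn RasterSurface grid values restricted to the study polygon.
#' @param surface a `RasterSurface`.
#' @export
surfaceValues <- function(surface) surface@values[surface@mask]
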