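#' Read a soil survey table
#'
#' Reads a survey with columns `site`, `x`, `y`, `land_use` and one column
#' per metal (`Pb, Cr, Mn, Cu, Zn, Co, Ni, As`), concentrations in mg/kg.
#' Rows with unparsable concentrations are rejected with their row index;
#' negative concentrations are a validation error. Values at or below the
#' metal's detection limit are flagged below-MDL.
#'
#' @param path CSV or XLSX file.
#' @param format `"csv"` or `"xlsx"`; inferred from the extension by default.
#' @param references reference table supplying MDLs (see [metalReferences()]).
#' @return a [SoilSurvey-class].
#' @export
readSurvey <- function(path, format = c("auto", "csv", "xlsx"),
                       references = metalReferences()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("survey file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  df <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else {
    if (file.size(path) == 0) stop("schema error: empty survey file")
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  names(df)[tolower(names(df)) %in% c("site", "site_id", "id")] <- "site"
  need <- c("site", "x", "y", "land_use", SOIL_METALS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("schema error: survey has no data rows")

  conc <- sapply(SOIL_METALS, function(m) suppressWarnings(as.numeric(df[[m]])))
  conc <- matrix(conc, nrow = nrow(df),
                 dimnames = list(NULL, SOIL_METALS))
  badRows <- which(apply(conc, 1, function(r) any(is.na(r))))
  if (length(badRows))
    stop("unparsable concentration(s) in data row(s): ",
         paste(badRows, collapse = ", "))
  negRows <- which(apply(conc, 1, function(r) any(r < 0)))
  if (length(negRows))
    stop("validation error: negative concentration(s) in data row(s): ",
         paste(negRows, collapse = ", "))

  mdl <- stats::setNames(references$mdl, references$metal)[SOIL_METALS]
  below <- sweep(conc, 2, mdl, "<=")
  SoilSurvey(conc = t(conc), x = as.numeric(df$x), y = as.numeric(df$y),
             land_use = df$land_use, site_id = as.character(df$site),
             below_mdl = t(below))
}

#' Write a result table as deterministic CSV
#'
#' Fixed column order (as given), numeric cells formatted to 4 significant
#' digits, so identical inputs produce byte-identical files.
#'
#' @param rows non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("refusing to write an empty table")
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(signif(out[[j]], 4), format = "g", digits = 4)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Export sites with attached values as GeoJSON
#'
#' Planar coordinates are emitted as-is (no CRS is asserted).
#'
#' @param survey a [SoilSurvey-class].
#' @param values optional data frame of per-site attributes to attach.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesGeoJSON <- function(survey, path, values = NULL) {
  xy <- siteCoords(survey)
  ids <- colnames(survey)
  feats <- lapply(seq_len(nSites(survey)), function(i) {
    props <- c(list(site = ids[i], land_use = as.character(landUse(survey)[i])),
               as.list(t(concMatrix(survey))[, i]))
    if (!is.null(values)) props <- c(props, as.list(values[i, , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(xy[i, 1], xy[i, 2])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a RasterSurface as an ESRI ASCII grid
#'
#' Masked-out cells are written as the nodata value.
#'
#' @param surface a [RasterSurface-class].
#' @param path output path.
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(surface, path, nodata = -9999) {
  v <- surface@values
  v[!surface@mask] <- nodata
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcenter", surface@origin[1]),
           paste("yllcenter", surface@origin[2]),
           paste("cellsize", surface@cellSize),
           paste("nodata_value", nodata))
  ## ASCII grids list rows north to south; row 1 of @values is southernmost
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1, paste,
                collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
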