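#' Per-metal reference constants
#'
#' Registry of the per-metal constants every assessment stage consumes:
#' geochemical background `background` (Cb, FAO values), risk-screening value
#' `screening` (Cs), standard limit `standard_limit` (Sj, the Nemerow
#' denominator), Hakanson toxic-response factor `toxic_response` (Tr), method
#' detection limit `mdl` and the relative measurement error fraction `sigma`
#' used when building PMF uncertainties.
#'
#' Backgrounds and detection limits are instrument/survey constants (the As
#' detection limit, reported in \eqn{\mu}g/kg, is converted to mg/kg).
#' Screening values, standard limits and toxic-response factors are
#' jurisdiction-dependent: the defaults are literature values (agricultural
#' screening standard where one exists and exceeds the background, otherwise
#' twice the background so that Cs > Cb always holds; standard Hakanson Tr),
#' and every column is overridable via `overrides` or a reference CSV read
#' with [readReferences()]. `sigma` defaults to 0.10 for all metals.
#'
#' @param overrides optional data frame (or named list of named vectors) with
#'   a `metal` column and any subset of the other columns; matching entries
#'   replace the defaults.
#' @return A `data.frame` with one row per metal and columns `metal`,
#'   `background`, `screening`, `standard_limit`, `toxic_response`, `mdl`,
#'   `sigma`.
#' @examples
#' refs <- metalReferences()
#' refs[refs$metal == "Pb", "background"]   # 50 mg/kg
#' metalReferences(data.frame(metal = "Pb", screening = 400))
#' @export
metalReferences <- function(overrides = NULL) {
  refs <- data.frame(
    metal          = SOIL_METALS,
    background     = c(Pb = 50, Cr = 100, Mn = 2000, Cu = 100,
                       Zn = 300, Co = 50, Ni = 100, As = 20)[SOIL_METALS],
    screening      = c(Pb = 120, Cr = 200, Mn = 4000, Cu = 200,
                       Zn = 600, Co = 100, Ni = 200, As = 30)[SOIL_METALS],
    standard_limit = c(Pb = 120, Cr = 200, Mn = 4000, Cu = 200,
                       Zn = 600, Co = 100, Ni = 200, As = 30)[SOIL_METALS],
    toxic_response = c(Pb = 5, Cr = 2, Mn = 1, Cu = 5,
                       Zn = 1, Co = 5, Ni = 5, As = 10)[SOIL_METALS],
    mdl            = c(Pb = 0.25, Cr = 0.16, Mn = 0.15, Cu = 0.05,
                       Zn = 0.21, Co = 0.12, Ni = 0.54, As = 0.0003)[SOIL_METALS],
    sigma          = rep(0.10, 8),
    row.names      = SOIL_METALS,
    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    ov <- as.data.frame(overrides, stringsAsFactors = FALSE)
    if (is.null(ov$metal)) stop("overrides must carry a 'metal' column")
    bad <- setdiff(ov$metal, refs$metal)
    if (length(bad))
      stop("unknown metal(s) in overrides: ", paste(bad, collapse = ", "))
    for (col in intersect(colnames(ov), setdiff(colnames(refs), "metal")))
      refs[ov$metal, col] <- ov[[col]]
  }
  validateReferences(refs)
  refs
}

validateReferences <- function(refs) {
  need <- c("metal", "background", "screening", "standard_limit",
            "toxic_response", "mdl", "sigma")
  miss <- setdiff(need, colnames(refs))
  if (length(miss))
    stop("reference table lacks column(s): ", paste(miss, collapse = ", "))
  num <- refs[setdiff(need, "metal")]
  if (any(!is.finite(as.matrix(num))))
    stop("reference constants must be finite numbers")
  if (any(num$background <= 0 | num$screening <= 0 | num$standard_limit <= 0 |
          num$toxic_response <= 0 | num$mdl <= 0))
    stop("reference constants must be positive (sigma may be 0)")
  if (any(num$sigma < 0)) stop("sigma must be >= 0")
  bad <- refs$metal[refs$screening <= refs$background]
  if (length(bad))
    stop("screening value must exceed background for: ",
         paste(bad, collapse = ", "))
  invisible(refs)
}

#' Read a reference-constant table from CSV
#'
#' Expects columns `metal, background, screening, standard_limit,
#' toxic_response, mdl, sigma`; rows override the shipped defaults, so a
#' partial table (fewer metals or, with NA cells, fewer columns) is allowed.
#'
#' @param path CSV file path.
#' @return the merged, validated reference `data.frame` (see
#'   [metalReferences()]).
#' @export
readReferences <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  ov <- ov[!vapply(ov, function(col) all(is.na(col)), logical(1))]
  metalReferences(overrides = ov)
}

refFor <- function(refs, metal) {
  i <- match(metal, refs$metal)
  if (is.na(i)) stop("no reference constants for metal: ", metal)
  refs[i, ]
}
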