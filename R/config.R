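#' Pipeline configuration
#'
#' Assembles and validates the knobs shared across pipeline stages. Values
#' not supplied fall back to documented defaults.
#'
#' @param soil_mass_M soil mass per hectare (kg/ha) entering the capacity
#'   terms Qi/Qib; the capacity index Pi itself is invariant to it.
#' @param pi_bins risk-class bins for Pi: a list with `breaks` (strictly
#'   increasing internal cut points) and `labels` (one more than breaks,
#'   worst class first). A class interval is closed on its lower bound, so a
#'   Pi exactly at a break takes the better class.
#' @param contamination_rule predicate on per-site index values used for
#'   site/area fractions; a list with `index` (`"pi"` or a metal
#'   concentration), `op` and `threshold`. Default: Pi < 1, i.e. the site
#'   exceeds the geochemical background.
#' @param grid_cell_size interpolation cell size (m); `NA` picks the size
#'   giving `grid_dim` cells along the longer axis.
#' @param grid_dim cells along the longer bounding-box axis (default 100).
#' @param random_seed integer seed fanned out to every stochastic stage.
#' @param pmf list: `p_range` candidate factor counts, `n_runs` multistart
#'   runs, `max_iter`, `tol`.
#' @param som list: `rows`, `cols` (NA = heuristic grid), `epochs`, `k_range`.
#' @param ebk_draws ensemble size for the variogram-resampling predictor.
#' @param integration `"nemerow_min"` (low-end-emphasising Nemerow on
#'   range-normalised Pi) or `"mean"`.
#' @return a validated named list of class `soilcap_config`.
#' @export
soilcapConfig <- function(soil_mass_M = 2.25e6,
                          pi_bins = list(
                            breaks = c(0, 0.4, 0.7),
                            labels = c("overloaded", "loaded",
                                       "precautionary", "safe")),
                          contamination_rule = list(index = "pi", op = "<",
                                                    threshold = 1),
                          grid_cell_size = NA_real_,
                          grid_dim = 100L,
                          random_seed = 1L,
                          pmf = list(),
                          som = list(),
                          ebk_draws = 100L,
                          integration = "nemerow_min") {
  pmf <- utils::modifyList(
    list(p_range = 3:5, n_runs = 20L, max_iter = 5000L, tol = 1e-6), pmf)
  som <- utils::modifyList(
    list(rows = NA_integer_, cols = NA_integer_, epochs = 50L,
         k_range = 2:10), som)
  cfg <- list(soil_mass_M = soil_mass_M, pi_bins = pi_bins,
              contamination_rule = contamination_rule,
              grid_cell_size = grid_cell_size, grid_dim = as.integer(grid_dim),
              random_seed = as.integer(random_seed), pmf = pmf, som = som,
              ebk_draws = as.integer(ebk_draws), integration = integration)
  if (soil_mass_M <= 0) stop("soil_mass_M must be > 0")
  if (is.unsorted(pi_bins$breaks, strictly = TRUE))
    stop("pi_bins$breaks must be strictly increasing")
  if (length(pi_bins$labels) != length(pi_bins$breaks) + 1)
    stop("pi_bins needs one more label than breaks")
  if (!is.na(grid_cell_size) && grid_cell_size <= 0)
    stop("grid_cell_size must be > 0")
  if (!integration %in% c("nemerow_min", "mean"))
    stop("integration must be 'nemerow_min' or 'mean'")
  class(cfg) <- "soilcap_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [soilcapConfig()]; absent keys keep their
#' defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `soilcap_config` list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(soilcapConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(soilcapConfig, raw)
}

## Per-stage child seed: offset from the global seed so stages are
## independently reproducible. Kept below 2^31.
stageSeed <- function(cfg_or_seed, stage_index) {
  seed <- if (is.list(cfg_or_seed)) cfg_or_seed$random_seed else cfg_or_seed
  (as.integer(seed) + 1013L * as.integer(stage_index)) %% .Machine$integer.max
}
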