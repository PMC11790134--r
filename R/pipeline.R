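#' Run the full assessment pipeline
#'
#' Executes, in dependency order, the land-use statistics, the pollution
#' indices with risk classes, the per-metal and integrated pollution-area
#' detection, the SOM spatial-pattern analysis and the PMF source
#' apportionment, writing one CSV per artefact plus a JSON run manifest.
#' Each stochastic stage gets its own child seed derived from the global
#' one, so stages are independently reproducible.
#'
#' @param survey a [SoilSurvey-class] or a survey file path.
#' @param config a [soilcapConfig()] list or a config file path.
#' @param out_dir output directory (created if needed).
#' @param references reference table or reference CSV path.
#' @return (invisibly) list of stage results plus `manifest`.
#' @export
runPipeline <- function(survey, config = soilcapConfig(),
                        out_dir = "soilcap-out",
                        references = metalReferences()) {
  if (is.character(config)) config <- readConfig(config)
  if (is.character(references)) references <- readReferences(references)
  input_path <- NULL
  if (is.character(survey)) {
    input_path <- survey
    survey <- readSurvey(survey, references = references)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) {
    line <- paste0(...)
    message(line)
    log <<- c(log, line)
  }
  outputs <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  note("stage 1/5 land-use statistics: n = ", nSites(survey))
  st <- stage("stats", landUseStats(survey))
  outputs$descriptives <- file.path(out_dir, "descriptives.csv")
  writeResultTable(st$descriptives, outputs$descriptives)
  outputs$anova <- file.path(out_dir, "anova_tests.csv")
  writeResultTable(st$tests, outputs$anova)

  note("stage 2/5 pollution indices")
  idx <- stage("indices", pollutionIndices(survey, references, config))
  outputs$indices <- file.path(out_dir, "index_table.csv")
  writeResultTable(indexTable(idx), outputs$indices)
  outputs$indices_long <- file.path(out_dir, "index_table_long.csv")
  writeResultTable(indexTableLong(idx), outputs$indices_long)

  note("stage 3/5 pollution-area detection")
  xy <- siteCoords(survey)
  grid <- makeStudyGrid(xy, grid_dim = config$grid_dim,
                        cell_size = config$grid_cell_size)
  areas <- stage("map", {
    rows <- lapply(colnames(idx@pi), function(mt) {
      det <- detectPollutedArea(xy, idx@pi[, mt],
                                rule = config$contamination_rule,
                                grid = grid)
      data.frame(metal = mt, site_pct = det$site_fraction,
                 area_pct = det$area_fraction)
    })
    intRule <- list(index = "integrated_pi", op = "<",
                    threshold = stats::median(idx@integratedPi))
    detInt <- detectPollutedArea(xy, idx@integratedPi, rule = intRule,
                                 grid = grid)
    list(table = do.call(rbind, rows), integrated = detInt)
  })
  outputs$areas <- file.path(out_dir, "pollution_areas.csv")
  writeResultTable(areas$table, outputs$areas)
  writeAsciiGrid(areas$integrated$surface,
                 file.path(out_dir, "integrated_pi_surface.asc"))

  note("stage 4/5 SOM spatial patterns")
  som <- stage("som", {
    fit <- trainSOM(prepareSOMInput(survey), rows = config$som$rows,
                    cols = config$som$cols, epochs = config$som$epochs,
                    seed = stageSeed(config, 4L))
    clusterCodebook(fit, k_range = config$som$k_range,
                    seed = stageSeed(config, 4L))
  })
  outputs$som_codebook <- file.path(out_dir, "som_codebook.csv")
  writeResultTable(as.data.frame(som@codebook), outputs$som_codebook)
  outputs$som_clusters <- file.path(out_dir, "som_clusters.csv")
  writeResultTable(data.frame(site = colnames(survey), bmu = som@bmu,
                              cluster = som@sampleCluster),
                   outputs$som_clusters)
  outputs$som_dbi <- file.path(out_dir, "som_dbi.csv")
  writeResultTable(data.frame(k = as.integer(names(som@dbiByK)),
                              dbi = som@dbiByK), outputs$som_dbi)

  note("stage 5/5 PMF source apportionment")
  pmf <- stage("pmf", {
    u <- buildUncertainty(survey, references)
    diag <- pmfDiagnostics(u$X, u$U, p_values = config$pmf$p_range,
                           n_runs = config$pmf$n_runs,
                           seed = stageSeed(config, 5L),
                           max_iter = config$pmf$max_iter,
                           tol = config$pmf$tol)
    bestP <- diag$table$p[which.min(diag$table$Q_over_Qexp)]
    list(diagnostics = diag, best = diag$solutions[[paste0("p", bestP)]],
         best_p = bestP)
  })
  outputs$pmf_diagnostics <- file.path(out_dir, "pmf_diagnostics.csv")
  writeResultTable(pmf$diagnostics$table, outputs$pmf_diagnostics)
  outputs$pmf_profiles <- file.path(out_dir, "pmf_profiles.csv")
  writeResultTable(data.frame(factor = rownames(pmf$best@F),
                              as.data.frame(pmf$best@F)),
                   outputs$pmf_profiles)
  outputs$pmf_contributions <- file.path(out_dir, "pmf_contributions.csv")
  writeResultTable(data.frame(factor = rownames(pmf$best@F),
                              mass_pct = pmf$best@factorContributionPct),
                   outputs$pmf_contributions)

  manifest <- list(
    tool = paste0("soilcap ", as.character(utils::packageVersion("soilcap"))),
    seed = config$random_seed,
    config = unclass(config),
    input_md5 = if (!is.null(input_path))
      unname(tools::md5sum(input_path)) else NA,
    n_sites = nSites(survey),
    pmf_best_p = pmf$best_p,
    som_best_k = som@bestK,
    outputs = outputs,
    log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("done: ", length(outputs), " artefacts in ", out_dir)
  invisible(list(stats = st, indices = idx, areas = areas, som = som,
                 pmf = pmf, manifest = manifest))
}

#' Command-line dispatcher
#'
#' Thin entry point behind the `soilcap` script
#' (`inst/scripts/soilcap.R`): subcommands `run`, `simulate`, `indices`,
#' `stats`, `map`, `som`, `pmf`, each mapping onto the corresponding
#' package functions. Arguments are `--key value` pairs: `--survey`,
#' `--config`, `--references`, `--out`, `--seed`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly (0 on success).
#' @export
soilcapCLI <- function(args) {
  if (!length(args)) {
    cat("usage: soilcap <run|simulate|indices|stats|map|som|pmf> [--survey f]",
        "[--config f] [--references f] [--out dir] [--seed n]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- list()
  rest <- args[-1]
  while (length(rest) >= 2 && startsWith(rest[1], "--")) {
    kv[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  out <- if (!is.null(kv$out)) kv$out else "soilcap-out"
  seed <- if (!is.null(kv$seed)) as.integer(kv$seed) else 1L
  cfg <- if (!is.null(kv$config)) readConfig(kv$config)
         else soilcapConfig(random_seed = seed)
  refs <- if (!is.null(kv$references)) readReferences(kv$references)
          else metalReferences()
  getSurvey <- function() {
    if (is.null(kv$survey)) stop("--survey is required for this subcommand")
    readSurvey(kv$survey, references = refs)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    run = runPipeline(getSurvey(), cfg, out, refs),
    simulate = {
      sv <- generateSurvey(seed = seed, references = refs)
      df <- data.frame(site = colnames(sv), siteCoords(sv),
                       land_use = as.character(landUse(sv)), concMatrix(sv))
      writeResultTable(df, file.path(out, "synthetic_survey.csv"))
    },
    indices = {
      idx <- pollutionIndices(getSurvey(), refs, cfg)
      writeResultTable(indexTable(idx), file.path(out, "index_table.csv"))
      writeResultTable(indexTableLong(idx),
                       file.path(out, "index_table_long.csv"))
    },
    stats = {
      st <- landUseStats(getSurvey())
      writeResultTable(st$descriptives, file.path(out, "descriptives.csv"))
      writeResultTable(st$tests, file.path(out, "anova_tests.csv"))
    },
    map = {
      sv <- getSurvey()
      idx <- pollutionIndices(sv, refs, cfg)
      grid <- makeStudyGrid(siteCoords(sv), grid_dim = cfg$grid_dim)
      rows <- do.call(rbind, lapply(colnames(idx@pi), function(mt) {
        det <- detectPollutedArea(siteCoords(sv), idx@pi[, mt],
                                  rule = cfg$contamination_rule, grid = grid)
        data.frame(metal = mt, site_pct = det$site_fraction,
                   area_pct = det$area_fraction)
      }))
      writeResultTable(rows, file.path(out, "pollution_areas.csv"))
    },
    som = {
      sv <- getSurvey()
      fit <- clusterCodebook(trainSOM(prepareSOMInput(sv), seed = seed),
                             seed = seed)
      writeResultTable(data.frame(site = colnames(sv), bmu = fit@bmu,
                                  cluster = fit@sampleCluster),
                       file.path(out, "som_clusters.csv"))
    },
    pmf = {
      sv <- getSurvey()
      u <- buildUncertainty(sv, refs)
      dg <- pmfDiagnostics(u$X, u$U, p_values = cfg$pmf$p_range,
                           n_runs = cfg$pmf$n_runs, seed = seed)
      writeResultTable(dg$table, file.path(out, "pmf_diagnostics.csv"))
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
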