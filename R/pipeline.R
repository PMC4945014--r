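#' Pipeline configuration
#'
#' Either a simulation config (synthetic world) or paths to tree and route
#' CSVs, plus the analysis settings shared by all stages.
#'
#' @param simulation a [sim_config()], or `NULL` to read CSV inputs.
#' @param trees_path,routes_path input CSVs (ignored when simulating).
#' @param delta BBMM location error SD in metres (default 3).
#' @param max_lag largest DIR lag (default 4, bounded by the length of the
#'   behavioural time series).
#' @param min_route_length minimum trees per route (default 6).
#' @param selection_lags lags assessed in the staged selection procedure.
#' @param mcmc an [mcmc_config()] for the selection models.
#' @param cox a [cox_config()] for the residence model.
#' @param cox_candidates named list of Cox covariate sets.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; each stage derives a sub-seed from it.
#' @param verbose print one log line per stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, trees_path = NULL,
                       routes_path = NULL, delta = 3, max_lag = 4,
                       min_route_length = 6, selection_lags = 0:4,
                       mcmc = mcmc_config(), cox = cox_config(mcmc = mcmc),
                       cox_candidates = list(
                         "dir+dis+dbh+sp" = c("dir", "dis", "dbh", "species"),
                         "dir+dis+dbh" = c("dir", "dis", "dbh"),
                         "dis" = "dis",
                         "dir" = "dir"),
                       out_dir = tempfile("treeforage_run_"),
                       seed = 1L, verbose = TRUE) {
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  if (min_route_length < 3)
    stop("min_route_length must be >= 3 (availability needs triplets)",
         call. = FALSE)
  if (is.null(simulation) && (is.null(trees_path) || is.null(routes_path)))
    stop("provide either a simulation config or both input paths",
         call. = FALSE)
  structure(list(simulation = simulation, trees_path = trees_path,
                 routes_path = routes_path, delta = delta, max_lag = max_lag,
                 min_route_length = min_route_length,
                 selection_lags = selection_lags, mcmc = mcmc, cox = cox,
                 cox_candidates = cox_candidates, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

stage_log <- function(verbose, ...) if (verbose) message("[treeforage] ", ...)

#' Run the full analysis pipeline
#'
#' simulate (optional) -> BBMM availability -> DIR records -> staged
#' tree-selection models -> Cox residence model -> report. Every stage
#' output is written to `config$out_dir` (`trees.csv`, `routes.csv`,
#' `availability.csv`, `dir.csv`, `model_ranking.csv`, `selection_fit.json`,
#' `cox_ranking.csv`, `cox_fit.json`, `survival_curves.csv`) together with a
#' `manifest.json` recording seed, package version and a config hash; two
#' runs with the same config produce identical manifest hashes.
#'
#' @param config a [run_config()].
#' @return invisible list with all stage outputs (`trees`, `routes`,
#'   `availability`, `dir`, `selection`, `residence`, `report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  vb <- config$verbose

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- route_seed(config$seed, 101L)
    trees <- generate_landscape(sim_cfg)
    sim <- simulate_routes(trees, sim_cfg)
    routes <- sim$routes
    stage_log(vb, sprintf("simulate: %d trees, %d routes kept, %d discarded",
                          nrow(trees), length(unique(routes$route_id)),
                          sim$discarded))
    jsonlite::write_json(sim$truth[setdiff(names(sim$truth), "steps")],
                         file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    trees <- read_trees(config$trees_path)
    routes <- read_routes(config$routes_path, config$min_route_length)
    stage_log(vb, sprintf("read: %d trees, %d routes", nrow(trees),
                          length(unique(routes$route_id))))
  }
  # enforce the minimum route length uniformly
  len <- table(routes$route_id)
  short <- names(len)[len < config$min_route_length]
  if (length(short)) {
    stage_log(vb, sprintf("discarding %d route(s) shorter than %d trees",
                          length(short), config$min_route_length))
    routes <- routes[!routes$route_id %in% short, ]
  }
  write_trees(trees, file.path(config$out_dir, "trees.csv"))
  write_routes(routes, file.path(config$out_dir, "routes.csv"))

  disks <- availability_disks(trees, routes, bbmm_params(delta = config$delta))
  sizes <- table(paste(disks$route_id, disks$period)[!is.na(disks$tree_id)])
  stage_log(vb, sprintf(
    "availability: sigma2_m = %.2f m^2/min, %d disks, mean %.1f trees/disk",
    attr(disks, "sigma2_m"), length(unique(paste(disks$route_id,
                                                 disks$period))),
    mean(sizes)))
  write.csv(disks, file.path(config$out_dir, "availability.csv"),
            row.names = FALSE)

  dtab <- dir_table(trees, routes, disks, max_lag = config$max_lag)
  stage_log(vb, sprintf("dir: %d tree-period records (%d used)",
                        nrow(dtab), sum(dtab$used)))
  write.csv(dtab, file.path(config$out_dir, "dir.csv"), row.names = FALSE)

  sel <- staged_selection(dtab, routes, trees,
                          lags = config$selection_lags, mcmc = config$mcmc,
                          seed = route_seed(config$seed, 201L))
  rank_all <- do.call(rbind, lapply(names(sel$blocks), function(b) {
    r <- sel$blocks[[b]]$ranking
    r$block <- b
    r
  }))
  write.csv(rank_all, file.path(config$out_dir, "model_ranking.csv"),
            row.names = FALSE)
  best0 <- sel$blocks[[1]]$fits[[sel$blocks[[1]]$ranking$model[1]]]
  jsonlite::write_json(list(summary = best0$summary, dic = best0$dic,
                            pd = best0$pd, v_mean = best0$v_mean,
                            natural = best0$natural),
                       file.path(config$out_dir, "selection_fit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  stage_log(vb, sprintf("selection: best model in first block = %s (DIC %.1f)",
                        sel$blocks[[1]]$ranking$model[1], best0$dic))

  rec <- residence_records(dtab, routes, trees, scale = "route")
  res <- candidate_set_selection(rec, config$cox_candidates,
                                 config = config$cox,
                                 seed = route_seed(config$seed, 301L))
  write.csv(res$ranking, file.path(config$out_dir, "cox_ranking.csv"),
            row.names = FALSE)
  best_cox <- res$fits[[res$ranking$model[1]]]
  jsonlite::write_json(list(natural = best_cox$natural, dic = best_cox$dic,
                            pd = best_cox$pd),
                       file.path(config$out_dir, "cox_fit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  # survival curves at DIR quartile profiles
  qs <- quantile(rec$dir, c(0.25, 0.5, 0.75))
  times <- seq(0, max(rec$time), length.out = 100)
  curves <- do.call(rbind, lapply(seq_along(qs), function(i) {
    pr <- list(dir = qs[[i]], dis = mean(rec$dis), dbh = mean(rec$dbh),
               species = "NPUM")
    cv <- remaining_probability(best_cox, pr, times)
    cv$profile <- names(qs)[i]
    cv
  }))
  write.csv(curves, file.path(config$out_dir, "survival_curves.csv"),
            row.names = FALSE)
  stage_log(vb, sprintf("residence: %d records, best model = %s (DIC %.1f)",
                        nrow(rec), res$ranking$model[1], best_cox$dic))

  report <- list(
    n_trees = nrow(trees),
    n_routes = length(unique(routes$route_id)),
    n_available = nrow(dtab), n_used = sum(dtab$used),
    mean_disk_size = mean(sizes),
    sigma2_m = attr(disks, "sigma2_m"),
    dir_used_means = colMeans(
      dtab[dtab$used == 1,
           c("dir_local", paste0("dir_lag", seq_len(config$max_lag)),
             "dir_route")], na.rm = TRUE),
    selection_ranking = rank_all,
    residence_ranking = res$ranking)

  # hash the scientific configuration only (not paths or verbosity)
  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config),
                   c("verbose", "out_dir", "trees_path", "routes_path"))],
    auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, tf)
  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("treeforage")),
                   config_hash = unname(tools::md5sum(tf)),
                   outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(trees = trees, routes = routes, availability = disks,
                 dir = dtab, selection = sel, residence = res,
                 report = report, manifest = manifest))
}
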