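### End-to-end orchestration: load or simulate a scene, filter and normalize
### bands, reduce, seed-classify, refine, optionally ensemble and feed back,
### evaluate, and write every artifact plus a machine-readable record of all
### effective parameters. All randomness flows from one root seed.

#' Build a run configuration
#'
#' Either `cube`/`labels` paths or a [scene_spec()] must be present (not
#' both absent). Defaults follow the fixed transfer protocol: refinement
#' parameters `r = 4`, `sigma_w = sigma_s = 1.3`, `beta = 0.4` and
#' classifier `gamma = 7`, with only the cost `C` regarded as
#' scene-specific.
#'
#' @param cube,labels input raster paths (any format [read_cube()]
#'   accepts), or `NULL` when simulating.
#' @param scene a [scene_spec()] for simulated runs.
#' @param band_exclusion a [band_exclusion()] or preset name.
#' @param evr_threshold,d_cap see [fit_projection()].
#' @param fraction,min_per_class see [stratified_sample()].
#' @param C,gamma fixed classifier parameters; leave `C = NULL` to grid
#'   search with [tune_hyperparameters()].
#' @param C_grid,gamma_grid grids used when tuning.
#' @param refine a [refine_params()].
#' @param ensemble number of band subsets for ensemble voting (0 = off).
#' @param feedback_runs weak-label feedback runs after refinement (0 = off).
#' @param out_dir output directory (`NULL` = no artifacts written).
#' @param seed root RNG seed.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(cube = NULL, labels = NULL, scene = NULL,
                       band_exclusion = "none", evr_threshold = 0.92,
                       d_cap = 18L, fraction = 0.1, min_per_class = 10L,
                       C = 32, gamma = 7, C_grid = NULL, gamma_grid = NULL,
                       refine = refine_params(), ensemble = 0L,
                       feedback_runs = 0L, out_dir = NULL, seed = 1L) {
  if (is.null(scene) && (is.null(cube) || is.null(labels)))
    stop("either input paths (cube + labels) or a scene spec is required")
  if (!is.null(scene) && !inherits(scene, "SceneSpec"))
    stop("scene must be a scene_spec()")
  if (is.character(band_exclusion))
    band_exclusion <- band_exclusion_preset(band_exclusion)
  stopifnot(inherits(refine, "RefineParams"))
  structure(list(cube = cube, labels = labels, scene = scene,
                 band_exclusion = band_exclusion,
                 evr_threshold = evr_threshold, d_cap = d_cap,
                 fraction = fraction, min_per_class = as.integer(min_per_class),
                 C = C, gamma = gamma, C_grid = C_grid,
                 gamma_grid = gamma_grid, refine = refine,
                 ensemble = as.integer(ensemble),
                 feedback_runs = as.integer(feedback_runs),
                 out_dir = out_dir, seed = seed),
            class = "RunConfig")
}

#' Read a run configuration from a JSON file
#'
#' Keys mirror the [run_config()] arguments; `scene` and `refine` may be
#' given as nested objects of [scene_spec()] / [refine_params()] arguments.
#'
#' @param path JSON file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$scene)) raw$scene <- do.call(scene_spec, raw$scene)
  if (!is.null(raw$refine)) raw$refine <- do.call(refine_params, raw$refine)
  do.call(run_config, raw)
}

# Core of a single pipeline pass over one cube/label pair.
pipeline_core <- function(cube, labels, config, tag = "run") {
  seed0 <- child_seed(config$seed, tag)
  cube <- exclude_bands(cube, config$band_exclusion, quiet = TRUE)
  n_removed <- attr(cube, "n_removed")
  cube <- minmax_normalize(cube)
  table <- mask_background(cube, labels)
  proj <- fit_projection(table, config$evr_threshold, config$d_cap)
  Z <- project(proj, table)
  Zr <- project_raster(proj, cube)                    # normalized per component
  # the classifier sees the same normalization as the spectral kernel
  Zn <- vapply(seq_len(ncol(Z)), function(j) {
    col <- Zr[, , j]
    col[table$coords[, 1L] + (table$coords[, 2L] - 1L) * nrow(col)]
  }, numeric(nrow(Z)))
  split <- stratified_sample(table$labels, config$fraction,
                             config$min_per_class,
                             seed = child_seed(seed0, "split"))
  if (is.null(config$C)) {
    tune_args <- list(features = Zn[split$train_idx, , drop = FALSE],
                      labels = table$labels[split$train_idx],
                      seed = child_seed(seed0, "cv"))
    if (!is.null(config$C_grid)) tune_args$C_grid <- config$C_grid
    if (!is.null(config$gamma_grid)) tune_args$gamma_grid <- config$gamma_grid
    svm <- do.call(tune_hyperparameters, tune_args)
  } else {
    svm <- svm_config(config$C, config$gamma)
  }
  pm <- fit_predict_proba(Zn, split, svm, table$labels, table$coords)
  test_mask <- matrix(FALSE, dim(labels)[1L], dim(labels)[2L])
  tc <- table$coords[split$test_idx, , drop = FALSE]
  test_mask[tc] <- TRUE
  seed_labels <- matrix(0L, dim(labels)[1L], dim(labels)[2L])
  seed_labels[table$coords] <- pm$class_ids[max.col(pm$probs, "first")]
  seed_eval <- eval_metrics(confusion(labels$labels, seed_labels, test_mask,
                                      pm$class_ids))
  state <- refine(pm, Zr, config$refine, dims = dim(labels))
  if (config$feedback_runs > 0L)
    state <- weak_label_feedback(state, Zr, config$refine,
                                 n_runs = config$feedback_runs)
  refined_eval <- eval_metrics(confusion(labels$labels, state$labels,
                                         test_mask, pm$class_ids))
  list(cube = cube, labels = labels, projection = proj, split = split,
       svm = svm, seed_map = pm, seed_labels = seed_labels,
       state = state, seed_eval = seed_eval, refined_eval = refined_eval,
       test_mask = test_mask, n_bands_removed = n_removed,
       features = Zr)
}

#' Run the full pipeline from a configuration
#'
#' Deterministic given `config$seed`. When `config$out_dir` is set, writes
#' the seed map and refined map (ENVI integer rasters), per-iteration
#' convergence deltas, a JSON metrics report and a JSON record of every
#' effective parameter.
#'
#' @param config a [run_config()].
#' @return list with the fitted stages, `seed_eval`/`refined_eval`
#'   ([eval_metrics()] reports), optional `ensemble` results, and
#'   `artifacts` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (!is.null(config$scene)) {
    scene <- make_scene(config$scene)
    cube <- scene$cube; labels <- scene$labels
    if (length(scene$open_set_ids)) {
      lab <- labels$labels
      lab[lab %in% scene$open_set_ids] <- 0L          # open-set: not trainable
      labels <- label_map(lab)
    }
  } else {
    cube <- read_cube(config$cube)
    labels <- read_label_map(config$labels)
  }
  res <- pipeline_core(cube, labels, config)
  ens <- NULL
  if (config$ensemble > 0L) {
    D <- length(cube$band_ids)
    part <- split_features(D, config$ensemble,
                           seed = child_seed(config$seed, "ensemble"))
    members <- lapply(seq_along(part$subsets), function(s) {
      keep <- part$subsets[[s]]
      sub <- hyper_cube(cube$values[, , keep, drop = FALSE],
                        band_ids = cube$band_ids[keep],
                        wavelengths = cube$wavelengths[keep],
                        nodata_mask = cube$nodata_mask)
      cfg <- config
      cfg$band_exclusion <- band_exclusion()           # already subset
      pipeline_core(sub, labels, cfg, tag = paste0("member", s))
    })
    voted <- majority_vote(lapply(members, function(m) m$state$labels),
                           probs = lapply(members, function(m) m$state$probs),
                           class_ids = members[[1L]]$seed_map$class_ids)
    ens <- list(partition = part, members = members, voted = voted,
                voted_eval = eval_metrics(confusion(labels$labels,
                                                    voted$labels,
                                                    res$test_mask)))
  }
  artifacts <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(config$out_dir, ...)
    write_label_map(label_map(res$seed_labels), p("seed_map.dat"))
    write_label_map(label_map(res$state$labels), p("refined_map.dat"))
    writeLines(sprintf("%d\t%.10g", seq_along(res$state$delta_history),
                       res$state$delta_history), p("delta_history.tsv"))
    report <- list(
      seed = list(oa = res$seed_eval$oa, aa = res$seed_eval$aa,
                  kappa = res$seed_eval$kappa,
                  per_class = as.list(res$seed_eval$per_class)),
      refined = list(oa = res$refined_eval$oa, aa = res$refined_eval$aa,
                     kappa = res$refined_eval$kappa,
                     per_class = as.list(res$refined_eval$per_class)),
      converged = res$state$converged, iterations = res$state$iteration)
    if (!is.null(ens)) report$ensemble <- list(oa = ens$voted_eval$oa,
                                               aa = ens$voted_eval$aa,
                                               kappa = ens$voted_eval$kappa)
    jsonlite::write_json(report, p("metrics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    params <- list(
      seed = config$seed, evr_threshold = config$evr_threshold,
      d_cap = config$d_cap, d = res$projection$d,
      fraction = config$fraction, min_per_class = config$min_per_class,
      C = res$svm$C, gamma = res$svm$gamma,
      r = config$refine$r, sigma_s = config$refine$sigma_s,
      sigma_w = config$refine$sigma_w, beta = config$refine$beta,
      epsilon = config$refine$epsilon, max_outer = config$refine$max_outer,
      potential_form = config$refine$potential_form,
      ensemble = config$ensemble, feedback_runs = config$feedback_runs,
      n_bands_removed = res$n_bands_removed)
    jsonlite::write_json(params, p("parameters.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    artifacts <- c(p("seed_map.dat"), p("refined_map.dat"),
                   p("delta_history.tsv"), p("metrics.json"),
                   p("parameters.json"))
  }
  c(res[c("projection", "split", "svm", "seed_map", "seed_labels", "state",
          "seed_eval", "refined_eval", "test_mask", "features")],
    list(ensemble = ens, artifacts = artifacts, config = config))
}

# Fixed cross-scene transfer parameter set (classifier gamma + refinement).
transfer_defaults <- function() {
  list(gamma = 7, refine = refine_params(r = 4L, sigma_s = 1.3,
                                         sigma_w = 1.3, beta = 0.4))
}

#' Run the pipeline in fixed-parameter transfer mode
#'
#' Applies the fixed transfer set (`gamma = 7`, `r = 4`,
#' `sigma_w = sigma_s = 1.3`, `beta = 0.4`) and refuses any attempt to
#' override the refinement parameters: only the classifier cost `C` (given
#' fixed or via a grid) and optionally `gamma` may differ between scenes.
#'
#' @param config a [run_config()]; its `refine` entry must be absent-equal
#'   to the transfer set and `C`/`C_grid` are the only knobs honored.
#' @param retune_gamma also allow `gamma` to be re-tuned (default FALSE).
#' @return as [run_pipeline()].
#' @export
transfer_run <- function(config, retune_gamma = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  fixed <- transfer_defaults()
  rp <- config$refine
  fp <- fixed$refine
  same <- rp$r == fp$r && rp$sigma_s == fp$sigma_s &&
    rp$sigma_w == fp$sigma_w && rp$beta == fp$beta
  if (!same)
    stop("transfer mode: refinement parameters (r, sigma_s, sigma_w, beta) ",
         "are fixed and cannot be re-tuned")
  if (!retune_gamma) {
    if (!is.null(config$gamma) && config$gamma != fixed$gamma)
      stop("transfer mode: gamma is fixed at ", fixed$gamma,
           "; pass retune_gamma = TRUE to re-tune it")
    config$gamma <- fixed$gamma
    if (is.null(config$C) && !is.null(config$gamma_grid))
      stop("transfer mode: gamma_grid is not honored without retune_gamma")
    if (is.null(config$C)) config$gamma_grid <- fixed$gamma
  }
  run_pipeline(config)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic scene), `run` (full
#' pipeline), `transfer` (fixed-parameter transfer run), `evaluate`
#' (compare two label rasters), `refine`, `ensemble`. Invoked by the
#' `inst/scripts/hsi` launcher as
#' `Rscript hsi <subcommand> --config cfg.json [--out dir]`.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) stop("usage: hsi <simulate|run|transfer|refine|ensemble|evaluate> ...")
  cmd <- argv[[1L]]
  opts <- list()
  rest <- argv[-1L]
  i <- 1L
  while (i <= length(rest)) {
    if (!grepl("^--", rest[i])) stop("unknown argument: ", rest[i])
    key <- sub("^--", "", rest[i])
    opts[[key]] <- if (i < length(rest) && !grepl("^--", rest[i + 1L])) {
      i <- i + 1L; rest[i]
    } else TRUE
    i <- i + 1L
  }
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing --", k)
    opts[[k]]
  }
  status <- 0L
  switch(cmd,
    simulate = {
      cfg <- read_run_config(need("config"))
      if (is.null(cfg$scene)) stop("simulate requires a scene spec")
      scene <- make_scene(cfg$scene)
      out <- need("out")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_cube(scene$cube, file.path(out, "scene.dat"))
      write_label_map(scene$labels, file.path(out, "labels.dat"))
      message("scene written to ", out)
    },
    run = {
      cfg <- read_run_config(need("config"))
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      res <- run_pipeline(cfg)
      print(res$refined_eval)
    },
    transfer = {
      cfg <- read_run_config(need("config"))
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      res <- transfer_run(cfg, retune_gamma = isTRUE(opts[["retune-gamma"]]))
      print(res$refined_eval)
    },
    refine = ,
    ensemble = {
      cfg <- read_run_config(need("config"))
      if (cmd == "ensemble" && cfg$ensemble < 2L) cfg$ensemble <- 4L
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      res <- run_pipeline(cfg)
      print(res$refined_eval)
    },
    evaluate = {
      truth <- read_label_map(need("truth"))
      pred <- read_label_map(need("pred"))
      print(eval_metrics(confusion(truth, pred)))
    },
    stop("unknown subcommand: ", cmd))
  invisible(status)
}
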