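#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory (created).
#' @param seed Global seed; every stochastic stage derives named substreams
#'   from it, so reruns with the same config reproduce identical outputs.
#' @param synthetic A [synth_config()] (or list of its arguments) to
#'   simulate both contexts; alternatively supply `bundles`.
#' @param bundles Named list with `execution` and/or `observation` bundle
#'   directories (read with [read_session()]).
#' @param stages Stages to run, in dependency order, among
#'   `"preprocess"`, `"classify"`, `"subspace"`, `"segments"`, `"decode"`,
#'   `"align"`.
#' @param population Unit class analyzed downstream of classification
#'   (`"MN"`, `"AE"`, or `"all"`).
#' @param sigma Smoothing kernel SD in ms.
#' @param n_folds,trials_per_object Bootstrap settings for angle courses,
#'   decoding, and CCA.
#' @param n_iter CCA bootstrap iterations.
#' @param n_chance Random-subspace draws for the principal-angle chance band.
#' @param alpha Unit-classification significance criterion.
#' @param reference_events Events for angle courses.
#' @param decode_events Events for decode curves.
#' @param decode_grid_step Grid step (ms) for decoding; larger = faster.
#' @param decode_epochs LSTM epoch budget.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synthetic = NULL,
                            bundles = NULL,
                            stages = c("preprocess", "classify", "subspace",
                                       "segments", "align"),
                            population = "MN", sigma = 50,
                            n_folds = 10L, trials_per_object = 20L,
                            n_iter = 500L, n_chance = 5000L, alpha = 0.0083,
                            reference_events = c("I", "G", "M", "H"),
                            decode_events = "M", decode_grid_step = 50L,
                            decode_epochs = 100L) {
  if (is.null(synthetic) && is.null(bundles))
    stop("config error: provide either a synthetic config or bundle paths")
  if (!is.null(synthetic) && !inherits(synthetic, "synth_config"))
    synthetic <- do.call(synth_config, synthetic)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, bundles = bundles, stages = stages,
                 population = population, sigma = sigma, n_folds = n_folds,
                 trials_per_object = trials_per_object, n_iter = n_iter,
                 n_chance = n_chance, alpha = alpha,
                 reference_events = reference_events,
                 decode_events = decode_events,
                 decode_grid_step = decode_grid_step,
                 decode_epochs = decode_epochs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose fields mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$synthetic)) vals$synthetic <- do.call(synth_config, as.list(vals$synthetic))
  do.call(pipeline_config, vals)
}

pipe_log <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order (data -> preprocess ->
#' classify -> subspace/segments -> decode -> align), writing CSV outputs
#' and a JSON run manifest (seed, parameters, per-stage output paths) under
#' `config$out_dir`. Re-running with the same config reproduces identical
#' stochastic outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = config$stages,
                   outputs = list(),
                   params = config[setdiff(names(config),
                                           c("synthetic", "bundles"))])

  # -- data ------------------------------------------------------------
  bundles <- list()
  if (!is.null(config$synthetic)) {
    pipe_log("data", "generating synthetic session (both contexts)")
    cfg <- config$synthetic
    cfg$seed <- derive_seed(config$seed, "synthetic")
    for (ctx in CONTEXTS) {
      gs <- generate_session(cfg, ctx)
      bundles[[ctx]] <- gs$bundle
      bp <- file.path(out, "bundles", ctx)
      write_session(gs$bundle, bp)
      manifest$outputs[[paste0("bundle_", ctx)]] <- bp
    }
  } else {
    for (ctx in names(config$bundles)) {
      pipe_log("data", paste("reading", ctx, "bundle"))
      bundles[[ctx]] <- read_session(config$bundles[[ctx]])
    }
  }
  have_both <- all(CONTEXTS %in% names(bundles))

  # -- preprocess ------------------------------------------------------
  tensors <- NULL
  if ("preprocess" %in% config$stages) {
    pipe_log("preprocess", sprintf("binning, smoothing (sigma=%g ms), aligning", config$sigma))
    ref_ctx <- if ("execution" %in% names(bundles)) "execution" else names(bundles)[1]
    stats_ <- compute_epoch_stats(bundles[[ref_ctx]])
    tensors <- lapply(bundles, function(b)
      align_concatenate(sqrt_transform(bin_and_smooth(b, config$sigma)), stats_))
    for (ctx in names(tensors)) {
      tp <- file.path(out, sprintf("tensor_%s.rds", ctx))
      saveRDS(tensors[[ctx]], tp)
      manifest$outputs[[paste0("tensor_", ctx)]] <- tp
    }
  }

  # -- classify --------------------------------------------------------
  classes <- NULL
  if ("classify" %in% config$stages) {
    if (!have_both) stop("classify stage needs both contexts")
    pipe_log("classify", "two-way ANOVA unit classification")
    classes <- classify_units(bundles$execution, bundles$observation,
                              alpha = config$alpha)
    cp <- file.path(out, "units_classified.csv")
    data.table::fwrite(classes, cp)
    manifest$outputs$units_classified <- cp
  }

  pop_tensors <- tensors
  if (!is.null(classes) && config$population != "all" && !is.null(tensors)) {
    keep <- classes$unit_id[classes$class == config$population]
    if (length(keep) >= 3)
      pop_tensors <- lapply(tensors, subset_units, units = keep)
    else
      warning("fewer than 3 units in the requested population; using all units")
  }

  need_tensors <- function(stage) {
    if (is.null(pop_tensors))
      stop(sprintf("stage '%s' needs preprocessed tensors; enable the preprocess stage",
                   stage))
  }

  # -- subspace: principal-angle courses -------------------------------
  if ("subspace" %in% config$stages) {
    need_tensors("subspace")
    for (ctx in names(pop_tensors)) {
      for (ev in config$reference_events) {
        pipe_log("subspace", sprintf("angle course ref=%s ctx=%s", ev, ctx))
        ac <- angle_course(pop_tensors[[ctx]], ev, n_folds = config$n_folds,
                           trials_per_object = config$trials_per_object,
                           seed = derive_seed(config$seed, "angles", ctx, ev),
                           n_chance = config$n_chance)
        ap <- file.path(out, sprintf("angles_%s_%s.csv", ev, ctx))
        write_angle_course(ac, ap)
        manifest$outputs[[sprintf("angles_%s_%s", ev, ctx)]] <- ap
      }
    }
    if (have_both) {
      for (ev in config$reference_events) {
        ac <- cross_context_angles(pop_tensors$execution, pop_tensors$observation,
                                   ev, n_folds = config$n_folds,
                                   trials_per_object = config$trials_per_object,
                                   seed = derive_seed(config$seed, "xangles", ev),
                                   n_chance = config$n_chance)
        ap <- file.path(out, sprintf("angles_%s_cross.csv", ev))
        write_angle_course(ac, ap)
        manifest$outputs[[sprintf("angles_%s_cross", ev)]] <- ap
      }
    }
  }

  # -- segments: separation grids --------------------------------------
  if ("segments" %in% config$stages) {
    need_tensors("segments")
    for (ctx in names(pop_tensors)) {
      pipe_log("segments", paste("separation grid", ctx))
      gr <- separation_grid(pop_tensors[[ctx]])
      gp <- file.path(out, sprintf("separation_grid_%s.csv", ctx))
      data.table::fwrite(as.data.frame(cbind(segment = rownames(gr), gr)), gp)
      manifest$outputs[[paste0("separation_grid_", ctx)]] <- gp
    }
  }

  # -- decode ----------------------------------------------------------
  if ("decode" %in% config$stages) {
    need_tensors("decode")
    for (ctx in names(pop_tensors)) {
      grid <- decode_grid(pop_tensors[[ctx]]$time_map, config$decode_grid_step)
      for (ev in config$decode_events) {
        pipe_log("decode", sprintf("sliding decode seg=%s ctx=%s (%d grid times)",
                                   ev, ctx, nrow(grid)))
        dc <- slide_decode(pop_tensors[[ctx]], NULL, ev, folds = config$n_folds,
                           grid = grid, epochs = config$decode_epochs,
                           seed = derive_seed(config$seed, "decode", ctx, ev))
        dp <- file.path(out, sprintf("decode_%s_%s.csv", ev, ctx))
        write_decode_curve(dc, dp)
        manifest$outputs[[sprintf("decode_%s_%s", ev, ctx)]] <- dp
      }
    }
  }

  # -- align: CCA ------------------------------------------------------
  if ("align" %in% config$stages) {
    need_tensors("align")
    if (!have_both) stop("align stage (context comparison) needs both contexts")
    pipe_log("align", "bootstrap CCA execution vs observation + within-group")
    outs <- list(
      "MN:E/O" = bootstrap_cca(pop_tensors$execution, pop_tensors$observation,
                               "H", trials_per_object = config$trials_per_object,
                               n_iter = config$n_iter, comparison = "MN:E/O",
                               seed = derive_seed(config$seed, "cca-eo")),
      "MN:E/E" = within_group_cca(pop_tensors$execution, "H",
                                  trials_per_object = config$trials_per_object,
                                  n_iter = config$n_iter, comparison = "MN:E/E",
                                  seed = derive_seed(config$seed, "cca-ee")),
      "MN:O/O" = within_group_cca(pop_tensors$observation, "H",
                                  trials_per_object = config$trials_per_object,
                                  n_iter = config$n_iter, comparison = "MN:O/O",
                                  seed = derive_seed(config$seed, "cca-oo")))
    paths <- write_cca_outcomes(outs, file.path(out, "cca"))
    manifest$outputs$cca <- file.path(out, "cca")
    comp <- compare_outcomes(outs)
    kp <- file.path(out, "cca", "kruskal.csv")
    data.table::fwrite(comp$kruskal, kp)
    manifest$outputs$cca_kruskal <- kp
  }

  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  pipe_log("done", paste("manifest:", mp))
  invisible(manifest)
}

#' Small synthetic end-to-end demonstration
#'
#' Runs the full pipeline on a reduced synthetic session (20 units, 10
#' trials per object) with scaled-down bootstrap settings; finishes in a
#' few minutes on one core.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return The run manifest, invisibly.
#' @export
run_demo <- function(out_dir = file.path(tempdir(), "instaspace-demo"),
                     seed = 1L) {
  cfg <- pipeline_config(
    out_dir = out_dir, seed = seed,
    synthetic = synth_config(n_units = 20, n_mn = 12, n_ae = 6, n_ao = 1,
                             n_ns = 1, trials_per_object = 10,
                             delay_range = c(500, 1200), seed = seed),
    stages = c("preprocess", "classify", "subspace", "segments", "align"),
    n_folds = 5, trials_per_object = 10, n_iter = 50, n_chance = 500,
    reference_events = "M")
  run_pipeline(cfg)
}
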