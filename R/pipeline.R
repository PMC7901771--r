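#' Run the full identification workflow
#'
#' Wires the stages together — obtain windows (from file or the synthetic
#' generator), obtain structures (built-in folder, external folder, or a
#' precomputed file), encode, split into training and evaluation sets,
#' build and train the network, evaluate, and extract motifs — writing all
#' artifacts under `out_dir`: the model archive, per-epoch training log,
#' metrics and ROC point CSVs, motif logos (PNG) and PFMs (MEME format),
#' and a YAML run manifest recording the configuration and seed. Any stage
#' failure aborts with a message naming the stage.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   * `out_dir` — output directory (created if missing);
#'   * `seed` — master seed, propagated to every stochastic step;
#'   * `input` — FASTA of labeled windows, or `preset = "strong"` /
#'     `generator` (a list of [generator_spec()] arguments) to simulate;
#'   * `encoding` — `"merged"` (default) or `"general"`;
#'   * `folder` — `"nussinov"` (default), `"external"`, or
#'     `"precomputed"` with `structures` giving the file;
#'   * `eval_fraction` — stratified held-out fraction (default 0.2);
#'   * `model` — list of [model_config()] overrides.
#' @return Invisibly, a list with the trained model, the metrics tibble,
#'   the ROC object, the extracted PFMs and the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% abort("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  encoding <- config$encoding %||% "merged"

  ds <- pipeline_stage("input", {
    if (!is.null(config$input)) {
      read_dataset(config$input)
    } else if (identical(config$preset, "strong")) {
      sp <- strong_preset()
      sp$seed <- seed
      generate_windows(sp)
    } else if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- gen$seed %||% seed
      generate_windows(do.call(generator_spec, gen))
    } else {
      abort("config needs one of: input, preset = 'strong', generator")
    }
  })

  structures <- NULL
  if (encoding == "merged") {
    structures <- pipeline_stage("folding", {
      folder <- config$folder %||% "nussinov"
      switch(folder,
        nussinov = fold_windows(ds, "nussinov"),
        external = fold_windows(ds, "external"),
        precomputed = {
          if (is.null(config$structures)) {
            abort("folder = 'precomputed' needs a 'structures' file")
          }
          read_structures(config$structures)
        },
        abort(paste0("unknown folder '", folder, "'"))
      )
    })
  }

  enc <- pipeline_stage("encoding", {
    encode_dataset(ds, kind = encoding, structures = structures)
  })

  split <- pipeline_stage("split", {
    frac <- config$eval_fraction %||% 0.2
    hold <- withr::with_seed(seed, stratified_holdout(enc$y, frac))
    list(
      train = list(x = enc$x[-hold, , , drop = FALSE], y = enc$y[-hold]),
      eval = list(x = enc$x[hold, , , drop = FALSE], y = enc$y[hold])
    )
  })

  model <- pipeline_stage("training", {
    overrides <- config$model %||% list()
    cfg <- do.call(model_config, c(
      list(input_rows = dim(enc$x)[2], input_cols = dim(enc$x)[3],
           seed = seed),
      overrides
    ))
    train_cnn(build_model(cfg), split$train)
  })

  results <- pipeline_stage("evaluation", {
    pred <- predict(model, split$eval)
    metrics <- compute_metrics(confusion_counts(split$eval$y, pred$label))
    roc <- roc_auc(pred$p_positive, split$eval$y)
    list(pred = pred, metrics = dplyr::mutate(metrics, auc = roc$auc),
         roc = roc)
  })

  pfms <- pipeline_stage("motifs", {
    pos <- list(x = split$train$x[split$train$y == 1, , , drop = FALSE])
    extract_motifs(model, pos)
  })

  paths <- pipeline_stage("artifacts", {
    paths <- list(
      model = file.path(out_dir, "model.rds"),
      history = file.path(out_dir, "training_log.csv"),
      metrics = file.path(out_dir, "metrics.csv"),
      roc = file.path(out_dir, "roc_points.csv"),
      motifs = file.path(out_dir, "motifs.meme"),
      logo = file.path(out_dir, "logos.png"),
      manifest = file.path(out_dir, "manifest.yaml")
    )
    save_model(model, paths$model)
    write.csv(model$history, paths$history, row.names = FALSE)
    write.csv(results$metrics, paths$metrics, row.names = FALSE)
    write.csv(results$roc$points, paths$roc, row.names = FALSE)
    if (length(pfms) > 0) {
      write_meme(pfms, paths$motifs)
      top <- names(sort(vapply(pfms, function(p) max(information_content(p)),
                               0), decreasing = TRUE))
      render_logo(pfms[head(top, 3)], paths$logo)
    }
    yaml::write_yaml(
      list(
        package = "psiCNN",
        version = as.character(utils::packageVersion("psiCNN")),
        seed = seed, encoding = encoding,
        folder = if (encoding == "merged") config$folder %||% "nussinov",
        n_windows = nrow(ds), xi = ds$xi[1],
        model = model$config[setdiff(names(model$config), "filter_heights")],
        filter_heights = model$config$filter_heights,
        metrics = as.list(round(results$metrics, 4))
      ),
      paths$manifest
    )
    paths
  })

  invisible(list(model = model, metrics = results$metrics, roc = results$roc,
                 pfms = pfms, paths = paths, windows = ds))
}

pipeline_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("stage '", name, "': ", conditionMessage(e)))
  })
}
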