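#' Run the full TLS maturation pipeline on synthetic data
#'
#' Executes the end-to-end chain -- synthesize slide, write/read GeoJSON
#' annotations, extract tiles, train, predict, aggregate, evaluate,
#' visualize -- into `out_dir`, writing a run manifest (`run_manifest.json`)
#' listing inputs, outputs and seeds.  Patients are partitioned into
#' train/validation/test roles; the classifier is trained on training
#' patients, monitored on validation patients, and all reported metrics are
#' computed on the held-out test patients.  All randomness funnels through
#' `seed`.
#'
#' @param out_dir output directory.
#' @param spec a [synthetic_slide_spec()]; its seed is overridden by `seed`.
#' @param params a [stain_params()].
#' @param config a [training_config()]; its seed is overridden by `seed`.
#' @param methods aggregation methods to evaluate and render.
#' @param ratios patient shares of (train, validation, test).
#' @param seed master seed.
#' @param overview_scale scale factor of the slide overview image.
#' @return invisible list with `status` (0 on success), `manifest` (run
#'   manifest), `metrics` (per-method TLS-level and tile-level
#'   [metrics_report()]s), and `model`.
#' @export
run_pipeline <- function(out_dir,
                         spec = synthetic_slide_spec(n_tls = 24,
                                                     mean_tiles_per_tls = 8,
                                                     tile_size = 56,
                                                     n_patients = 12),
                         params = stain_params(),
                         config = training_config(),
                         methods = c("max_confidence", "custom"),
                         ratios = c(0.625, 0.172, 0.203),
                         seed = 1,
                         overview_scale = 0.1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  artifacts <- list()
  note <- function(stage, path) {
    artifacts[[stage]] <<- c(artifacts[[stage]], path)
    path
  }

  # 1. synth
  slide <- generate_slide(spec, params)
  slide_png <- note("synth", file.path(out_dir, "slide.png"))
  write_image(slide$image, slide_png)
  geojson <- note("synth", file.path(out_dir, "annotations.geojson"))
  write_annotations(slide$annotations, geojson)
  truth_csv <- note("synth", file.path(out_dir, "truth.csv"))
  utils::write.csv(slide$truth, truth_csv, row.names = FALSE)

  # 2. tile (read annotations back from GeoJSON: the pipeline consumes its
  # own interchange format)
  annotations <- read_annotations(geojson)
  tiles <- extract_all_tiles(slide$image, annotations,
                             tile_size = spec$tile_size)
  if (!nrow(tiles)) stop("tiling produced no tiles; aborting", call. = FALSE)
  tiles <- write_tile_images(tiles, file.path(out_dir, "tiles"))
  manifest_csv <- note("tile", file.path(out_dir, "tile_manifest.csv"))
  manifest <- write_manifest(tiles, annotations, manifest_csv,
                             tile_size = spec$tile_size)
  overview_png <- note("tile", file.path(out_dir, "overview.png"))
  write_image(render_overview(slide$image, manifest,
                              scale_factor = overview_scale,
                              tile_size = spec$tile_size), overview_png)

  # 3. train
  roles <- partition_patients(manifest, ratios = ratios, seed = seed)
  role_of <- stats::setNames(roles$role, roles$patient_id)
  tr <- manifest[role_of[manifest$patient_id] == "train", , drop = FALSE]
  va <- manifest[role_of[manifest$patient_id] == "validation", , drop = FALSE]
  te <- manifest[role_of[manifest$patient_id] == "test", , drop = FALSE]
  if (!nrow(tr) || !nrow(va) || !nrow(te)) {
    stop("patient partition left an empty train/validation/test set; increase n_patients",
         call. = FALSE)
  }
  model <- train_classifier(tr, va, config)
  ckpt <- note("train", file.path(out_dir, "checkpoint.json"))
  save_checkpoint(model, ckpt)
  hist_csv <- note("train", file.path(out_dir, "training_history.csv"))
  utils::write.csv(model$history, hist_csv, row.names = FALSE)

  # 4. predict (held-out test patients)
  preds <- predict_tiles(model, te)
  preds$tls_id <- te$tls_id

  # 5. aggregate
  agg <- aggregate_all(preds, methods)
  agg_csv <- note("aggregate", file.path(out_dir, "tls_predictions.csv"))
  utils::write.csv(agg, agg_csv, row.names = FALSE)

  # 6. evaluate
  metrics <- list(tile = metrics_report(te$true_class, preds$pred_class))
  tls_truth <- unique(te[, c("tls_id", "true_class")])
  for (m in methods) {
    am <- agg[agg$method == m, ]
    am <- am[match(tls_truth$tls_id, am$tls_id), ]
    metrics[[paste0("tls_", m)]] <- metrics_report(tls_truth$true_class,
                                                   am$pred_class)
  }
  metrics_dir <- file.path(out_dir, "metrics")
  dir.create(metrics_dir, showWarnings = FALSE)
  for (nm in names(metrics)) {
    note("evaluate", file.path(metrics_dir, paste0(nm, ".json")))
    write_metrics_json(metrics[[nm]], file.path(metrics_dir,
                                                paste0(nm, ".json")))
  }

  # 7. visualize
  viz <- write_prediction_outputs(preds, agg, te,
                                  file.path(out_dir, "visualization"))
  artifacts$visualize <- c(viz$tile_csv, viz$tls_csv, viz$mosaics)

  run_manifest <- list(
    package = "tlsmat",
    version = as.character(utils::packageVersion("tlsmat")),
    seed = seed,
    spec = unclass(spec),
    config = unclass(config),
    methods = methods,
    ratios = ratios,
    stages = names(artifacts),
    artifacts = artifacts)
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(status = 0L, manifest = run_manifest, metrics = metrics,
                 model = model))
}
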