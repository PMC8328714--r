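# End-to-end orchestration: phantom generation -> training -> prediction
# -> CRF refinement -> connected-component postprocessing -> evaluation,
# with a single master seed deterministically deriving every stage seed.

#' Default pipeline configuration
#'
#' Training defaults echo the reference setup (Adam, learning rate 0.0001,
#' momentum 0.9, regularization 0.0005, at most 21,000 iterations, zero
#' bias initialization, loss weights 0.8/0.2); postprocessing defaults are
#' a mean-TTP threshold of 100 and a volume-ratio threshold of 0.1.
#'
#' @return Nested list of defaults; see [validate_config()] for the keys.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    phantom = list(shape = c(64L, 64L, 1L), spacing = c(1, 1, 5),
                   n_lesions = 1L, radius_range = c(5, 12),
                   channel_model = default_channel_model(),
                   ttp_model = c(background_mean = 60, lesion_mean = 120,
                                 noise_sd = 8),
                   n_train = 100L, n_eval = 20L),
    network = list(depth = 2L, base_channels = 8L, input_channels = NULL),
    train = list(learning_rate = 1e-4, momentum = 0.9,
                 regularization = 5e-4, max_iterations = 21000L,
                 batch_size = 8L, loss_weights = c(0.8, 0.2)),
    crf = list(enabled = TRUE, w1 = 1, w2 = 1, sigma_alpha = 3,
               sigma_beta = 10, sigma_gamma = 3, iterations = 5L,
               reference_channel = NULL),
    postprocess = list(enabled = TRUE, ttp_threshold = 100,
                       volume_ratio_threshold = 0.1, connectivity = 26L,
                       ttp_removal_side = "below", ttp_channel = "TTP")
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(paste0("unknown config key", if (length(unknown) > 1) "s", " in ",
                 section, ": ", paste(unknown, collapse = ", ")),
          class = "strokeseg_config_error")
  # keep keys whose user value is NULL at their defaults (YAML "~")
  modifyList(defaults, user[!vapply(user, is.null, logical(1))])
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills every omitted key
#' with the package default, and validates ranges. An empty file resolves
#' to the full default configuration.
#'
#' @param path Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else {
    if (!file.exists(path))
      abort(paste0("config file not found: ", path),
            class = "strokeseg_io_error")
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) list() else cfg
  }
  defs <- pipeline_defaults()
  top_unknown <- setdiff(names(user), names(defs))
  if (length(top_unknown))
    abort(paste0("unknown config keys: ", paste(top_unknown, collapse = ", ")),
          class = "strokeseg_config_error")
  cfg <- defs
  for (nm in c("seed", "output_dir"))
    if (!is.null(user[[nm]])) cfg[[nm]] <- user[[nm]]
  for (nm in c("phantom", "network", "train", "crf", "postprocess"))
    cfg[[nm]] <- merge_section(defs[[nm]], user[[nm]], nm)

  tr <- cfg$train
  if (tr$learning_rate <= 0)
    abort("train.learning_rate must be > 0", class = "strokeseg_config_error")
  if (tr$max_iterations < 1)
    abort("train.max_iterations must be >= 1",
          class = "strokeseg_config_error")
  if (abs(sum(tr$loss_weights) - 1) > 1e-9 || any(tr$loss_weights < 0))
    abort("train.loss_weights must be non-negative and sum to 1",
          class = "strokeseg_config_error")
  # construct the stage objects once so their own validation runs
  cfg$phantom_config <- phantom_config(
    shape = cfg$phantom$shape, spacing = cfg$phantom$spacing,
    n_lesions = cfg$phantom$n_lesions,
    radius_range = cfg$phantom$radius_range,
    channel_model = lapply(cfg$phantom$channel_model, unlist),
    ttp_model = unlist(cfg$phantom$ttp_model), seed = cfg$seed)
  cfg$crf_params <- crf_params(w1 = cfg$crf$w1, w2 = cfg$crf$w2,
                               sigma_alpha = cfg$crf$sigma_alpha,
                               sigma_beta = cfg$crf$sigma_beta,
                               sigma_gamma = cfg$crf$sigma_gamma,
                               iterations = cfg$crf$iterations)
  cfg$postprocess_params <- postprocess_params(
    ttp_threshold = cfg$postprocess$ttp_threshold,
    volume_ratio_threshold = cfg$postprocess$volume_ratio_threshold,
    connectivity = cfg$postprocess$connectivity,
    ttp_removal_side = cfg$postprocess$ttp_removal_side)
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config A `pipeline_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keep <- setdiff(names(config),
                  c("phantom_config", "crf_params", "postprocess_params"))
  yaml::write_yaml(unclass(config)[keep], path)
  invisible(path)
}

#' Run the full segmentation pipeline
#'
#' Generates training and held-out phantom datasets, trains the network,
#' predicts on the held-out samples, optionally refines with the fully
#' connected CRF and postprocesses with the TTP / volume screens, then
#' evaluates against ground truth. Every stage seed derives from the
#' master seed, so a run is fully reproducible on one device.
#'
#' @param config A [validate_config()] result (or a list/path accepted by
#'   it).
#' @param output_dir Directory for masks, logs and the manifest; defaults
#'   to `config$output_dir` or a temporary directory.
#' @return A `run_manifest`: config hash, per-stage status, file paths,
#'   the per-sample metric table (`metrics`) and its column means
#'   (`summary`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- output_dir %||% config$output_dir %||%
    file.path(tempdir(), paste0("strokeseg-run-", config$seed))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  stages <- list()
  files <- list()

  # phantoms
  train_set <- generate_dataset(config$phantom_config,
                                config$phantom$n_train, seed = seeds[1])
  eval_set <- generate_dataset(config$phantom_config,
                               config$phantom$n_eval, seed = seeds[2])
  stages$phantom <- "ok"

  # network
  in_ch <- config$network$input_channels %||%
    setdiff(names(train_set[[1]]$stack), config$postprocess$ttp_channel)
  model <- build_model(list(channels = in_ch, depth = config$network$depth,
                            base_channels = config$network$base_channels,
                            input_size = config$phantom$shape[1:2],
                            seed = seeds[3]))
  tcfg <- train_config(learning_rate = config$train$learning_rate,
                       momentum = config$train$momentum,
                       regularization = config$train$regularization,
                       max_iterations = config$train$max_iterations,
                       batch_size = config$train$batch_size,
                       seed = seeds[4],
                       loss_weights = config$train$loss_weights)
  model <- train_network(model, train_set, tcfg)
  log_path <- file.path(out, "training_log.csv")
  write.csv(as.data.frame(model$history), log_path, row.names = FALSE)
  files$training_log <- log_path
  stages$train <- "ok"

  ref_channel <- config$crf$reference_channel %||% in_ch[1]
  rows <- vector("list", length(eval_set))
  mask_files <- character(length(eval_set))
  for (i in seq_along(eval_set)) {
    s <- eval_set[[i]]
    pr <- predict(model, s$stack)
    mask <- pr$mask
    dice_net <- tryCatch(evaluate(mask, s$truth)$dice,
                         strokeseg_undefined_metric = function(e) NA_real_)
    if (isTRUE(config$crf$enabled)) {
      ref <- mean_field_refine(pr$probs, s$stack[[ref_channel]],
                               config$crf_params)
      mask <- ref$map
    }
    if (isTRUE(config$postprocess$enabled) && sum(mask$labels) > 0)
      mask <- postprocess(mask, s$stack[[config$postprocess$ttp_channel]],
                          config$postprocess_params)
    rep_i <- tryCatch(evaluate(mask, s$truth),
                      strokeseg_undefined_metric = function(e)
                        tibble(dice = NA_real_, precision = NA_real_,
                               recall = NA_real_, hd_mm = NA_real_,
                               assd_mm = NA_real_, tp = NA_integer_,
                               fp = NA_integer_, fn = NA_integer_,
                               tn = NA_integer_))
    rep_i$sample <- i
    rep_i$dice_network <- dice_net
    rows[[i]] <- rep_i
    mask_files[i] <- file.path(out, sprintf("pred_%03d.nii.gz", i))
    write_mask(mask, mask_files[i])
  }
  stages$predict <- "ok"
  stages$crf <- if (isTRUE(config$crf$enabled)) "ok" else "skipped"
  stages$postprocess <- if (isTRUE(config$postprocess$enabled)) "ok"
                        else "skipped"
  metrics <- do.call(rbind, rows)
  metrics <- metrics[, c("sample", "dice", "precision", "recall", "hd_mm",
                         "assd_mm", "dice_network", "tp", "fp", "fn", "tn")]
  metrics_path <- file.path(out, "metrics.csv")
  write.csv(as.data.frame(metrics), metrics_path, row.names = FALSE)
  files$metrics <- metrics_path
  files$masks <- mask_files
  stages$evaluate <- "ok"

  summary <- colMeans(metrics[, c("dice", "precision", "recall", "hd_mm",
                                  "assd_mm", "dice_network")], na.rm = TRUE)
  manifest <- structure(list(config_hash = rlang::hash(unclass(config)),
                             seed = config$seed, stage_seeds = seeds,
                             stages = stages, files = files,
                             metrics = metrics, summary = summary,
                             model = model, output_dir = out),
                        class = "run_manifest")
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(list(config_hash = manifest$config_hash,
                            seed = config$seed,
                            stage_seeds = seeds,
                            stages = stages,
                            files = files,
                            summary = as.list(summary)),
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$files$manifest <- manifest_path
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> hash ", substr(x$config_hash, 1, 12), ", stages: ",
      paste(names(x$stages), unlist(x$stages), sep = "=", collapse = ", "),
      "\n  mean held-out dice ", round(x$summary[["dice"]], 4), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
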