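#' Default run configuration
#'
#' Nested list of every tunable the command-line workflows accept, with
#' the full-budget training recipes as defaults (localizer: batch 4, lr
#' 1e-4, 2000 epochs; regressor: batch 8, lr 1e-6, 10000 epochs). One
#' master `seed` is split deterministically into per-module streams.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    paths = list(data = "", models = "", outputs = ""),
    phantom = list(n_subjects = 10, image_h = 96, image_w = 128,
                   pixel_spacing_mm = 0.3, sss_depth_mm = 20,
                   sss_diameter_mm = 3.6, n_cortical_vessels = 14,
                   noise_sd = 0.02),
    train = list(batch_size = 4, learning_rate = 1e-4, epochs = 2000,
                 heatmap_sigma = 3, augment = TRUE),
    prednet = list(batch_size = 8, learning_rate = 1e-6, epochs = 10000),
    unmix = list(o2sat_step = 1, fit_scale = TRUE, region_h = 50,
                 region_w = 80, per_depth = TRUE),
    roi = list(a = 1, b = -4, c = 4, d = 11, sigma = 1),
    roi_space = list(ab_max = 5, c_min = 2, c_max = 20,
                     sigma_set = c(1, 2, 3, 4)),
    mcd = list(mode = "combined", n_model = 20, n_data = 20)
  )
}

check_against_defaults <- function(cfg, defaults, path = "") {
  errs <- character()
  for (key in names(cfg)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      errs <- c(errs, paste0("unknown key: ", full))
      next
    }
    d <- defaults[[key]]; v <- cfg[[key]]
    if (is.list(d)) {
      if (!is.list(v)) errs <- c(errs, paste0(full, " must be a section"))
      else errs <- c(errs, check_against_defaults(v, d, full))
    } else if (is.numeric(d) && !is.numeric(v)) {
      errs <- c(errs, paste0(full, " must be numeric"))
    } else if (is.logical(d) && !is.logical(v)) {
      errs <- c(errs, paste0(full, " must be logical"))
    } else if (is.character(d) && !is.character(v)) {
      errs <- c(errs, paste0(full, " must be character"))
    }
  }
  errs
}

merge_config <- function(defaults, cfg) {
  for (key in names(cfg)) {
    defaults[[key]] <- if (is.list(defaults[[key]]) && is.list(cfg[[key]]))
      merge_config(defaults[[key]], cfg[[key]]) else cfg[[key]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills omitted fields from
#' [default_run_config()], and rejects unknown keys and type mismatches
#' with a message listing every offender. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(defaults)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  errs <- check_against_defaults(cfg, defaults)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  merge_config(defaults, cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

log_run <- function(out_path, subcommand, seed, cfg) {
  log_file <- file.path(dirname(out_path), "paoxi-run.log")
  line <- sprintf("%s %s seed=%s config=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  subcommand, seed, config_hash(cfg))
  cat(line, "\n", file = log_file, append = TRUE, sep = "")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE; i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  flags
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

usage <- function() {
  cat("usage: paoxi <subcommand> [--flags]\n",
      "subcommands:\n",
      "  simulate     --subjects N --seed S --out study.rds [--config run.yaml]\n",
      "  train-loc    --data study.rds --fold-out SUBJ --out model.ckpt\n",
      "               [--epochs E --seed S --config run.yaml]\n",
      "  predict      --model model.ckpt --data study.rds --out points.csv\n",
      "  unmix        --data study.rds --out readings.csv [--config run.yaml]\n",
      "  optimize-roi --data study.rds --out roi.json [--config run.yaml]\n",
      "  mcd          --model model.ckpt --data study.rds --mode MODE\n",
      "               [--n-model N --n-data N --seed S] --out mcd.csv\n",
      "  evaluate     --data study.rds --mode two-step|gt|M1..M4 --seed S\n",
      "               --out report.json [--config run.yaml]\n",
      "  --version    print package and schema versions\n", sep = "")
}

default_ucfg <- function(cfg, phantom_cfg = phantom_config()) {
  ref <- build_reference_spectra(wavelength_grid(),
                                 o2sat_step = cfg$unmix$o2sat_step)
  unmix_config(ref, matched_compensation(phantom_cfg),
               fit_scale = cfg$unmix$fit_scale,
               region_h = cfg$unmix$region_h,
               region_w = cfg$unmix$region_w,
               per_depth = cfg$unmix$per_depth)
}

roi_from_cfg <- function(cfg)
  roi_params(cfg$roi$a, cfg$roi$b, cfg$roi$c, cfg$roi$d, cfg$roi$sigma)

#' Command-line dispatch
#'
#' Entry point behind the `paoxi` script (`inst/cli/paoxi`): parses the
#' subcommand and flags, runs the corresponding workflow, writes its
#' output file plus an append-only run log (timestamp, seed, config
#' hash), and returns an exit status (0 on success).
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
dispatch <- function(argv) {
  if (length(argv) == 0) { usage(); return(invisible(1L)) }
  if (argv[1] == "--version") {
    cat(sprintf("paoxi %s (dataset schema v%d)\n",
                as.character(utils::packageVersion("paoxi")),
                .dataset_schema_version))
    return(invisible(0L))
  }
  sub <- argv[1]
  status <- tryCatch({
    flags <- parse_flags(argv[-1])
    cfg <- load_config(flags[["config"]])
    seed <- flag_num(flags, "seed", cfg$seed)
    out <- flags[["out"]]
    switch(sub,
      "simulate" = {
        n <- flag_num(flags, "subjects", cfg$phantom$n_subjects)
        pc <- phantom_config(image_h = cfg$phantom$image_h,
                             image_w = cfg$phantom$image_w,
                             pixel_spacing_mm = cfg$phantom$pixel_spacing_mm,
                             sss_depth_mm = cfg$phantom$sss_depth_mm,
                             sss_diameter_mm = cfg$phantom$sss_diameter_mm,
                             n_cortical_vessels = cfg$phantom$n_cortical_vessels,
                             noise_sd = cfg$phantom$noise_sd)
        ds <- generate_study(n_subjects = n, cfg = pc, seed = seed)
        save_dataset(ds, out)
        log_run(out, sub, seed, cfg)
        0L
      },
      "train-loc" = {
        ds <- load_dataset(flags[["data"]])
        hold <- flags[["fold-out"]]
        samples <- if (is.null(hold)) ds$samples
          else ds$samples[subject_of(ds) != hold]
        tc <- train_config(batch_size = cfg$train$batch_size,
                           learning_rate = cfg$train$learning_rate,
                           epochs = flag_num(flags, "epochs",
                                             cfg$train$epochs),
                           seed = seed,
                           heatmap_sigma = cfg$train$heatmap_sigma,
                           augment = cfg$train$augment)
        model <- build_localizer(
          unet_config(length(ds$samples[[1]]$image$grid$values)),
          seed = seed)
        fit <- train_localizer(model, samples, tc)
        save_localizer(fit$model, out)
        log_run(out, sub, seed, cfg)
        0L
      },
      "predict" = {
        ds <- load_dataset(flags[["data"]])
        model <- load_localizer(flags[["model"]])
        rows <- lapply(seq_along(ds$samples), function(i) {
          pt <- heatmap_to_point(predict_heatmap(model, ds$samples[[i]]$image))
          data.frame(sample_idx = i,
                     subject_id = ds$samples[[i]]$subject_id,
                     pred_x = pt[1], pred_y = pt[2])
        })
        write.csv(do.call(rbind, rows), out, row.names = FALSE)
        log_run(out, sub, seed, cfg)
        0L
      },
      "unmix" = {
        ds <- load_dataset(flags[["data"]])
        ucfg <- default_ucfg(cfg)
        roi <- roi_from_cfg(cfg)
        rows <- lapply(seq_along(ds$samples), function(i) {
          s <- ds$samples[[i]]
          data.frame(sample_idx = i, subject_id = s$subject_id,
                     gt = s$o2satss_gt,
                     o2satss = measure_o2satss(s$image, s$sss_xy, ucfg, roi))
        })
        write.csv(do.call(rbind, rows), out, row.names = FALSE)
        log_run(out, sub, seed, cfg)
        0L
      },
      "optimize-roi" = {
        ds <- load_dataset(flags[["data"]])
        ucfg <- default_ucfg(cfg)
        sp <- cfg$roi_space
        space <- roi_search_space(a_range = -sp$ab_max:sp$ab_max,
                                  b_range = -sp$ab_max:sp$ab_max,
                                  c_range = sp$c_min:sp$c_max,
                                  d_range = sp$c_min:sp$c_max,
                                  sigma_set = sp$sigma_set)
        res <- grid_search_roi(prepare_roi_entries(ds$samples, ucfg), space)
        jsonlite::write_json(list(
          feasible = res$feasible,
          params = unclass(if (res$feasible) res$params
                           else res$best_unconstrained$params),
          mse = if (res$feasible) res$mse else res$best_unconstrained$mse),
          out, auto_unbox = TRUE, digits = NA)
        utils::write.csv(res$table, sub("\\.json$", "_table.csv", out),
                         row.names = FALSE)
        log_run(out, sub, seed, cfg)
        0L
      },
      "mcd" = {
        ds <- load_dataset(flags[["data"]])
        model <- load_localizer(flags[["model"]])
        ucfg <- default_ucfg(cfg)
        roi <- roi_from_cfg(cfg)
        mode <- if (is.null(flags[["mode"]])) cfg$mcd$mode else flags[["mode"]]
        rows <- lapply(seq_along(ds$samples), function(i) {
          mc <- mcd_config(mode,
                           n_model = flag_num(flags, "n-model",
                                              cfg$mcd$n_model),
                           n_data = flag_num(flags, "n-data",
                                             cfg$mcd$n_data),
                           seed = seed + i)
          r <- mcd_sample(model, ds$samples[[i]]$image, ucfg, roi, mc)
          data.frame(subject = ds$samples[[i]]$subject_id, sample = i,
                     epsilon = r$epsilon, beta = r$beta,
                     x_std = r$xy_std["x"], y_std = r$xy_std["y"])
        })
        write.csv(do.call(rbind, rows), out, row.names = FALSE)
        log_run(out, sub, seed, cfg)
        0L
      },
      "evaluate" = {
        ds <- load_dataset(flags[["data"]])
        ucfg <- default_ucfg(cfg)
        roi <- roi_from_cfg(cfg)
        mode <- gsub("-", "_", flags[["mode"]])
        rep <- run_full_pipeline(ds, mode, ucfg, roi,
          loc_cfg = train_config(batch_size = cfg$train$batch_size,
                                 learning_rate = cfg$train$learning_rate,
                                 epochs = cfg$train$epochs, seed = seed),
          prednet_cfg = prednet_train_config(
            batch_size = cfg$prednet$batch_size,
            learning_rate = cfg$prednet$learning_rate,
            epochs = cfg$prednet$epochs, seed = seed))
        jsonlite::write_json(list(mode = rep$mode, metrics = rep$metrics,
                                  n_failed = rep$n_failed),
                             out, auto_unbox = TRUE, digits = NA)
        utils::write.csv(rep$per_sample,
                         sub("\\.json$", "_samples.csv", out),
                         row.names = FALSE)
        log_run(out, sub, seed, cfg)
        0L
      },
      { usage(); 1L })
  }, error = function(e) {
    message("paoxi ", sub, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
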