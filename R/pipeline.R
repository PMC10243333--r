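#' Default experiment configuration
#'
#' A desk-scale end-to-end configuration: a seeded synthetic cohort,
#' optional rigid motion plus registration, 2-frame/10-frame pair
#' construction, training of the three architectures at widths scaled to
#' CPU feasibility, image-quality evaluation on the test split, and renal
#' uptake agreement analysis.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed global seed; every stage derives its own stream from it.
#' @return a nested configuration list.
#' @export
default_experiment_config <- function(out_dir = "results/experiment",
                                      seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    phantom = list(n_cases = 20L, image_shape = c(64L, 64L), n_frames = 10L,
                   kidney_mean_counts_per_frame = 21,
                   background_mean_counts_per_frame = 2,
                   motion_max_px = 0, motion_max_deg = 0),
    registration = list(enabled = FALSE, iterations = 100L, lr = 0.01),
    dataset = list(fractions = c(0.6, 0.2, 0.2), pairs_per_case = 15L,
                   val_pairs_per_case = 10L, test_pairs_per_case = 5L),
    train = list(
      learning_rate = 2e-3, max_epochs = 5L, batch_size = 2L,
      dncnn = list(n_filters = 4L, units = 15L),
      win5rb = list(n_filters = 4L, kernel = 7L),
      resunet = list(level_filters = c(4L, 8L, 16L), bridge_filters = 32L)
    ),
    metrics = list(windowed_ssim = FALSE, joint_hist_bins = 64L),
    uptake = list(mu_per_cm = 0.153)
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_experiment_config()].
#'
#' @param path YAML file.
#' @return a configuration list.
#' @export
read_experiment_config <- function(path) {
  usr <- yaml::read_yaml(path)
  modifyList(default_experiment_config(), usr)
}

stage_done <- function(out_dir, files) all(file.exists(file.path(out_dir, files)))

subsample_pairs <- function(pair_list, k, seed) {
  if (is.null(k) || k >= length(pair_list)) return(pair_list)
  set.seed(seed)
  pair_list[sort(sample(length(pair_list), k))]
}

#' Run the end-to-end experiment
#'
#' Simulate -> (register) -> build dataset -> train the three architectures
#' -> evaluate image quality on the test split -> quantify renal uptake and
#' agreement. Each stage writes its artifacts under `config$out_dir` and is
#' skipped on rerun when its outputs already exist (unless `force`).
#'
#' @param config a configuration list (see [default_experiment_config()]).
#' @param force rerun stages whose outputs already exist.
#' @param verbose print stage progress.
#' @return invisibly, a list with the run manifest and the main result
#'   tables (`metrics_summary`, `uptake`, `agreement`).
#' @export
run_experiment <- function(config = default_experiment_config(),
                           force = FALSE, verbose = TRUE) {
  od <- config$out_dir
  if (!dir.exists(od)) dir.create(od, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  timings <- list()
  archs <- c("dncnn", "win5rb", "resunet")

  # -- stage 1: simulate ----------------------------------------------------
  f_cohort <- "cohort.rds"
  if (force || !stage_done(od, f_cohort)) {
    say("[simulate] generating %d cases", config$phantom$n_cases)
    t0 <- Sys.time()
    sc <- config$phantom$image_shape[1] / 64
    scale_ell <- function(e) list(center = e$center * sc,
                                  semi_axes = e$semi_axes * sc,
                                  rotation_deg = e$rotation_deg)
    def <- phantom_spec()
    base <- phantom_spec(
      image_shape = config$phantom$image_shape,
      pixel_size_mm = def$pixel_size_mm / sc,
      n_frames = config$phantom$n_frames,
      kidneys = lapply(def$kidneys, scale_ell),
      body = scale_ell(def$body),
      kidney_mean_counts_per_frame = config$phantom$kidney_mean_counts_per_frame,
      background_mean_counts_per_frame = config$phantom$background_mean_counts_per_frame)
    specs <- sample_cohort(config$phantom$n_cases, base,
                           seed = config$seed)
    if (config$phantom$motion_max_px > 0 || config$phantom$motion_max_deg > 0) {
      set.seed(config$seed + 1L)
      specs <- lapply(specs, function(s) {
        s$motion <- c(list(rigid_transform()), lapply(seq_len(s$n_frames - 1L),
          function(f) rigid_transform(
            stats::runif(1, -config$phantom$motion_max_deg,
                         config$phantom$motion_max_deg),
            stats::runif(2, -config$phantom$motion_max_px,
                         config$phantom$motion_max_px), 1)))
        s
      })
    }
    cohort <- lapply(specs, generate_phantom)
    saveRDS(cohort, file.path(od, f_cohort))
    timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")
  } else say("[simulate] outputs exist, skipping")
  cohort <- readRDS(file.path(od, f_cohort))

  # -- stage 2: register ----------------------------------------------------
  f_reg <- "registered.rds"
  if (isTRUE(config$registration$enabled)) {
    if (force || !stage_done(od, f_reg)) {
      say("[register] aligning frames to frame 1")
      t0 <- Sys.time()
      registered <- lapply(cohort, function(case) {
        r <- register_series(case$series,
                             iterations = config$registration$iterations,
                             lr = config$registration$lr)
        case$series <- r$series
        case$transforms <- r$transforms
        case
      })
      saveRDS(registered, file.path(od, f_reg))
      jsonlite::write_json(
        lapply(registered, function(case)
          lapply(case$transforms, function(tr)
            list(rotation_deg = tr$rotation_deg,
                 translation_px = tr$translation_px, scale = tr$scale))),
        file.path(od, "transforms.json"), auto_unbox = TRUE, digits = NA)
      timings$register <- as.numeric(Sys.time() - t0, units = "secs")
    } else say("[register] outputs exist, skipping")
    cohort <- readRDS(file.path(od, f_reg))
  }

  # -- stage 3: dataset -----------------------------------------------------
  f_ds <- "dataset.rds"
  if (force || !stage_done(od, f_ds)) {
    say("[dataset] building 2-frame/10-frame pairs and case split")
    t0 <- Sys.time()
    split <- split_cases(names(cohort), fractions = config$dataset$fractions,
                         seed = config$seed + 2L)
    pairs_of <- function(ids, k) {
      out <- list()
      for (id in ids) {
        pl <- subsample_pairs(build_pairs(cohort[[id]]$series, id), k,
                              seed = config$seed + 3L)
        out <- c(out, lapply(pl, standardize_pair))
      }
      out
    }
    ds <- list(split = split,
               train = pairs_of(split$train, config$dataset$pairs_per_case),
               validation = pairs_of(split$validation,
                                     config$dataset$val_pairs_per_case),
               test = pairs_of(split$test, config$dataset$test_pairs_per_case))
    saveRDS(ds, file.path(od, f_ds))
    manifest <- do.call(rbind, lapply(c("train", "validation", "test"),
      function(s) data.frame(
        split = s,
        case_id = vapply(ds[[s]], function(p) p$case_id, character(1)),
        frame_a = vapply(ds[[s]], function(p) p$frame_indices[1], integer(1)),
        frame_b = vapply(ds[[s]], function(p) p$frame_indices[2], integer(1)))))
    utils::write.csv(manifest, file.path(od, "dataset_manifest.csv"),
                     row.names = FALSE)
    timings$dataset <- as.numeric(Sys.time() - t0, units = "secs")
  } else say("[dataset] outputs exist, skipping")
  ds <- readRDS(file.path(od, f_ds))

  # -- stage 4: train -------------------------------------------------------
  models <- list()
  for (arch in archs) {
    f_model <- sprintf("model_%s.rds", arch)
    if (force || !stage_done(od, f_model)) {
      say("[train] %s", arch)
      t0 <- Sys.time()
      model <- switch(arch,
        dncnn = build_dncnn(n_filters = config$train$dncnn$n_filters,
                            units = config$train$dncnn$units,
                            seed = config$seed + 10L),
        win5rb = build_win5rb(n_filters = config$train$win5rb$n_filters,
                              kernel = config$train$win5rb$kernel,
                              seed = config$seed + 10L),
        resunet = build_resunet(level_filters = config$train$resunet$level_filters,
                                bridge_filters = config$train$resunet$bridge_filters,
                                seed = config$seed + 10L))
      cfg <- train_config(learning_rate = config$train$learning_rate,
                          max_epochs = config$train$max_epochs,
                          batch_size = config$train$batch_size,
                          seed = config$seed + 20L)
      res <- train(model, ds$train, ds$validation, cfg)
      save_model(res$model, file.path(od, f_model))
      utils::write.csv(res$history, file.path(od, sprintf("history_%s.csv", arch)),
                       row.names = FALSE)
      timings[[paste0("train_", arch)]] <- as.numeric(Sys.time() - t0,
                                                      units = "secs")
    } else say("[train] %s exists, skipping", arch)
    models[[arch]] <- load_model(file.path(od, sprintf("model_%s.rds", arch)))
  }

  # -- stage 5: evaluate ----------------------------------------------------
  f_metrics <- c("metrics_summary.csv", "metrics_per_image.csv")
  shorts <- lapply(ds$test, function(p) p$short_time)
  refs <- lapply(ds$test, function(p) p$full_time)
  preds <- lapply(models, function(m)
    lapply(ds$test, function(p) predict_counts(m, p$short_time, p$params)))
  if (force || !stage_done(od, f_metrics)) {
    say("[evaluate] image-quality metrics on %d test pairs", length(refs))
    t0 <- Sys.time()
    ev <- evaluate_split(preds, shorts, refs,
                         windowed = isTRUE(config$metrics$windowed_ssim))
    utils::write.csv(ev$summary, file.path(od, "metrics_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$per_image, file.path(od, "metrics_per_image.csv"),
                     row.names = FALSE)
    for (mname in c(list(`short-time` = shorts), preds) |> names()) {
      imgs <- if (mname == "short-time") shorts else preds[[mname]]
      jh <- joint_histogram(imgs, refs, bins = config$metrics$joint_hist_bins)
      utils::write.csv(cbind(r2 = jh$r2, as.data.frame(jh$histogram)),
                       file.path(od, sprintf("joint_histogram_%s.csv", mname)),
                       row.names = FALSE)
    }
    timings$evaluate <- as.numeric(Sys.time() - t0, units = "secs")
  } else say("[evaluate] outputs exist, skipping")

  # -- stage 6: uptake ------------------------------------------------------
  f_upt <- c("uptake.csv", "agreement.csv")
  if (force || !stage_done(od, f_upt)) {
    say("[uptake] renal uptake and agreement on the test cases")
    t0 <- Sys.time()
    rows <- list()
    for (id in ds$split$test) {
      case <- cohort[[id]]
      rois <- roi_set(case$truth$kidney_masks, case$truth$background_mask,
                      pixel_size_mm = case$series$pixel_size_mm)
      D <- case$truth$total_dose_counts
      nf <- dim(case$series$frames)[3]
      full <- sum_frames(case$series)
      short <- sum_frames(case$series, c(1L, 2L))
      imgs <- c(list(`full-time` = full, `short-time` = short),
                lapply(models, function(m) predict_counts(m, short)))
      Ds <- c(D, D * 2 / nf, rep(D, length(models)))
      for (i in seq_along(imgs)) {
        u <- image_uptake(imgs[[i]], rois, D = Ds[i], k = 1)
        u$case_id <- id
        u$image_type <- names(imgs)[i]
        u$true_uptake_percent <- case$truth$true_uptake_fraction[u$kidney] * 100
        rows[[length(rows) + 1L]] <- u
      }
    }
    upt <- do.call(rbind, rows)
    utils::write.csv(upt, file.path(od, "uptake.csv"), row.names = FALSE)
    ref <- upt[upt$image_type == "full-time", ]
    agr <- list()
    for (ty in setdiff(unique(upt$image_type), "full-time")) {
      cmp <- upt[upt$image_type == ty, ]
      key <- paste(ref$case_id, ref$kidney)
      cmp <- cmp[match(key, paste(cmp$case_id, cmp$kidney)), ]
      ag <- agreement_analysis(ref$uptake_percent, cmp$uptake_percent)
      agr[[length(agr) + 1L]] <- data.frame(
        image_type = ty, r2 = ag$r2, bias = ag$bias, lower = ag$lower,
        upper = ag$upper, n = ag$n)
      p <- bland_altman_plot(ref$uptake_percent, cmp$uptake_percent,
                             title = sprintf("Renal uptake: %s vs full-time", ty))
      try(ggplot2::ggsave(file.path(od, sprintf("bland_altman_%s.png", ty)),
                          p, width = 5, height = 4, dpi = 120), silent = TRUE)
    }
    utils::write.csv(do.call(rbind, agr), file.path(od, "agreement.csv"),
                     row.names = FALSE)
    timings$uptake <- as.numeric(Sys.time() - t0, units = "secs")
  } else say("[uptake] outputs exist, skipping")

  manifest <- list(config = config, timings = timings,
                   r_version = R.version.string,
                   total_seconds = as.numeric(Sys.time() - t_start,
                                              units = "secs"))
  jsonlite::write_json(manifest, file.path(od, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(
    manifest = manifest,
    metrics_summary = utils::read.csv(file.path(od, "metrics_summary.csv")),
    uptake = utils::read.csv(file.path(od, "uptake.csv")),
    agreement = utils::read.csv(file.path(od, "agreement.csv"))))
}
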