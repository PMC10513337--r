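# End-to-end orchestration: generate synthetic sections, train/apply the
# segmenter, measure bundles, profile them radially, compare internodes,
# and train/apply the VAE morpher. All randomness flows from named seeds in
# the config, so a rerun with the same config reproduces every artifact.

#' Default pipeline run configuration
#'
#' @param stages character vector among "generate", "segment", "measure",
#'   "profile", "stats", "vae" (dependency order enforced: measure needs
#'   generate; profile/stats/vae need measure; segment needs generate).
#' @param internodes internode ids to simulate.
#' @param seeds integer seeds, one section per seed and internode.
#' @param out_dir output directory.
#' @param seg segmentation config ([seg_config()]) or NULL to skip training
#'   even when "segment" is requested.
#' @param vae VAE config ([vae_config()]).
#' @param n_bins area-fraction profile bins.
#' @param alpha significance level for the stats stage.
#' @param use_truth_masks measure from ground-truth masks (TRUE) or from
#'   the segmenter's predictions (FALSE; requires the segment stage).
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("generate", "measure", "profile", "stats"),
                       internodes = c(2L, 32L), seeds = 1:3,
                       out_dir = tempfile("culmorph_run_"),
                       seg = NULL, vae = vae_config(),
                       n_bins = 20L, alpha = 0.05, use_truth_masks = TRUE) {
  known <- c("generate", "segment", "measure", "profile", "stats", "vae")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(schema = "culmorph/run/1", stages = stages,
                 internodes = as.integer(internodes),
                 seeds = as.integer(seeds), out_dir = out_dir, seg = seg,
                 vae = vae, n_bins = as.integer(n_bins), alpha = alpha,
                 use_truth_masks = use_truth_masks),
            class = "run_config")
}

require_stage <- function(config, stage, needed_by) {
  if (!stage %in% config$stages)
    stop("stage '", needed_by, "' requires stage '", stage,
         "', which is not selected")
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order and writes CSV/PNG
#' artifacts plus a plain-text log into `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  cat("culmorph pipeline run\n", file = log_path)
  logf("stages: %s", paste(config$stages, collapse = ", "))
  logf("internodes: %s; seeds: %s",
       paste(config$internodes, collapse = ","),
       paste(config$seeds, collapse = ","))
  res <- list(sections = list())
  if ("generate" %in% config$stages) {
    for (id in config$internodes) {
      arch <- make_archetype(id)
      write_archetype_yaml(arch, file.path(config$out_dir,
                                           sprintf("archetype_i%02d.yaml", id)))
      for (s in config$seeds) {
        key <- sprintf("i%02d_s%d", id, s)
        sec <- generate_section(arch, seed = s)
        res$sections[[key]] <- c(sec, list(internode = id, seed = s))
        write_section_png(sec$image,
                          file.path(config$out_dir, paste0(key, ".png")))
        write_mask_tiff(sec$truth,
                        file.path(config$out_dir, paste0(key, "_mask.tiff")))
        logf("generated %s: %d bundles", key, max(sec$truth$instance_mask))
      }
    }
  }
  if ("segment" %in% config$stages && !is.null(config$seg)) {
    require_stage(config, "generate", "segment")
    cfg <- config$seg
    tiles <- list()
    for (sec in res$sections) {
      tl <- crop_tiles(sec$image, (sec$truth$instance_mask > 0) * 1L,
                       cfg$tile_size)
      tiles <- c(tiles, tl)
    }
    model <- train_seg(build_unet(cfg), tiles, cfg)
    write_history_csv(model, file.path(config$out_dir, "seg_history.csv"))
    save_model(model, file.path(config$out_dir, "seg_model.rds"))
    res$seg_model <- model
    for (key in names(res$sections)) {
      pred <- predict_mask(model, res$sections[[key]]$image)
      res$sections[[key]]$pred <- pred
      ev <- evaluate_seg(pred, res$sections[[key]]$truth)
      logf("segmented %s: accuracy %.4f, merges %d, missed %d", key,
           ev$pixel_accuracy, ev$connection_errors, ev$missed)
      png::writePNG(pred, file.path(config$out_dir, paste0(key, "_pred.png")))
    }
  }
  if ("measure" %in% config$stages) {
    require_stage(config, "generate", "measure")
    for (key in names(res$sections)) {
      sec <- res$sections[[key]]
      frame <- sec$truth$frame
      labels <- if (config$use_truth_masks) sec$truth$instance_mask
                else label_components(sec$pred)
      rec <- measure_bundles(labels, frame)
      rec$internode <- sec$internode
      rec$seed <- sec$seed
      res$sections[[key]]$records <- rec
      write_bundles_csv(rec, file.path(config$out_dir,
                                       paste0(key, "_bundles.csv")))
      logf("measured %s: %d bundles", key, nrow(rec))
    }
    res$records <- do.call(rbind, lapply(res$sections, `[[`, "records"))
  }
  if ("profile" %in% config$stages) {
    require_stage(config, "measure", "profile")
    for (key in names(res$sections)) {
      sec <- res$sections[[key]]
      mask <- if (config$use_truth_masks) sec$truth$instance_mask else sec$pred
      prof <- area_fraction_profile(mask, sec$truth$frame, config$n_bins)
      write_profile_csv(prof, file.path(config$out_dir,
                                        paste0(key, "_area_profile.csv")))
      res$sections[[key]]$profile <- prof
    }
  }
  if ("stats" %in% config$stages) {
    require_stage(config, "measure", "stats")
    ratios <- lapply(res$sections, function(sec) {
      mask <- if (config$use_truth_masks) sec$truth$instance_mask else sec$pred
      data.frame(internode = sec$internode,
                 ratio = area_ratio(mask, sec$truth$frame))
    })
    ratios <- do.call(rbind, ratios)
    groups <- split(ratios$ratio, ratios$internode)
    if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
      tk <- anova_tukey(groups, config$alpha)
      write_stats_csv(tk, file.path(config$out_dir, "area_ratio_tukey.csv"))
      res$area_ratio_stats <- tk
    }
    by_int <- split(res$records$area_px[!res$records$touches_border],
                    res$records$internode[!res$records$touches_border])
    if (length(by_int) >= 2) {
      ks <- kruskal_dscf(by_int, config$alpha)
      write_stats_csv(ks, file.path(config$out_dir, "bundle_area_dscf.csv"))
      res$bundle_area_stats <- ks
    }
    logf("stats stage complete")
  }
  if ("vae" %in% config$stages) {
    require_stage(config, "measure", "vae")
    sec <- res$sections[[1]]
    ext <- extract_bundle_images(sec$truth$instance_mask, sec$records,
                                 config$vae$input_size)
    model <- train_vae(ext$images, config$vae)
    res$vae_model <- model
    anchors <- select_anchors(ext)
    path_obj <- morph(model, anchors$images, anchors$positions)
    res$latent_path <- path_obj
    write_frames_png(path_obj, file.path(config$out_dir, "morph"))
    write_latents_csv(path_obj, file.path(config$out_dir, "morph_latents.csv"))
    logf("vae stage complete: %d frames", length(path_obj$frames))
  }
  logf("done")
  invisible(res)
}
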