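#' Analyze one plant's frame series in memory
#'
#' Runs the full per-plant pipeline on an in-memory [frame_series()]:
#' blank subtraction, optional translation registration, cumulative
#' denoising, segment extraction from both the cumulative masks and the
#' tip-tracking (new growth) masks, vector formatting, iterative cleaning,
#' and trait computation.
#'
#' @param series a [frame_series()] of raw frames.
#' @param blank the batch blank frame (or matrix), or `NULL` to skip.
#' @param key one-row data.frame of plant metadata (`plant_id`, `genotype`,
#'   `replicate`).
#' @param cfg a [pipeline_config()].
#' @return list: `traits` (one row per time point), `true_root`, `removed`,
#'   `segments_raw`, `decision_log`, `registration`, `masks` (the cumulative
#'   [binary_series()]).
#' @export
analyze_series <- function(series, blank = NULL, key = NULL,
                           cfg = pipeline_config()) {
  stopifnot(inherits(series, "frame_series"))
  plant_id <- series[[1]]$plant_id
  if (is.null(key))
    key <- data.frame(plant_id = plant_id, genotype = NA_character_,
                      replicate = NA_character_)
  if (!is.null(blank))
    series <- frame_series(lapply(series, subtract_blank, blank = blank))
  reg_report <- NULL
  if (isTRUE(cfg$register)) {
    if (is.null(cfg$template_box))
      stop("registration requested but no template_box configured")
    reg <- register_series(series, cfg$template_box, cfg$max_shift,
                           cfg$min_corr)
    series <- reg$series
    reg_report <- reg$report
  }
  frame_ncol <- ncol(series[[1]]$pixels)
  masks <- denoise_overlay(series, cfg$denoise_c1, cfg$denoise_m,
                           cfg$denoise_c2, cfg$threshold,
                           cfg$min_particle_px, cfg$working_max,
                           cfg$input_max)
  rm(series)  # raw frames can be large; masks suffice from here on
  gc(verbose = FALSE)
  tips <- tip_series(masks)
  times <- masks$times_h
  raw_list <- lapply(seq_along(times), function(i)
    extract_segments(masks$masks[[i]], times[i], cfg$max_segment_len,
                     cfg$min_skeleton_px))
  raw <- do.call(rbind, raw_list)
  if (nrow(raw) == 0) stop("no root segments detected for ", plant_id)
  raw$plant_id <- plant_id
  vecs <- format_segments(raw, key)
  center_x <- if (is.null(cfg$center_x)) frame_ncol / 2 else cfg$center_x
  cp <- clean_params(cfg$proximity_max, cfg$hard_max_factor,
                     cfg$min_cluster_size, cfg$linearity_threshold,
                     center_x, cfg$anchor)
  cleaned <- clean_iterative(vecs, cp)
  new_by_time <- list()
  for (i in seq_along(times)) {
    nsegs <- extract_segments(tips[[i]], times[i], cfg$max_segment_len,
                              cfg$min_skeleton_px)
    nsegs$plant_id <- plant_id
    new_by_time[[as.character(times[i])]] <-
      if (nrow(nsegs)) format_segments(nsegs, key) else
        cbind(nsegs, data.frame(x_start = numeric(0), y_start = numeric(0),
                                x_end = numeric(0), y_end = numeric(0),
                                gravity_angle = numeric(0)))
  }
  traits <- trait_records(cleaned$true_root, new_by_time,
                          plant_id = plant_id,
                          genotype = key$genotype[1],
                          replicate = key$replicate[1])
  list(traits = traits, true_root = cleaned$true_root,
       removed = cleaned$removed, segments_raw = raw,
       decision_log = cleaned$decision_log, registration = reg_report,
       masks = masks)
}

read_frame_tiff <- function(path, time_h, plant_id, input_max = 65535) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  new_frame(round(px * input_max), time_h, plant_id)
}

#' Read a plant's key file
#'
#' @param path CSV with at least `plant_id`, `genotype`, `replicate`;
#'   optionally `barcode`, `experiment_start_date`, `box`, `position`.
#' @return data.frame; errors on duplicate `plant_id`.
#' @export
read_key <- function(path) {
  key <- read.csv(path, comment.char = "#")
  need <- c("plant_id", "genotype", "replicate")
  miss <- setdiff(need, names(key))
  if (length(miss) > 0)
    stop("key is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(key$plant_id))
    stop("duplicate plant_id in key")
  key
}

#' Run the full pipeline over an input directory
#'
#' Expects `input_dir` to contain `key.csv`, `blank.tif`, and per-plant
#' 16-bit TIFF series named `<plant_id>_d<day>.tif`. Executes preprocess,
#' segment extraction, cleaning, and traits for every plant in the key,
#' then (when at least two genotypes are present and `fit_model` is set)
#' the trajectory mixed model, heritability, and trajectory clustering per
#' trait. All outputs are CSVs with provenance headers plus the resolved
#' configuration, written to `output_dir`.
#'
#' @param input_dir directory of inputs.
#' @param output_dir directory for outputs (created).
#' @param cfg a [pipeline_config()].
#' @return `output_dir`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         cfg = pipeline_config()) {
  key <- read_key(file.path(input_dir, "key.csv"))
  blank_path <- file.path(input_dir, "blank.tif")
  if (!file.exists(blank_path)) stop("missing blank image: ", blank_path)
  blank <- read_frame_tiff(blank_path, 0, "blank", cfg$input_max)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(output_dir, "config.yml"))

  all_traits <- list(); all_true <- list(); all_removed <- list()
  all_raw <- list(); all_reg <- list(); qc <- list()
  for (pi in seq_len(nrow(key))) {
    pid <- key$plant_id[pi]
    files <- list.files(input_dir, sprintf("^%s_d[0-9]+\\.tif$", pid),
                        full.names = TRUE)
    if (length(files) == 0) stop("no frames found for plant ", pid)
    days <- as.integer(sub(".*_d([0-9]+)\\.tif$", "\\1", files))
    ord <- order(days)
    files <- files[ord]; days <- days[ord]
    if (!is.null(cfg$expected_frames) &&
        length(files) != cfg$expected_frames) {
      qc[[length(qc) + 1]] <- data.frame(
        plant_id = pid, criterion = "count",
        detail = sprintf("%d frames, expected %d", length(files),
                         cfg$expected_frames))
      next
    }
    series <- frame_series(lapply(seq_along(files), function(i)
      read_frame_tiff(files[i], 24 * days[i], pid, cfg$input_max)))
    res <- analyze_series(series, blank, key[pi, , drop = FALSE], cfg)
    fg <- mean(res$masks$masks[[length(res$masks$masks)]])
    if (fg > cfg$max_fg_fraction) {
      qc[[length(qc) + 1]] <- data.frame(
        plant_id = pid, criterion = "noise",
        detail = sprintf("final mask coverage %.3f > %.3f", fg,
                         cfg$max_fg_fraction))
      next
    }
    all_traits[[pid]] <- res$traits
    all_true[[pid]] <- res$true_root
    all_removed[[pid]] <- res$removed
    all_raw[[pid]] <- res$segments_raw
    if (!is.null(res$registration)) all_reg[[pid]] <- res$registration
    writeLines(utils::capture.output(print(res$decision_log)),
               file.path(output_dir, sprintf("decisions_%s.txt", pid)))
  }
  seed <- cfg$rng_seed
  traits <- do.call(rbind, all_traits)
  write_csv_prov(traits, file.path(output_dir, "clean_traits.csv"), cfg, seed)
  write_csv_prov(do.call(rbind, all_true),
                 file.path(output_dir, "clean_true_root.csv"), cfg, seed)
  removed <- do.call(rbind, all_removed)
  if (is.null(removed)) removed <- data.frame()
  write_csv_prov(removed, file.path(output_dir, "clean_removed_points.csv"),
                 cfg, seed)
  write_csv_prov(do.call(rbind, all_raw),
                 file.path(output_dir, "segments_raw.csv"), cfg, seed)
  if (length(all_reg) > 0)
    write_csv_prov(do.call(rbind, all_reg),
                   file.path(output_dir, "registration_report.csv"), cfg, seed)
  write_csv_prov(if (length(qc)) do.call(rbind, qc) else
    data.frame(plant_id = character(0), criterion = character(0),
               detail = character(0)),
    file.path(output_dir, "qc_report.csv"), cfg, seed)

  if (isTRUE(cfg$fit_model) &&
      length(unique(traits$genotype[!is.na(traits$genotype)])) >= 2) {
    model_outputs(traits, output_dir, cfg, seed)
  }
  invisible(output_dir)
}

# fit the trajectory model per trait and write fitted values, heritability
# and trajectory clusters
model_outputs <- function(traits, output_dir, cfg, seed) {
  trait_cols <- c("width", "depth", "center_of_mass_x", "center_of_mass_y",
                  "convexhull_area", "depth_width_ratio", "total_length",
                  "average_angle", "length_per_day")
  fv_list <- list(); h2_list <- list()
  for (tc in intersect(trait_cols, names(traits))) {
    obs <- data.frame(y = traits[[tc]], t = traits$time_h - min(traits$time_h),
                      genotype = traits$genotype,
                      replicate = traits$replicate)
    obs <- obs[is.finite(obs$y), , drop = FALSE]
    if (nrow(obs) < 8 || length(unique(obs$genotype)) < 2) next
    fit <- tryCatch(fit_trait_model(obs), error = function(e) NULL)
    if (is.null(fit)) next
    fv <- fitted_values(fit, cfg$time_grid)
    fv <- cbind(trait = tc, fv)
    fv_list[[tc]] <- fv
    h2_list[[tc]] <- data.frame(trait = tc,
                                H2 = broad_sense_heritability(fit))
  }
  if (length(fv_list) > 0) {
    write_csv_prov(do.call(rbind, fv_list),
                   file.path(output_dir, "fitted_values.csv"), cfg, seed)
    write_csv_prov(do.call(rbind, h2_list),
                   file.path(output_dir, "heritability.csv"), cfg, seed)
  }
  # trajectory clustering on average angle of new growth per day
  aa <- traits[is.finite(traits$average_angle_per_day), , drop = FALSE]
  if (nrow(aa) > 0 && length(unique(aa$genotype)) >= 2) {
    m <- tapply(aa$average_angle_per_day, list(aa$genotype, aa$time_h),
                mean)
    cl <- tryCatch(cluster_trajectories(m, cfg$cut_distance),
                   error = function(e) NULL)
    if (!is.null(cl))
      write_csv_prov(data.frame(genotype = names(cl),
                                cluster = as.integer(cl)),
                     file.path(output_dir, "clusters.csv"), cfg, seed)
  }
  invisible(NULL)
}
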